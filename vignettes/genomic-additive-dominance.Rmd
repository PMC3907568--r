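---
title: "Genomic BLUP and REML for additive and dominance SNP effects"
author: "gdblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic BLUP and REML for additive and dominance SNP effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gdblup` works with the classical quantitative-genetics partition of a
genotypic value into a breeding value and a dominance deviation, applied SNP
by SNP under Hardy-Weinberg equilibrium (HWE). For a biallelic SNP with
counted-allele frequency $p$ (and $q = 1 - p$), an individual carrying
$x \in \{0, 1, 2\}$ copies contributes

* to its breeding value: $(x - 2p)\,\alpha$, where $\alpha$ is the average
  effect of a gene substitution, and
* to its dominance deviation: $-2q^2\delta$, $2pq\,\delta$ or $-2p^2\delta$
  for $x = 2, 1, 0$, where $\delta$ is the dominance effect.

Both contrasts have zero expectation under HWE genotype frequencies
$(p^2, 2pq, q^2)$, and at $p = 1/2$ the additive contrast reduces to the
familiar $(-1, 0, 1)$ coding. Stacking the contrasts over $q$ individuals and
$m$ SNPs gives the coding matrices $T_\alpha$ and $T_\delta$
(`additiveCoding()`, `dominanceCoding()`), and phenotypes follow the mixed
model

$$ y = Xb + Z T_\alpha \alpha + Z T_\delta \delta + e, $$

with $\alpha \sim N(0, I\sigma^2_\alpha)$, $\delta \sim N(0, I\sigma^2_\delta)$,
$e \sim N(0, I\sigma^2_e)$, and the covariance between breeding values and
dominance deviations null. Allele frequencies default to in-sample estimates
(so the additive coding is exactly column-centred); an external frequency
vector can be supplied so that a training and a validation panel share one
coding. Missing genotypes are rejected rather than imputed — imputation
quality is a data-preparation concern that the model cannot audit.

# Genomic relationship matrices

The Gram matrices $T_\alpha T_\alpha'$ and $T_\delta T_\delta'$ grow with the
number of SNPs, so `genomicRelationship()` offers three normalizations:

* **Definition I** divides by the expected diagonal variance under HWE:
  $k_\alpha = \sum_k 2p_k(1-p_k)$ for the additive matrix and
  $k_\delta = \sum_k (2p_k(1-p_k))^2$ for the dominance matrix.
* **Definition II** divides by the observed mean diagonal, making the mean
  diagonal exactly 1. Definitions I and II coincide when observed and
  expected SNP variances agree.
* **Definition III** applies the correlation transform
  $G_{ij}/\sqrt{G_{ii}G_{jj}}$, making every diagonal exactly 1; the additive
  version is the genomic analogue of Wright's coefficient of relationship,
  and Definitions II and III coincide when all raw diagonals are equal.

Each definition is carried as a per-individual row scaling of the coding
matrices, so the normalized codings satisfy $T^*_\alpha T^{*\prime}_\alpha = G$
exactly (`normalizedCoding()`); this makes the SNP-effect variances equal the
variances of breeding values and dominance deviations, and no conversion
between the two scales is needed. `definition = "unnormalized"` keeps the raw
Gram matrices; it exists to demonstrate the pathology that variance estimates
then shrink roughly like $1/m$ as markers are added (a characterization test
in the suite), which the default normalization prevents.

The matrices may be singular (whenever $q > m$, or with duplicated
genotypes); nothing downstream inverts them.

# Two identical formulations

GBLUP and REML are implemented twice, with identical results:

* **CE** (conditional expectation) factorizes the $n \times n$ phenotypic
  covariance $V = ZGZ'\sigma^2_a + ZDZ'\sigma^2_d + I\sigma^2_e$. It is
  preferred when markers outnumber individuals.
* **QM** absorbs the fixed effects with $S = I - X(X'X)^+X'$ and solves the
  $2m \times 2m$ SNP-effect equations $[W'SW + \Lambda]\,\hat\theta = W'Sy$
  with $W = Z[T^*_\alpha, T^*_\delta]$ and ridge
  $\Lambda = \mathrm{blockdiag}(\sigma^2_e/\sigma^2_a I,\;
  \sigma^2_e/\sigma^2_d I)$. It is preferred when individuals outnumber
  markers.

`chooseFormulation()` applies the rule *CE if $q < 2m$, else QM*; every
front end accepts `formulation = "auto"`. The equality of the two paths — in
$\hat b$, $\hat a$, $\hat d$, $\hat g$, reliabilities, EM updates and the
restricted likelihood (including its additive constant) — is asserted to
$10^{-8}$ relative error across shapes $q < m$, $q = m$, $q > m$, singular
relationship matrices and rank-deficient $X$; it is the package's primary
correctness certificate, and it settles any residual ambiguity in the
textbook-level algebra, since an error in either path breaks the identity.

Predictions for individuals *without* phenotypic observations need no
separate formulas: such individuals simply have empty columns in $Z$, and the
same expressions produce their GBLUP through the validation-to-training
relationship blocks (CE) or through their coding rows (QM). A validation
individual genotypically identical to a training individual receives exactly
that individual's prediction under Definition III — a test in the suite.

## Reliabilities

With $P = V^{-1} - V^{-1}X(X'V^{-1}X)^+X'V^{-1}$, the prediction variance of
$\hat a$ is $\sigma^4_a\,GZ'PZG$, and the reliability of individual $i$ is
$\mathrm{Var}(\hat a)_{ii}/(G_{ii}\sigma^2_a)$ (likewise for dominance). For
genotypic values the numerator includes the cross term between $\hat a$ and
$\hat d$ and the denominator is $G_{ii}\sigma^2_a + D_{ii}\sigma^2_d$, with
no covariance term because the model assumes null covariance between breeding
value and dominance deviation. The QM route computes the same quantities from
the prediction-error-variance blocks $\sigma^2_e T^* C^{-1} T^{*\prime}$ of
the inverse absorbed coefficient matrix. A null variance component makes the
corresponding reliability 0 (with a warning) rather than 0/0. Note that the
reliability of a training individual does not reach 1 even as
$\sigma^2_a \to \infty$ at small $q$: fixed-effect estimation error
contributes a term of order $1/q$.

# GREML

## EM updates

The EM algorithm follows the Henderson–Harville expectation-maximization
construction in the *SNP-effect* parameterization, written in both CE and QM
quantities:

* CE form: $\sigma^2_i \leftarrow \sigma^2_i + (\sigma^4_i/m)\,
  [y'P V_i P y - \mathrm{tr}(P V_i)]$ for the additive and dominance
  components ($V_a = ZGZ'$, $V_d = ZDZ'$) and
  $\sigma^2_e \leftarrow \sigma^2_e + (\sigma^4_e/n)[y'PPy - \mathrm{tr}(P)]$.
* QM form: $\sigma^2_\alpha \leftarrow (\hat\alpha'\hat\alpha +
  \sigma^2_e\,\mathrm{tr}\,C^{\alpha\alpha})/m$ (likewise for dominance) and
  $\sigma^2_e \leftarrow [\hat e'\hat e + \sigma^2_e(r -
  \lambda_\alpha \mathrm{tr}\,C^{\alpha\alpha} -
  \lambda_\delta \mathrm{tr}\,C^{\delta\delta})]/n$, where $r$ is the rank of
  the full mixed-model-equation coefficient matrix
  ($\mathrm{rank}(X) + 2m$) and $C^{\cdot\cdot}$ are blocks of the inverse
  absorbed coefficient matrix.

The denominators deserve a note, because an alternative EM exists in the
individual-effect parameterization with $q$ in place of $m$. The two have
the same fixed points but different paths. The SNP-effect version was chosen
because it is a genuine EM for *every* shape of the problem — the $q$-denominator
construction presumes an invertible $G$, which fails exactly in the regime the
QM formulation exists for ($q > m$) — so the restricted likelihood is provably
non-decreasing along iterations (checked at every step in the test suite),
and because only this choice makes the CE and QM forms of all three updates
algebraically identical, residual update included. Both properties are
asserted to machine precision in the tests. Components that reach zero stay
at zero under EM (the update is multiplicative); components falling below
`boundary * sigmaP` (default $10^{-8}$) are clamped to zero as genuine
boundary estimates.

## AI-REML and the hybrid default

The average-information algorithm uses scores
$-\tfrac12[\mathrm{tr}(PV_i) - y'PV_iPy]$ and the AI matrix
$\tfrac12\,y'PV_iPV_jPy$. In the QM engine every ingredient — $Py$,
$\mathrm{tr}(P)$, $\mathrm{tr}(PV_i)$ — is obtained from the absorbed system
without ever forming $P$ ($n \times n$) or inverting $G$, $D$.

Newton steps near a variance boundary routinely propose negative components,
and a naive fall-back to EM then crawls (EM approaches a boundary only
geometrically). The driver therefore takes an active-set step: components
proposed negative are clamped to zero and the step is re-solved for the
remainder; a zero component re-enters when its score turns positive; the
proposal is accepted only if the restricted likelihood does not decrease,
with step-halving (factors 1, 1/2, 1/4, 1/10) before giving up and taking an
EM step. `algorithm = "hybrid"` (the default) and `"ai"` both use this
safeguarded Newton; `"em"` is the pure EM. Default initialization splits
$\mathrm{var}(y)$ evenly across the three components; convergence is declared
when the largest component change relative to the current phenotypic variance
falls below `tol` (default $10^{-8}$), a metric that remains meaningful when
a component sits at zero. Standard errors come from the inverse AI matrix at
convergence, restricted to interior components (boundary estimates get `NA`),
with heritability SEs by the delta method — an extension beyond the original
methodology, flagged as such.

Heritabilities are $h^2_a = \sigma^2_a/\sigma^2_p$,
$h^2_d = \sigma^2_d/\sigma^2_p$, $H^2 = h^2_a + h^2_d$ with
$\sigma^2_p = \sigma^2_a + \sigma^2_d + \sigma^2_e$.

## Numerical choices

* $V$ and the absorbed coefficient matrix are factorized by Cholesky, once
  per component setting and reused for BLUE, GBLUP and reliabilities.
* Generalized inverses ($X'V^{-1}X$, $X'X$) use symmetric eigendecomposition
  with relative eigenvalue threshold $10^{-10}$; both engines then return the
  same (minimum-norm) $\hat b$ even for rank-deficient $X$.
* The positive-semidefiniteness tolerance for relationship matrices is
  smallest eigenvalue $\ge -10^{-8} \times$ largest, appropriate for
  floating-point Gram matrices.
* One observation per individual is the fast path; repeated records work
  through $Z$ and are covered by tests.

# The simulator

`simConfig()`/`simulateGenotypes()`/`simulatePhenotypes()` emulate the kind
of data the methodology was evaluated on:

* founder genotypes drawn independently per SNP under HWE, allele
  frequencies Uniform(0.05, 0.95);
* optional sib families by Mendelian gene dropping (each parental allele
  transmitted with probability count/2), with every pair of panel
  individuals labelled full-sib, half-sib or unrelated;
* QTL effects $\alpha_k, \delta_k$ standard normal, or $|N(0,1)|$ for the
  dominance effects in directional mode (positive dominance deviation for
  every heterozygote);
* breeding values and dominance deviations built through the codings and
  rescaled so the realized in-sample variances hit the targets *exactly*
  (phenotypic variance 1 by construction). Exact-variance rescaling was
  chosen over expected-variance scaling so that estimator bias measured on
  replicates is attributable to the estimator, not to sampling of effects.

What the generator does **not** emulate is linkage disequilibrium: SNPs are
independent within founders, and the only LD is the family structure created
by gene dropping. Real SNP panels carry extensive LD between markers and
causal variants; results that depend on it (e.g. the behaviour of large
linked marker panels, which in dense real-structure panels overestimate a
null dominance heritability by about 0.05) are outside what these simulations
can reproduce. Passing tests therefore certify the estimator and its
implementation on architecture-matched causal panels, not performance on any
particular real LD structure.

# Study conditions used by the test suite

The acceptance-style checks run at the following sizes, chosen as the
package's documented study conditions:

* **Full-sib relationships**: 100 full-sib pairs by gene dropping, 5000
  independent SNPs, Definition III; mean full-sib dominance correlation
  expected 0.25 (±0.02), mean additive relationship 0.5.
* **Zero-heritability calibration**: 10 replicates of 1654 individuals and
  503 causal SNPs carrying only dominance (or only additive) effects at
  $h^2 = 0.30$; GREML on the causal variants (Definition II) must keep the
  mean estimate of the null component at or below 0.01 (additive) / 0.02
  (dominance).
* **Recovery grid**: $h^2_a, h^2_d \in \{0, 0.05, 0.15, 0.30\}$, 10
  replicates per cell, 500 individuals. The causal panel is 300 SNPs,
  scaling the reference proportion of about 0.61 causal variants per
  individual (1006 per 1654) to the grid's sample size; keeping that ratio,
  rather than the marker count, preserves the difficulty of separating the
  additive and dominance relationship structures. On this grid the suite
  checks 2-SE recovery of the nonzero-truth components (a component whose
  truth is 0 has a boundary-truncated estimator whose mean is strictly
  positive, so the symmetric band is checked only where it can hold; null
  components are covered by the calibration checks above), complete
  separation of the 0.05 vs 0.30 levels across replicates, the advantage of
  genotypic-value GBLUP over breeding-value GBLUP when dominance is present
  (and its absence when $h^2_d = 0$), and agreement of mean predicted
  accuracy $\sqrt{\text{reliability}}$ with observed accuracy at the grid
  aggregate within 0.05.

One caveat is recorded openly: the per-cell 2-SE recovery check is ~28
simultaneous 95% intervals, so even an exactly unbiased estimator passes all
of them jointly only about a quarter of the time; occasional hair-width
failures there reflect the multiplicity of the check, not a defect in the
estimator, and the suite reports them rather than widening the bands.

# Known limitations

* No LD-aware genotype simulation, no selection or inbreeding dynamics, no
  pedigree-based relationship matrices (pedigree expectations appear only as
  test oracles).
* Single-trait, one-variance-structure models; no single-step blending, no
  Bayesian alternatives.
* Dense linear algebra throughout: intended sizes are up to a few thousand
  individuals (CE) or a few thousand SNP effects (QM); `choose_formulation`
  keeps the factorized matrix as small as the data allow. No iterative
  solvers.
* Genotypes must be complete; sex chromosomes are not treated specially.
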
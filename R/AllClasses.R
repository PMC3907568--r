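#' @import methods
NULL

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' Container for biallelic SNP allele counts
#'
#' Holds a q x m matrix of allele counts (0/1/2 copies of the counted allele
#' per individual per SNP) together with SNP and individual identifiers and
#' the allele frequencies used for all downstream coding. Frequencies are
#' estimated in-sample unless supplied, so that the additive coding is exactly
#' column-centred. SNPs that are monomorphic (or fall below a minor allele
#' frequency threshold) are removed at construction time: coding contrasts are
#' undefined at p = 0 or p = 1.
#'
#' @slot counts integer-valued matrix, individuals in rows, SNPs in columns,
#'   entries in \{0, 1, 2\}.
#' @slot snpIds character vector of SNP identifiers (column names).
#' @slot individualIds character vector of individual identifiers (row names).
#' @slot freqs numeric vector of frequencies of the counted allele, strictly
#'   inside (0, 1).
#'
#' @seealso [GenotypeMatrix()] for the validating constructor,
#'   [additiveCoding()], [dominanceCoding()], [genomicRelationship()].
#' @export
setClass("GenotypeMatrix",
  slots = c(
    counts        = "matrix",
    snpIds        = "character",
    individualIds = "character",
    freqs         = "numeric"
  )
)

setValidity("GenotypeMatrix", function(object) {
  cts <- object@counts
  msg <- character()
  if (length(cts) == 0L)
    msg <- c(msg, "empty genotype matrix")
  if (anyNA(cts))
    msg <- c(msg, "missing genotypes are not supported; impute before import")
  else if (!all(cts %in% c(0, 1, 2)))
    msg <- c(msg, "genotype counts must be 0, 1 or 2")
  if (length(object@snpIds) != ncol(cts))
    msg <- c(msg, "snpIds length != number of SNP columns")
  if (length(object@individualIds) != nrow(cts))
    msg <- c(msg, "individualIds length != number of rows")
  if (anyDuplicated(object@individualIds))
    msg <- c(msg, "duplicate individual ids")
  if (length(object@freqs) != ncol(cts))
    msg <- c(msg, "freqs length != number of SNP columns")
  else if (length(object@freqs) && (any(object@freqs <= 0) || any(object@freqs >= 1)))
    msg <- c(msg, "allele frequencies must lie strictly in (0, 1)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DesignSet
## ---------------------------------------------------------------------------

#' Model matrices for the SNP additive + dominance mixed model
#'
#' Bundles the fixed-effect matrix X (n x c), the incidence matrix Z (n x q)
#' allocating phenotypic observations to individuals, and the unnormalized
#' additive (breeding-value) and dominance (dominance-deviation) coding
#' matrices T_alpha and T_delta (q x m). Individuals without phenotypic
#' observations (a validation set) simply have all-zero Z columns; the same
#' prediction formulas then yield their GBLUP through the relationship blocks.
#'
#' @slot y numeric vector of phenotypic observations (length n).
#' @slot X fixed-effect model matrix, n x c.
#' @slot Z observation-to-individual incidence matrix, n x q, one 1 per row.
#' @slot Talpha additive coding matrix, q x m, entries x - 2p.
#' @slot Tdelta dominance coding matrix, q x m (Falconer contrasts).
#' @slot individualIds identifiers for the q coded individuals.
#' @slot freqs allele frequencies used for the coding.
#' @export
setClass("DesignSet",
  slots = c(
    y             = "numeric",
    X             = "matrix",
    Z             = "matrix",
    Talpha        = "matrix",
    Tdelta        = "matrix",
    individualIds = "character",
    freqs         = "numeric"
  )
)

setValidity("DesignSet", function(object) {
  msg <- character()
  n <- length(object@y)
  q <- nrow(object@Talpha)
  if (nrow(object@X) != n) msg <- c(msg, "nrow(X) != length(y)")
  if (nrow(object@Z) != n) msg <- c(msg, "nrow(Z) != length(y)")
  if (ncol(object@Z) != q) msg <- c(msg, "ncol(Z) != number of coded individuals")
  if (n > 0 && !all(rowSums(object@Z == 1) == 1 & rowSums(object@Z != 0) == 1))
    msg <- c(msg, "each row of Z must contain exactly one 1")
  if (!identical(dim(object@Talpha), dim(object@Tdelta)))
    msg <- c(msg, "Talpha and Tdelta dimensions differ")
  if (length(object@individualIds) != q)
    msg <- c(msg, "individualIds length != nrow(Talpha)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RelationshipPair
## ---------------------------------------------------------------------------

#' Genomic additive and dominance relationship matrices
#'
#' A pair of q x q genomic relationship (or correlation) matrices for breeding
#' values and dominance deviations under one of three normalizations:
#' Definition I divides the Gram matrices of the coding matrices by their
#' expected diagonal variance under Hardy-Weinberg equilibrium
#' (sum 2 p (1 - p) for the additive matrix, sum (2 p (1 - p))^2 for the
#' dominance matrix); Definition II divides by the observed mean diagonal, so
#' the mean diagonal is exactly 1; Definition III rescales to a correlation
#' matrix, so every diagonal is exactly 1 (the genomic version of Wright's
#' coefficient of relationship).
#'
#' The per-individual scaling vectors satisfy
#' `G = diag(scaleAlpha) Talpha Talpha' diag(scaleAlpha)` (and likewise for
#' D), so the normalized codings `diag(scaleAlpha) Talpha` reproduce G exactly
#' and are the Model-2 coding matrices of the mixed-model-equation (QM)
#' formulation.
#'
#' @slot G additive relationship matrix, q x q, symmetric PSD.
#' @slot D dominance relationship matrix, q x q, symmetric PSD.
#' @slot definition "I", "II", "III", or "unnormalized".
#' @slot kAlpha,kDelta the scalar normalizers (Definitions I/II; NA for III).
#' @slot scaleAlpha,scaleDelta per-individual row scalings of the coding
#'   matrices (constant vectors for Definitions I/II).
#' @slot individualIds identifiers of the q individuals.
#' @export
setClass("RelationshipPair",
  slots = c(
    G             = "matrix",
    D             = "matrix",
    definition    = "character",
    kAlpha        = "numeric",
    kDelta        = "numeric",
    scaleAlpha    = "numeric",
    scaleDelta    = "numeric",
    individualIds = "character"
  )
)

setValidity("RelationshipPair", function(object) {
  msg <- character()
  q <- nrow(object@G)
  if (ncol(object@G) != q || !identical(dim(object@D), dim(object@G)))
    msg <- c(msg, "G and D must be square matrices of equal dimension")
  if (q > 0) {
    if (max(abs(object@G - t(object@G))) > 1e-8 * max(1, max(abs(object@G))))
      msg <- c(msg, "G is not symmetric")
    if (max(abs(object@D - t(object@D))) > 1e-8 * max(1, max(abs(object@D))))
      msg <- c(msg, "D is not symmetric")
  }
  if (!object@definition %in% c("I", "II", "III", "unnormalized"))
    msg <- c(msg, "definition must be 'I', 'II', 'III' or 'unnormalized'")
  if (length(object@individualIds) != q)
    msg <- c(msg, "individualIds length != matrix dimension")
  if (length(object@scaleAlpha) != q || length(object@scaleDelta) != q)
    msg <- c(msg, "scaling vectors must have one entry per individual")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## VarianceComponents
## ---------------------------------------------------------------------------

#' Additive, dominance and residual variance components
#'
#' @slot sigmaA variance of breeding values, >= 0.
#' @slot sigmaD variance of dominance deviations, >= 0.
#' @slot sigmaE residual variance, > 0 for a solvable mixed model.
#' @export
setClass("VarianceComponents",
  slots = c(sigmaA = "numeric", sigmaD = "numeric", sigmaE = "numeric")
)

setValidity("VarianceComponents", function(object) {
  v <- c(object@sigmaA, object@sigmaD, object@sigmaE)
  if (length(v) != 3L || anyNA(v)) return("three finite components required")
  if (any(v < 0)) return("variance components must be non-negative")
  TRUE
})

## ---------------------------------------------------------------------------
## HeritabilityEstimates
## ---------------------------------------------------------------------------

#' Narrow-sense, dominance and broad-sense heritabilities
#'
#' h2a = sigmaA / sigmaP, h2d = sigmaD / sigmaP, H2 = h2a + h2d with
#' sigmaP = sigmaA + sigmaD + sigmaE.
#'
#' @slot h2a narrow-sense (additive) heritability.
#' @slot h2d dominance heritability.
#' @slot H2 broad-sense heritability.
#' @slot sigmaP phenotypic variance.
#' @export
setClass("HeritabilityEstimates",
  slots = c(h2a = "numeric", h2d = "numeric", H2 = "numeric", sigmaP = "numeric")
)

setValidity("HeritabilityEstimates", function(object) {
  h <- c(object@h2a, object@h2d, object@H2)
  if (anyNA(h)) return("heritabilities must be finite")
  if (any(h < -1e-12) || any(h > 1 + 1e-12)) return("heritabilities must lie in [0, 1]")
  if (abs(object@h2a + object@h2d - object@H2) > 1e-10)
    return("H2 must equal h2a + h2d")
  TRUE
})

## ---------------------------------------------------------------------------
## PredictionSet
## ---------------------------------------------------------------------------

#' GBLUP of breeding values, dominance deviations and genotypic values
#'
#' Per-individual predictions with reliabilities for every coded individual,
#' whether or not it contributed a phenotypic observation (`observed`).
#' The genotypic-value prediction is the elementwise sum of the additive and
#' dominance predictions.
#'
#' @slot individualIds identifiers.
#' @slot aHat GBLUP of breeding values.
#' @slot dHat GBLUP of dominance deviations.
#' @slot gHat GBLUP of genotypic values, `aHat + dHat`.
#' @slot relA,relD,relG reliabilities in [0, 1].
#' @slot bHat BLUE of the fixed effects.
#' @slot observed logical; TRUE for training individuals (with phenotypes).
#' @slot formulation "ce" or "qm".
#' @export
setClass("PredictionSet",
  slots = c(
    individualIds = "character",
    aHat = "numeric", dHat = "numeric", gHat = "numeric",
    relA = "numeric", relD = "numeric", relG = "numeric",
    bHat = "numeric",
    observed = "logical",
    formulation = "character"
  )
)

setValidity("PredictionSet", function(object) {
  q <- length(object@individualIds)
  msg <- character()
  for (s in c("aHat", "dHat", "gHat", "observed"))
    if (length(slot(object, s)) != q) msg <- c(msg, sprintf("%s length != q", s))
  if (length(object@gHat) == q &&
      max(abs(object@gHat - (object@aHat + object@dHat))) > 1e-8 * max(1, max(abs(object@gHat))))
    msg <- c(msg, "gHat must equal aHat + dHat")
  rel <- c(object@relA, object@relD, object@relG)
  if (length(rel) && (any(rel < -1e-8) || any(rel > 1 + 1e-8)))
    msg <- c(msg, "reliabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## REMLFit
## ---------------------------------------------------------------------------

#' Result of a GREML fit
#'
#' @slot vc final [VarianceComponents-class].
#' @slot heritability [HeritabilityEstimates-class] derived from `vc`.
#' @slot se named numeric vector of standard errors (from the inverse of the
#'   average-information matrix at convergence; heritability SEs by the delta
#'   method). NA when not computable (e.g. boundary estimates).
#' @slot trace data.frame with one row per iteration: sigmaA, sigmaD, sigmaE,
#'   logLik (restricted, up to an additive constant), delta (convergence
#'   metric) and step ("em" or "ai").
#' @slot converged logical.
#' @slot algorithm "em", "ai" or "hybrid".
#' @slot formulation "ce" or "qm" (the one actually used).
#' @export
setClass("REMLFit",
  slots = c(
    vc           = "VarianceComponents",
    heritability = "HeritabilityEstimates",
    se           = "numeric",
    trace        = "data.frame",
    converged    = "logical",
    algorithm    = "character",
    formulation  = "character"
  )
)

## ---------------------------------------------------------------------------
## SimConfig / TruthSet
## ---------------------------------------------------------------------------

#' Configuration of the phenotype/genotype simulator
#'
#' Defaults emulate the study conditions used throughout the package tests:
#' founder genotypes under Hardy-Weinberg equilibrium at independent SNPs with
#' allele frequencies Uniform(0.05, 0.95), optional sib families produced by
#' Mendelian gene dropping, QTL effects drawn standard normal (or folded
#' normal for directional dominance) and rescaled so the realized in-sample
#' heritabilities match the targets exactly.
#'
#' @slot nInd number of unrelated individuals (ignored if a family design is
#'   given via nSires > 0).
#' @slot nSires,damsPerSire,offspringPerDam,nUnrelated family design for
#'   gene dropping; offspring (plus the extra unrelated individuals) form the
#'   genotyped panel.
#' @slot mQtl number of causal SNPs.
#' @slot mNull number of additional non-causal SNPs.
#' @slot h2a,h2d target additive and dominance heritabilities, h2a + h2d < 1.
#' @slot freqRange allele-frequency range for the uniform founder law.
#' @slot dominanceMode "random" (zero-mean effects) or "directional"
#'   (positive dominance deviation for each heterozygote).
#' @slot mu phenotypic mean.
#' @slot seed optional integer seed applied by the simulator entry points.
#' @export
setClass("SimConfig",
  slots = c(
    nInd = "numeric",
    nSires = "numeric", damsPerSire = "numeric", offspringPerDam = "numeric",
    nUnrelated = "numeric",
    mQtl = "numeric", mNull = "numeric",
    h2a = "numeric", h2d = "numeric",
    freqRange = "numeric",
    dominanceMode = "character",
    mu = "numeric",
    seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@h2a < 0 || object@h2d < 0 || object@h2a + object@h2d >= 1)
    msg <- c(msg, "need h2a >= 0, h2d >= 0 and h2a + h2d < 1")
  if (length(object@freqRange) != 2L || object@freqRange[1] <= 0 ||
      object@freqRange[2] >= 1 || diff(object@freqRange) < 0)
    msg <- c(msg, "freqRange must be inside (0, 1)")
  if (!object@dominanceMode %in% c("random", "directional"))
    msg <- c(msg, "dominanceMode must be 'random' or 'directional'")
  if (object@mQtl + object@mNull < 1) msg <- c(msg, "at least one SNP required")
  if (object@nSires > 0) {
    if (object@damsPerSire < 1 || object@offspringPerDam < 1)
      msg <- c(msg, "family design needs damsPerSire >= 1 and offspringPerDam >= 1")
  } else if (object@nInd < 1) {
    msg <- c(msg, "nInd must be >= 1 without a family design")
  }
  if (length(msg)) msg else TRUE
})

#' True genetic values behind a simulated phenotype
#'
#' @slot y phenotypes, mu + a + d + e.
#' @slot a true breeding values (exact in-sample variance h2a * sigmaP).
#' @slot d true dominance deviations (exact in-sample variance h2d * sigmaP).
#' @slot g genotypic values a + d.
#' @slot e residuals (exact in-sample variance (1 - H2) * sigmaP).
#' @slot alpha,delta per-SNP substitution and dominance effects (zero for
#'   non-causal SNPs).
#' @slot qtl indices of the causal SNPs in the genotype matrix.
#' @slot mu phenotypic mean.
#' @export
setClass("TruthSet",
  slots = c(
    y = "numeric", a = "numeric", d = "numeric", g = "numeric", e = "numeric",
    alpha = "numeric", delta = "numeric", qtl = "integer", mu = "numeric"
  )
)
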
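#' @include greml.R
NULL

#' Simulator configuration
#'
#' See [SimConfig-class] for the meaning of each field. Defaults describe
#' unrelated individuals; set `nSires > 0` for a gene-dropping family design
#' (the genotyped panel is then the offspring plus `nUnrelated` extra
#' unrelated individuals).
#'
#' @param nInd number of unrelated individuals.
#' @param nSires,damsPerSire,offspringPerDam,nUnrelated family design.
#' @param mQtl,mNull causal and non-causal SNP counts.
#' @param h2a,h2d target heritabilities (realized exactly in-sample).
#' @param freqRange founder allele-frequency range (uniform law).
#' @param dominanceMode "random" or "directional".
#' @param mu phenotypic mean.
#' @param seed optional seed applied by [simulateGenotypes()] and
#'   [simulatePhenotypes()].
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nInd = 500, nSires = 0, damsPerSire = 2,
                      offspringPerDam = 2, nUnrelated = 100,
                      mQtl = 1000, mNull = 0, h2a = 0.15, h2d = 0.15,
                      freqRange = c(0.05, 0.95),
                      dominanceMode = c("random", "directional"),
                      mu = 0, seed = NA_real_) {
  new("SimConfig", nInd = nInd, nSires = nSires, damsPerSire = damsPerSire,
      offspringPerDam = offspringPerDam, nUnrelated = nUnrelated,
      mQtl = mQtl, mNull = mNull, h2a = h2a, h2d = h2d,
      freqRange = freqRange, dominanceMode = match.arg(dominanceMode),
      mu = mu, seed = seed)
}

.maybeSeed <- function(config) {
  if (!is.na(config@seed)) set.seed(as.integer(config@seed))
}

.hweDraw <- function(n, freqs) {
  m <- length(freqs)
  matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), n, m)
}

## One Mendelian gamete per parent: each transmitted allele is a Bernoulli
## draw with probability count/2 (0, 1/2 or 1).
.geneDrop <- function(parent1, parent2) {
  stats::rbinom(length(parent1), 1L, parent1 / 2) +
    stats::rbinom(length(parent2), 1L, parent2 / 2)
}

#' Simulate SNP genotypes under HWE, optionally with sib families
#'
#' Founder genotypes are drawn independently per SNP under Hardy-Weinberg
#' equilibrium with allele frequencies uniform on `freqRange`. With a family
#' design, each sire is mated to `damsPerSire` dams and offspring genotypes
#' are produced by Mendelian gene dropping; the genotyped panel consists of
#' the offspring plus `nUnrelated` additional founders, and every pair of
#' panel individuals is labelled full-sib (both parents shared), half-sib
#' (sire shared) or unrelated.
#'
#' @param config a [SimConfig-class].
#' @return list with `genotypes` (a [GenotypeMatrix-class]), `pedigree`
#'   (data.frame id/sire/dam, NA for founders) and `pairClasses` (data.frame
#'   id1/id2/class; NULL without a family design).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  .maybeSeed(config)
  m <- as.integer(config@mQtl + config@mNull)
  freqs <- stats::runif(m, config@freqRange[1], config@freqRange[2])
  if (config@nSires == 0) {
    counts <- .hweDraw(as.integer(config@nInd), freqs)
    ## the generator promises m polymorphic SNPs: redraw any column that
    ## came out monomorphic in the panel (possible at extreme frequencies)
    repeat {
      bad <- which(colSums(counts) %in% c(0L, 2L * nrow(counts)))
      if (!length(bad)) break
      freqs[bad] <- stats::runif(length(bad), config@freqRange[1],
                                 config@freqRange[2])
      counts[, bad] <- .hweDraw(nrow(counts), freqs[bad])
    }
    ids <- sprintf("ind%04d", seq_len(nrow(counts)))
    rownames(counts) <- ids
    gm <- GenotypeMatrix(counts)
    return(list(genotypes = gm,
                pedigree = data.frame(id = ids, sire = NA, dam = NA),
                pairClasses = NULL))
  }
  nS <- as.integer(config@nSires)
  nDpS <- as.integer(config@damsPerSire)
  nOpD <- as.integer(config@offspringPerDam)
  sires <- .hweDraw(nS, freqs)
  dams <- .hweDraw(nS * nDpS, freqs)
  nOff <- nS * nDpS * nOpD
  off <- matrix(0L, nOff, m)
  sireOf <- integer(nOff)
  damOf <- integer(nOff)
  k <- 0L
  for (s in seq_len(nS)) for (dd in seq_len(nDpS)) {
    dIdx <- (s - 1L) * nDpS + dd
    for (o in seq_len(nOpD)) {
      k <- k + 1L
      off[k, ] <- .geneDrop(sires[s, ], dams[dIdx, ])
      sireOf[k] <- s
      damOf[k] <- dIdx
    }
  }
  nU <- as.integer(config@nUnrelated)
  unrel <- if (nU > 0) .hweDraw(nU, freqs) else NULL
  counts <- rbind(off, unrel)
  ## redraw columns monomorphic in the genotyped panel (founders, offspring
  ## and extra unrelated individuals for that SNP only; SNPs are independent)
  repeat {
    bad <- which(colSums(counts) %in% c(0L, 2L * nrow(counts)))
    if (!length(bad)) break
    for (j in bad) {
      freqs[j] <- stats::runif(1, config@freqRange[1], config@freqRange[2])
      sires[, j] <- stats::rbinom(nS, 2L, freqs[j])
      dams[, j] <- stats::rbinom(nS * nDpS, 2L, freqs[j])
      off[, j] <- stats::rbinom(nOff, 1L, sires[sireOf[seq_len(nOff)], j] / 2) +
                  stats::rbinom(nOff, 1L, dams[damOf[seq_len(nOff)], j] / 2)
      counts[, j] <- c(off[, j], if (nU > 0) stats::rbinom(nU, 2L, freqs[j]))
    }
  }
  ids <- c(sprintf("off%04d", seq_len(nOff)),
           if (nU > 0) sprintf("unr%04d", seq_len(nU)))
  rownames(counts) <- ids
  sireOf <- c(sireOf, rep(NA_integer_, nU))
  damOf <- c(damOf, rep(NA_integer_, nU))
  idx <- utils::combn(length(ids), 2L)
  i <- idx[1, ]; j <- idx[2, ]
  cls <- rep("unrelated", ncol(idx))
  sameSire <- !is.na(sireOf[i]) & !is.na(sireOf[j]) & sireOf[i] == sireOf[j]
  sameDam <- sameSire & damOf[i] == damOf[j]
  cls[sameSire] <- "half-sib"
  cls[sameDam] <- "full-sib"
  list(
    genotypes = GenotypeMatrix(counts),
    pedigree = data.frame(id = ids,
                          sire = ifelse(is.na(sireOf), NA, paste0("sire", sireOf)),
                          dam = ifelse(is.na(damOf), NA, paste0("dam", damOf))),
    pairClasses = data.frame(id1 = ids[i], id2 = ids[j], class = cls)
  )
}

#' Simulate phenotypes with additive and dominance QTL effects
#'
#' Causal SNPs are drawn at random; their substitution effects `alpha_k` and
#' dominance effects `delta_k` are standard normal (random mode) or folded
#' normal for dominance (directional mode: a positive dominance deviation for
#' each heterozygote). Per-individual breeding values and dominance
#' deviations are built through the breeding-value and dominance-deviation
#' codings and then rescaled so the realized in-sample variance shares equal
#' the targets exactly, with the phenotypic variance (sum of the three
#' component variances) equal to 1; estimator bias measured against these
#' data is therefore attributable to the estimator, not to sampling of the
#' effects.
#'
#' @param gm a [GenotypeMatrix-class] (e.g. from [simulateGenotypes()]).
#' @param config a [SimConfig-class]; `mQtl` of the SNPs in `gm` become
#'   causal.
#' @return A [TruthSet-class].
#' @export
simulatePhenotypes <- function(gm, config) {
  stopifnot(is(gm, "GenotypeMatrix"), is(config, "SimConfig"))
  .maybeSeed(config)
  m <- nSnp(gm)
  mQtl <- as.integer(config@mQtl)
  if (mQtl > m) stop("mQtl exceeds the number of SNPs in the genotype matrix")
  if ((config@h2a > 0 || config@h2d > 0) && mQtl < 1)
    stop("nonzero heritability requires at least one causal SNP")
  q <- nInd(gm)
  qtl <- sort(sample.int(m, mQtl))
  alpha <- numeric(m)
  delta <- numeric(m)
  if (config@h2a > 0) alpha[qtl] <- stats::rnorm(mQtl)
  if (config@h2d > 0) {
    d0 <- stats::rnorm(mQtl)
    delta[qtl] <- if (config@dominanceMode == "directional") abs(d0) else d0
  }
  a <- drop(additiveCoding(gm) %*% alpha)
  d <- drop(dominanceCoding(gm) %*% delta)
  scaleFor <- function(v, target) {
    if (target == 0) return(0)
    s <- stats::var(v)
    if (s <= 0) stop("cannot rescale a zero-variance genetic component; ",
                     "increase the number of causal SNPs")
    sqrt(target / s)
  }
  fa <- scaleFor(a, config@h2a)
  fd <- scaleFor(d, config@h2d)
  a <- a * fa
  d <- d * fd
  alpha <- alpha * fa   # keep per-SNP effects on the realized scale
  delta <- delta * fd
  e0 <- stats::rnorm(q)
  e <- e0 * scaleFor(e0, 1 - config@h2a - config@h2d)
  a <- unname(a)
  d <- unname(d)
  g <- a + d
  new("TruthSet", y = config@mu + g + e, a = a, d = d, g = g, e = e,
      alpha = alpha, delta = delta, qtl = qtl, mu = config@mu)
}

#' Phenotype table for a simulated truth set
#'
#' @param gm the [GenotypeMatrix-class] the truth was simulated on.
#' @param truth a [TruthSet-class].
#' @return data.frame with columns `id` and `y`, ready for [buildDesign()].
#' @export
phenotypeTable <- function(gm, truth) {
  data.frame(id = individualIds(gm), y = truth@y)
}

#' Observed and predicted accuracies of GBLUP against simulated truth
#'
#' Pearson correlations of the true breeding values, dominance deviations and
#' genotypic values with their GBLUP, plus the mean predicted accuracies
#' (square roots of the reliabilities). Correlations with a zero-variance
#' truth component are undefined and reported as NA.
#'
#' @param truth a [TruthSet-class].
#' @param ps a [PredictionSet-class] over the same individuals (in order).
#' @return one-row data.frame: r_a (cor(a, aHat)), r_d, r_g (cor(g, gHat)),
#'   r_g_a (cor(g, aHat)), r_g_d, predAccA, predAccD, predAccG.
#' @export
evaluateAccuracy <- function(truth, ps) {
  stopifnot(is(truth, "TruthSet"), is(ps, "PredictionSet"))
  if (length(truth@y) != length(ps@aHat))
    stop("truth and predictions cover different numbers of individuals")
  sc <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  data.frame(
    r_a = sc(truth@a, ps@aHat), r_d = sc(truth@d, ps@dHat),
    r_g = sc(truth@g, ps@gHat), r_g_a = sc(truth@g, ps@aHat),
    r_g_d = sc(truth@g, ps@dHat),
    predAccA = if (length(ps@relA)) mean(sqrt(pmax(ps@relA, 0))) else NA_real_,
    predAccD = if (length(ps@relD)) mean(sqrt(pmax(ps@relD, 0))) else NA_real_,
    predAccG = if (length(ps@relG)) mean(sqrt(pmax(ps@relG, 0))) else NA_real_
  )
}

#' Simulation study over a heritability grid
#'
#' For every grid cell and replicate: simulate genotypes and phenotypes,
#' estimate the variance components by GREML, compute GBLUP with the
#' estimated components, and record heritability estimates and observed and
#' predicted accuracies. Deterministic under the master seed (per-replicate
#' seeds are drawn once from it).
#'
#' @param grid data.frame with columns `h2a` and `h2d` (one row per cell).
#' @param nReps replicates per cell (default 10).
#' @param nInd,mQtl,mNull problem size per replicate.
#' @param definition GRM definition for the analysis (default "II").
#' @param algorithm,formulation passed to [greml()].
#' @param seed master seed.
#' @param dominanceMode passed to [simConfig()].
#' @param verbose print progress.
#' @return data.frame: one row per cell x replicate with true values,
#'   estimates and accuracy measures; aggregate with [summarizeStudy()].
#' @export
runStudy <- function(grid, nReps = 10, nInd = 500, mQtl = 1000, mNull = 0,
                     definition = "II", algorithm = "hybrid",
                     formulation = "auto", seed = 1,
                     dominanceMode = "random", verbose = FALSE) {
  stopifnot(all(c("h2a", "h2d") %in% names(grid)))
  set.seed(as.integer(seed))
  repSeeds <- matrix(sample.int(.Machine$integer.max %/% 2, nrow(grid) * nReps),
                     nrow(grid), nReps)
  out <- list()
  for (cell in seq_len(nrow(grid))) {
    for (rep in seq_len(nReps)) {
      cfg <- simConfig(nInd = nInd, mQtl = mQtl, mNull = mNull,
                       h2a = grid$h2a[cell], h2d = grid$h2d[cell],
                       dominanceMode = dominanceMode,
                       seed = repSeeds[cell, rep])
      sim <- simulateGenotypes(cfg)
      truth <- simulatePhenotypes(sim$genotypes, cfg)
      ds <- buildDesign(phenotypeTable(sim$genotypes, truth), sim$genotypes)
      pair <- genomicRelationship(ds, definition)
      fit <- greml(ds, pair, algorithm = algorithm, formulation = formulation,
                   tol = 1e-6)
      ps <- suppressWarnings(gblup(ds, pair, fit@vc, formulation = formulation))
      acc <- evaluateAccuracy(truth, ps)
      h <- fit@heritability
      row <- cbind(
        data.frame(h2aTrue = grid$h2a[cell], h2dTrue = grid$h2d[cell],
                   rep = rep, h2aHat = h@h2a, h2dHat = h@h2d, H2Hat = h@H2,
                   sigmaA = fit@vc@sigmaA, sigmaD = fit@vc@sigmaD,
                   sigmaE = fit@vc@sigmaE, converged = fit@converged),
        acc)
      out[[length(out) + 1L]] <- row
      if (verbose)
        message(sprintf("cell (%.2f, %.2f) rep %d: h2aHat=%.3f h2dHat=%.3f",
                        grid$h2a[cell], grid$h2d[cell], rep, h@h2a, h@h2d))
    }
  }
  do.call(rbind, out)
}

#' Aggregate a simulation study into bias / MSE / accuracy tables
#'
#' @param study output of [runStudy()].
#' @return data.frame with one row per cell: mean estimates, bias, relative
#'   bias (NA when the true value is 0), MSE, relative MSE, and mean observed
#'   and predicted accuracies.
#' @export
summarizeStudy <- function(study) {
  cells <- unique(study[, c("h2aTrue", "h2dTrue")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    s <- study[study$h2aTrue == cells$h2aTrue[r] &
               study$h2dTrue == cells$h2dTrue[r], ]
    relOrNA <- function(x, t) if (t > 0) x / t else NA_real_
    out[[r]] <- data.frame(
      h2aTrue = cells$h2aTrue[r], h2dTrue = cells$h2dTrue[r], n = nrow(s),
      h2aMean = mean(s$h2aHat), h2dMean = mean(s$h2dHat),
      h2aSD = stats::sd(s$h2aHat), h2dSD = stats::sd(s$h2dHat),
      h2aBias = mean(s$h2aHat) - cells$h2aTrue[r],
      h2dBias = mean(s$h2dHat) - cells$h2dTrue[r],
      h2aRelBias = relOrNA(mean(s$h2aHat) - cells$h2aTrue[r], cells$h2aTrue[r]),
      h2dRelBias = relOrNA(mean(s$h2dHat) - cells$h2dTrue[r], cells$h2dTrue[r]),
      h2aMSE = mean((s$h2aHat - cells$h2aTrue[r])^2),
      h2dMSE = mean((s$h2dHat - cells$h2dTrue[r])^2),
      h2aRelMSE = relOrNA(mean((s$h2aHat - cells$h2aTrue[r])^2), cells$h2aTrue[r]^2),
      h2dRelMSE = relOrNA(mean((s$h2dHat - cells$h2dTrue[r])^2), cells$h2dTrue[r]^2),
      r_g = mean(s$r_g, na.rm = TRUE), r_g_a = mean(s$r_g_a, na.rm = TRUE),
      r_a = mean(s$r_a, na.rm = TRUE), r_d = mean(s$r_d, na.rm = TRUE),
      predAccA = mean(s$predAccA), predAccG = mean(s$predAccG)
    )
  }
  do.call(rbind, out)
}
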
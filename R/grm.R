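#' @include coding.R
NULL

.makePair <- function(rawA, rawD, definition, kA, kD, sA, sD, ids) {
  G <- diag(sA, nrow = length(sA)) %*% rawA %*% diag(sA, nrow = length(sA))
  D <- diag(sD, nrow = length(sD)) %*% rawD %*% diag(sD, nrow = length(sD))
  G <- (G + t(G)) / 2
  D <- (D + t(D)) / 2
  dimnames(G) <- dimnames(D) <- list(ids, ids)
  new("RelationshipPair", G = G, D = D, definition = definition,
      kAlpha = kA, kDelta = kD, scaleAlpha = sA, scaleDelta = sD,
      individualIds = ids)
}

.grmFromCodings <- function(Ta, Td, freqs, ids, definition) {
  rawA <- tcrossprod(Ta)
  rawD <- tcrossprod(Td)
  q <- nrow(rawA)
  switch(definition,
    I = {
      kA <- sum(2 * freqs * (1 - freqs))
      kD <- sum((2 * freqs * (1 - freqs))^2)
      if (kA <= 0 || kD <= 0) stop("zero normalizer: all SNPs monomorphic")
      .makePair(rawA, rawD, "I", kA, kD,
                rep(1 / sqrt(kA), q), rep(1 / sqrt(kD), q), ids)
    },
    II = {
      kA <- mean(diag(rawA))
      kD <- mean(diag(rawD))
      if (kA <= 0 || kD <= 0) stop("zero normalizer: observed mean diagonal is 0")
      .makePair(rawA, rawD, "II", kA, kD,
                rep(1 / sqrt(kA), q), rep(1 / sqrt(kD), q), ids)
    },
    III = {
      dA <- diag(rawA)
      dD <- diag(rawD)
      bad <- which(dA <= 0 | dD <= 0)
      if (length(bad))
        stop("degenerate individual(s) with zero diagonal (no informative ",
             "genotype for the additive or dominance coding): ",
             paste(ids[bad], collapse = ", "))
      pair <- .makePair(rawA, rawD, "III", NA_real_, NA_real_,
                        1 / sqrt(dA), 1 / sqrt(dD), ids)
      diag(pair@G) <- 1   # exact by construction, guard rounding
      diag(pair@D) <- 1
      pair
    },
    unnormalized = .makePair(rawA, rawD, "unnormalized", 1, 1,
                             rep(1, q), rep(1, q), ids),
    stop("unknown definition '", definition, "'")
  )
}

#' Genomic additive and dominance relationship matrices
#'
#' Computes the genomic additive relationship matrix G and dominance
#' relationship matrix D from the breeding-value and dominance-deviation
#' coding matrices, under one of three normalizations:
#'
#' * **Definition I** divides the Gram matrices by the expected variance of
#'   their diagonal elements under Hardy-Weinberg equilibrium:
#'   `sum(2 p (1-p))` for the additive matrix and `sum((2 p (1-p))^2)` for the
#'   dominance matrix.
#' * **Definition II** divides by the observed mean diagonal, so the mean
#'   diagonal of each output is exactly 1. Definitions I and II coincide when
#'   the observed and expected SNP variances agree.
#' * **Definition III** rescales to correlation matrices (every diagonal
#'   exactly 1, off-diagonals in [-1, 1]); the additive correlations are the
#'   genomic version of Wright's coefficient of relationship. Definitions II
#'   and III coincide when all raw diagonal elements are equal.
#'
#' `definition = "unnormalized"` returns the raw Gram matrices; it exists to
#' demonstrate the pathology that, without normalization, variance-component
#' estimates shrink as the number of markers grows.
#'
#' @param x a [GenotypeMatrix-class] or [DesignSet-class].
#' @param definition "I", "II", "III" or "unnormalized" (default "II").
#' @param ... unused.
#' @return A [RelationshipPair-class].
#' @examples
#' gm <- GenotypeMatrix(rbind(a = c(2, 0, 1), b = c(0, 2, 1), c = c(1, 1, 0)))
#' genomicRelationship(gm, "III")
#' @export
setMethod("genomicRelationship", "GenotypeMatrix",
  function(x, definition = "II", ...) {
    .grmFromCodings(additiveCoding(x), dominanceCoding(x), alleleFreqs(x),
                    individualIds(x), match.arg(definition,
                    c("II", "I", "III", "unnormalized")))
  })

#' @rdname genomicRelationship-GenotypeMatrix-method
#' @export
setMethod("genomicRelationship", "DesignSet",
  function(x, definition = "II", ...) {
    .grmFromCodings(x@Talpha, x@Tdelta, x@freqs, x@individualIds,
                    match.arg(definition, c("II", "I", "III", "unnormalized")))
  })

#' @describeIn RelationshipPair the additive relationship matrix G
#' @param x a `RelationshipPair`
#' @export
setMethod("additiveRelationship", "RelationshipPair", function(x) x@G)
#' @describeIn RelationshipPair the dominance relationship matrix D
#' @export
setMethod("dominanceRelationship", "RelationshipPair", function(x) x@D)
#' @describeIn RelationshipPair the normalization used
#' @export
setMethod("grmDefinition", "RelationshipPair", function(x) x@definition)
#' @describeIn RelationshipPair individual identifiers
#' @export
setMethod("individualIds", "RelationshipPair", function(x) x@individualIds)
#' @describeIn RelationshipPair number of individuals
#' @export
setMethod("nInd", "RelationshipPair", function(x) nrow(x@G))

setMethod("show", "RelationshipPair", function(object) {
  cat("RelationshipPair (Definition ", object@definition, "): ",
      nInd(object), " individuals\n", sep = "")
  cat("  mean diag G =", signif(mean(diag(object@G)), 6),
      " mean diag D =", signif(mean(diag(object@D)), 6), "\n")
})

#' Normalized (Model-2) coding matrices reproducing a relationship pair
#'
#' Returns the row-rescaled coding matrices T_alpha* and T_delta* such that
#' `T_alpha* %*% t(T_alpha*)` equals the pair's G and likewise for D. These
#' are the SNP-effect design matrices of the mixed-model-equation (QM)
#' formulation; with them the SNP-effect variances equal the variances of
#' breeding values and dominance deviations, so no conversion is needed.
#'
#' @param pair a [RelationshipPair-class].
#' @param design the [DesignSet-class] the pair was computed from (same
#'   individuals and SNPs).
#' @return list with elements `Talpha` and `Tdelta`.
#' @export
setMethod("normalizedCoding", signature("RelationshipPair", "DesignSet"),
  function(pair, design) {
    stopifnot(nInd(pair) == nInd(design))
    list(Talpha = pair@scaleAlpha * design@Talpha,
         Tdelta = pair@scaleDelta * design@Tdelta)
  })

#' Summaries of genomic relationships by pedigree relationship class
#'
#' Groups the off-diagonal elements of the additive and dominance matrices by
#' a supplied pair classification (e.g. full-sib / half-sib / unrelated) and
#' reports mean, SD, min, max and the number of outlier pairs beyond a
#' z-score threshold within each class.
#'
#' @param pair a [RelationshipPair-class].
#' @param classes data.frame with columns `id1`, `id2`, `class` partitioning
#'   (a subset of) the individual pairs.
#' @param zThreshold flag pairs whose value deviates from the class mean by
#'   more than this many class SDs (default 3.5).
#' @return data.frame with one row per class x matrix combination.
#' @export
relationshipSummary <- function(pair, classes, zThreshold = 3.5) {
  stopifnot(is(pair, "RelationshipPair"),
            all(c("id1", "id2", "class") %in% names(classes)))
  i <- match(as.character(classes$id1), pair@individualIds)
  j <- match(as.character(classes$id2), pair@individualIds)
  if (anyNA(i) || anyNA(j))
    stop("pair classification refers to unknown individual ids")
  if (any(i == j)) stop("pair classification must not contain self-pairs")
  cls <- as.character(classes$class)
  out <- list()
  for (mat in c("additive", "dominance")) {
    M <- if (mat == "additive") pair@G else pair@D
    vals <- M[cbind(i, j)]
    for (cl in unique(cls)) {
      v <- vals[cls == cl]
      mu <- mean(v)
      sdv <- stats::sd(v)
      nOut <- if (is.finite(sdv) && sdv > 0) sum(abs(v - mu) > zThreshold * sdv) else 0L
      out[[length(out) + 1L]] <- data.frame(
        matrix = mat, class = cl, n = length(v), mean = mu, sd = sdv,
        min = min(v), max = max(v), nOutlier = nOut)
    }
  }
  do.call(rbind, out)
}
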
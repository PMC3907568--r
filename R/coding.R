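#' @include AllGenerics.R
NULL

#' Estimate allele frequencies from allele counts
#'
#' The frequency of the counted allele at SNP k is the column mean of the
#' count matrix divided by 2, i.e. `sum(counts[, k]) / (2 q)`.
#'
#' @param counts q x m matrix of allele counts in \{0, 1, 2\}.
#' @return Numeric vector of length m. SNPs with frequency exactly 0 or 1 are
#'   monomorphic; downstream constructors drop them.
#' @examples
#' estimateAlleleFreqs(cbind(c(0, 1, 2), c(2, 2, 2)))  # 0.5, 1
#' @export
estimateAlleleFreqs <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("genotype matrix must have at least one row and one column")
  if (anyNA(counts))
    stop("missing genotypes are not supported; impute before import")
  if (!all(counts %in% c(0, 1, 2)))
    stop("genotype counts must be 0, 1 or 2")
  colMeans(counts) / 2
}

#' Construct a GenotypeMatrix
#'
#' Validates the count matrix, estimates in-sample allele frequencies when
#' none are supplied, and removes monomorphic SNPs and SNPs at or below the
#' minor-allele-frequency threshold (the number removed is reported).
#' Supplying `freqs` (e.g. frequencies estimated on a combined
#' training + validation panel) overrides the in-sample estimates so that
#' separate panels can share one coding.
#'
#' @param counts q x m matrix of allele counts in \{0, 1, 2\}.
#' @param snpIds,individualIds identifiers; default to dimnames or generated.
#' @param freqs optional externally supplied frequencies of the counted
#'   allele, length m.
#' @param mafThreshold SNPs with minor allele frequency <= this value are
#'   dropped (default 0: only monomorphic SNPs are removed).
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(counts, snpIds = NULL, individualIds = NULL,
                           freqs = NULL, mafThreshold = 0) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("genotype matrix must have at least one row and one column")
  if (is.null(snpIds))
    snpIds <- colnames(counts) %||% paste0("snp", seq_len(ncol(counts)))
  if (is.null(individualIds))
    individualIds <- rownames(counts) %||% paste0("ind", seq_len(nrow(counts)))
  storage.mode(counts) <- "double"
  estimated <- is.null(freqs)
  if (estimated) freqs <- estimateAlleleFreqs(counts)
  if (length(freqs) != ncol(counts))
    stop("freqs must have one entry per SNP")
  maf <- pmin(freqs, 1 - freqs)
  keep <- maf > mafThreshold
  if (!all(keep)) {
    message(sum(!keep), " SNP(s) dropped (monomorphic or MAF <= ",
            format(mafThreshold), ")")
    if (!any(keep)) stop("no polymorphic SNP left after filtering")
    counts <- counts[, keep, drop = FALSE]
    snpIds <- snpIds[keep]
    freqs <- freqs[keep]
  }
  dimnames(counts) <- list(individualIds, snpIds)
  new("GenotypeMatrix", counts = counts, snpIds = as.character(snpIds),
      individualIds = as.character(individualIds), freqs = unname(freqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn GenotypeMatrix allele-count matrix accessor
#' @param x a `GenotypeMatrix`
#' @export
setMethod("genotypeCounts", "GenotypeMatrix", function(x) x@counts)
#' @describeIn GenotypeMatrix SNP identifiers
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) x@snpIds)
#' @describeIn GenotypeMatrix individual identifiers
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) x@individualIds)
#' @describeIn GenotypeMatrix frequencies of the counted allele
#' @export
setMethod("alleleFreqs", "GenotypeMatrix", function(x) x@freqs)
#' @describeIn GenotypeMatrix number of individuals
#' @export
setMethod("nInd", "GenotypeMatrix", function(x) nrow(x@counts))
#' @describeIn GenotypeMatrix number of SNPs
#' @export
setMethod("nSnp", "GenotypeMatrix", function(x) ncol(x@counts))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nInd(object), "individuals x", nSnp(object), "SNPs\n")
  cat("  allele frequency range:",
      paste(signif(range(object@freqs), 3), collapse = " - "), "\n")
})

#' Subset a GenotypeMatrix by individuals and/or SNPs
#'
#' Allele frequencies are carried over unchanged (they refer to the coding,
#' not to the subset), so training/validation splits keep a common coding.
#'
#' @param x a `GenotypeMatrix`
#' @param i individual index (integer, logical or id)
#' @param j SNP index
#' @param drop ignored
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nSnp(x))
  if (is.character(i)) i <- match(i, x@individualIds)
  new("GenotypeMatrix", counts = x@counts[i, j, drop = FALSE],
      snpIds = x@snpIds[j], individualIds = x@individualIds[i],
      freqs = x@freqs[j])
})

.checkFreqs <- function(freqs) {
  if (any(freqs <= 0) || any(freqs >= 1))
    stop("degenerate SNP: allele frequencies must lie strictly in (0, 1)")
  freqs
}

.additiveCoding <- function(counts, freqs) {
  .checkFreqs(freqs)
  out <- sweep(counts, 2L, 2 * freqs, "-")
  dimnames(out) <- dimnames(counts)
  out
}

## Falconer dominance-deviation contrasts: the three genotype classes
## (2, 1, 0 copies) take values -2(1-p)^2, 2p(1-p), -2p^2; zero-mean under
## Hardy-Weinberg genotype frequencies p^2, 2p(1-p), (1-p)^2.
.dominanceCoding <- function(counts, freqs) {
  .checkFreqs(freqs)
  q <- nrow(counts)
  p2 <- matrix(freqs, q, length(freqs), byrow = TRUE)
  out <- matrix(0, q, length(freqs), dimnames = dimnames(counts))
  out[counts == 2] <- (-2 * (1 - p2)^2)[counts == 2]
  out[counts == 1] <- (2 * p2 * (1 - p2))[counts == 1]
  out[counts == 0] <- (-2 * p2^2)[counts == 0]
  out
}

#' Additive (breeding-value) coding matrix
#'
#' Entry for an individual with allele count x at a SNP with counted-allele
#' frequency p is `x - 2p`: the breeding-value contrast of the gene
#' substitution effect under Hardy-Weinberg equilibrium. Columns are exactly
#' mean-zero when frequencies are estimated in-sample; at p = 0.5 the coding
#' is (-1, 0, 1) for counts (0, 1, 2).
#'
#' @param x a [GenotypeMatrix-class] or a plain count matrix.
#' @param freqs allele frequencies (taken from the object when omitted).
#' @return q x m numeric matrix.
#' @export
setMethod("additiveCoding", "GenotypeMatrix", function(x, freqs) {
  if (missing(freqs)) freqs <- x@freqs
  .additiveCoding(x@counts, freqs)
})
#' @rdname additiveCoding-GenotypeMatrix-method
#' @export
setMethod("additiveCoding", "matrix", function(x, freqs) .additiveCoding(x, freqs))

#' Dominance (dominance-deviation) coding matrix
#'
#' Entries for allele counts 2, 1, 0 at a SNP with counted-allele frequency p
#' are `-2(1-p)^2`, `2p(1-p)` and `-2p^2`: the dominance-deviation contrasts
#' under Hardy-Weinberg equilibrium. The coding is invariant to which allele
#' is counted, and its expectation over HWE genotype frequencies is zero.
#'
#' @inheritParams additiveCoding,GenotypeMatrix-method
#' @return q x m numeric matrix.
#' @export
setMethod("dominanceCoding", "GenotypeMatrix", function(x, freqs) {
  if (missing(freqs)) freqs <- x@freqs
  .dominanceCoding(x@counts, freqs)
})
#' @rdname dominanceCoding-GenotypeMatrix-method
#' @export
setMethod("dominanceCoding", "matrix", function(x, freqs) .dominanceCoding(x, freqs))

#' Build the model matrices for the additive + dominance mixed model
#'
#' Assembles y, the fixed-effect matrix X from a model formula on the
#' phenotype table, the incidence matrix Z mapping observations to coded
#' individuals, and the additive/dominance coding matrices for all genotyped
#' individuals. Genotyped individuals absent from the phenotype table get
#' all-zero Z columns and are treated as the validation set by the prediction
#' functions.
#'
#' @param pheno data.frame with an individual-id column, one trait column and
#'   any fixed-effect covariates.
#' @param geno a [GenotypeMatrix-class] covering every phenotyped individual.
#' @param fixed one-sided formula for the fixed effects (default `~ 1`,
#'   intercept only), evaluated in `pheno`.
#' @param idCol,traitCol column names in `pheno` (defaults "id" and "y").
#' @return A [DesignSet-class].
#' @examples
#' gm <- GenotypeMatrix(rbind(a = c(0, 2), b = c(1, 1), c = c(2, 0)))
#' ph <- data.frame(id = c("a", "b", "c"), y = c(1.2, 0.3, -0.5))
#' ds <- buildDesign(ph, gm)
#' @export
buildDesign <- function(pheno, geno, fixed = ~1, idCol = "id", traitCol = "y") {
  stopifnot(is(geno, "GenotypeMatrix"), is.data.frame(pheno))
  if (!idCol %in% names(pheno)) stop("phenotype table lacks id column '", idCol, "'")
  if (!traitCol %in% names(pheno)) stop("phenotype table lacks trait column '", traitCol, "'")
  ids <- as.character(pheno[[idCol]])
  hit <- match(ids, individualIds(geno))
  if (anyNA(hit))
    stop("phenotyped individual(s) without genotypes: ",
         paste(unique(ids[is.na(hit)]), collapse = ", "))
  y <- as.numeric(pheno[[traitCol]])
  if (anyNA(y)) stop("missing phenotype values")
  X <- stats::model.matrix(fixed, data = pheno)
  rk <- qr(X)$rank
  if (rk < ncol(X))
    warning("fixed-effect matrix is rank deficient (rank ", rk, " < ", ncol(X),
            " columns); a generalized inverse will be used")
  n <- length(y)
  q <- nInd(geno)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), hit)] <- 1
  new("DesignSet", y = y, X = X, Z = Z,
      Talpha = additiveCoding(geno), Tdelta = dominanceCoding(geno),
      individualIds = individualIds(geno), freqs = alleleFreqs(geno))
}

#' @describeIn DesignSet individual identifiers of the coded individuals
#' @param x a `DesignSet`
#' @export
setMethod("individualIds", "DesignSet", function(x) x@individualIds)
#' @describeIn DesignSet number of coded individuals
#' @export
setMethod("nInd", "DesignSet", function(x) nrow(x@Talpha))
#' @describeIn DesignSet number of SNPs
#' @export
setMethod("nSnp", "DesignSet", function(x) ncol(x@Talpha))
#' @describeIn DesignSet allele frequencies behind the coding
#' @export
setMethod("alleleFreqs", "DesignSet", function(x) x@freqs)

setMethod("show", "DesignSet", function(object) {
  cat("DesignSet:", length(object@y), "observations,", nInd(object),
      "individuals,", nSnp(object), "SNPs,", ncol(object@X), "fixed-effect columns\n")
  nv <- sum(colSums(object@Z) == 0)
  if (nv > 0) cat("  ", nv, "individual(s) without observations (validation set)\n")
})

#' Choose between the CE and QM formulations
#'
#' The conditional-expectation (CE) form solves an n x n system and is
#' preferred when markers outnumber individuals; the mixed-model-equation (QM)
#' form solves a 2m x 2m system. The rule: use CE if q < 2m, otherwise QM.
#'
#' @param q number of individuals, m number of SNP markers.
#' @param m number of SNP markers.
#' @return `"ce"` or `"qm"`.
#' @examples
#' chooseFormulation(1654, 40000)  # "ce"
#' chooseFormulation(4000, 1000)   # "qm"
#' @export
chooseFormulation <- function(q, m) {
  stopifnot(q >= 1, m >= 1)
  if (q < 2 * m) "ce" else "qm"
}
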
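#' @include simulate.R
NULL

.pkgVersion <- function() as.character(utils::packageVersion("gdblup"))

## md5 of the canonical JSON serialization of a config list; embedded in every
## artifact so outputs can be traced back to the run that produced them.
.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Read a genotype matrix from a PLINK .raw-style or plain TSV file
#'
#' Two whitespace-delimited text dialects are supported and auto-detected
#' from the header. The PLINK "raw" dialect has columns FID IID PAT MAT SEX
#' PHENOTYPE followed by one 0/1/2 column per SNP (IID is used as the
#' individual id). The plain "tsv" dialect has an id column followed by one
#' 0/1/2 column per SNP. Missing values are rejected (pre-impute), malformed
#' tokens are reported with their position, and the MAF filter reports how
#' many SNPs it removed.
#'
#' @param path file path.
#' @param dialect "auto" (default), "raw" or "tsv".
#' @param mafThreshold passed to [GenotypeMatrix()] (default 0: drop only
#'   monomorphic SNPs).
#' @param freqs optional external allele frequencies (same length/order as
#'   the SNP columns, applied before filtering).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, dialect = c("auto", "raw", "tsv"),
                          mafThreshold = 0, freqs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (ncol(dt) < 2L) stop("genotype file needs an id column and >= 1 SNP column")
  hdr <- names(dt)
  if (dialect == "auto")
    dialect <- if (identical(toupper(hdr[1:2]), c("FID", "IID"))) "raw" else "tsv"
  if (dialect == "raw") {
    if (ncol(dt) < 7L) stop("raw dialect needs FID IID PAT MAT SEX PHENOTYPE + SNPs")
    ids <- as.character(dt[[2]])
    cts <- dt[, -(1:6), drop = FALSE]
  } else {
    ids <- as.character(dt[[1]])
    cts <- dt[, -1, drop = FALSE]
  }
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  counts <- as.matrix(cts)
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(counts),
                                               nrow(counts)))) & !is.na(counts),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric genotype token '", counts[bad[1, 1], bad[1, 2]],
           "' at row ", bad[1, 1], " (", ids[bad[1, 1]], "), SNP ",
           colnames(cts)[bad[1, 2]])
    storage.mode(counts) <- "double"
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)
    stop("missing genotype at row ", bad[1, 1], " (", ids[bad[1, 1]],
         "), SNP ", colnames(cts)[bad[1, 2]],
         "; impute before import (no internal imputation)")
  }
  if (!all(counts %in% c(0, 1, 2))) {
    bad <- which(!(counts %in% c(0, 1, 2)), arr.ind = FALSE)
    bad <- arrayInd(bad[1], dim(counts))
    stop("genotype token '", counts[bad[1, 1], bad[1, 2]], "' at row ",
         bad[1, 1], " (", ids[bad[1, 1]], "), SNP ",
         colnames(cts)[bad[1, 2]], " is not 0/1/2")
  }
  GenotypeMatrix(counts, snpIds = colnames(cts), individualIds = ids,
                 freqs = freqs, mafThreshold = mafThreshold)
}

#' Write a genotype matrix as a PLINK .raw-style or plain TSV file
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file.
#' @param dialect "raw" (default) or "tsv"; see [readGenotypes()].
#' @export
writeGenotypes <- function(gm, path, dialect = c("raw", "tsv")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(genotypeCounts(gm))
  names(df) <- snpIds(gm)
  if (dialect == "raw") {
    df <- cbind(data.frame(FID = individualIds(gm), IID = individualIds(gm),
                           PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9), df)
  } else {
    df <- cbind(data.frame(id = individualIds(gm)), df)
  }
  data.table::fwrite(df, path, sep = " ", quote = FALSE)
  invisible(path)
}

#' Write genomic relationship matrices
#'
#' Writes `<prefix>.G.tsv` and `<prefix>.D.tsv` (dense, tab-separated, with
#' an id header), `<prefix>.ids` (one id per line) and GCTA-style
#' lower-triangle text files `<prefix>.G.grm.txt` / `<prefix>.D.grm.txt`
#' (columns: index i, index j, number of SNPs, value).
#'
#' @param pair a [RelationshipPair-class].
#' @param prefix output path prefix.
#' @param nSnps number of SNPs recorded in the GCTA triangle (informational).
#' @return the written file paths, invisibly.
#' @export
writeGRM <- function(pair, prefix, nSnps = NA_integer_) {
  ids <- individualIds(pair)
  paths <- c(G = paste0(prefix, ".G.tsv"), D = paste0(prefix, ".D.tsv"),
             ids = paste0(prefix, ".ids"),
             Ggrm = paste0(prefix, ".G.grm.txt"),
             Dgrm = paste0(prefix, ".D.grm.txt"))
  for (w in c("G", "D")) {
    M <- slot(pair, w)
    df <- data.frame(id = ids, M, check.names = FALSE)
    names(df) <- c("id", ids)
    data.table::fwrite(df, paths[[w]], sep = "\t", quote = FALSE)
    lt <- which(lower.tri(M, diag = TRUE), arr.ind = TRUE)
    tri <- data.frame(i = lt[, 1], j = lt[, 2], nsnp = nSnps,
                      value = M[lt])
    data.table::fwrite(tri, paths[[paste0(w, "grm")]], sep = "\t",
                       quote = FALSE, col.names = FALSE)
  }
  writeLines(ids, paths[["ids"]])
  invisible(paths)
}

#' Read genomic relationship matrices written by [writeGRM()]
#'
#' @param prefix path prefix used when writing.
#' @param definition definition tag to attach (the normalization itself is
#'   not re-derivable from the files; default "II").
#' @return A [RelationshipPair-class] (scaling vectors are not recoverable
#'   from disk and are set to NA).
#' @export
readGRM <- function(prefix, definition = "II") {
  ids <- readLines(paste0(prefix, ".ids"))
  rd <- function(p) {
    df <- data.table::fread(p, data.table = FALSE)
    M <- as.matrix(df[, -1, drop = FALSE])
    dimnames(M) <- list(ids, ids)
    M
  }
  G <- rd(paste0(prefix, ".G.tsv"))
  D <- rd(paste0(prefix, ".D.tsv"))
  new("RelationshipPair", G = G, D = D, definition = definition,
      kAlpha = NA_real_, kDelta = NA_real_,
      scaleAlpha = rep(NA_real_, length(ids)),
      scaleDelta = rep(NA_real_, length(ids)), individualIds = ids)
}

#' Write per-individual GBLUP predictions
#'
#' Tab-separated: id, aHat, relA, dHat, relD, gHat, relG, observed.
#'
#' @param ps a [PredictionSet-class].
#' @param path output file.
#' @param config optional run-config list; its hash is embedded in a header
#'   comment.
#' @export
writePredictions <- function(ps, path, config = NULL) {
  df <- as.data.frame(ps)
  hdr <- sprintf("# gdblup %s%s", .pkgVersion(),
                 if (!is.null(config)) paste0(" config=", .configHash(config)) else "")
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       append = TRUE))
  invisible(path)
}

#' Write a GREML report as JSON
#'
#' Contains the tool version, optional config hash, variance components,
#' heritabilities, standard errors, convergence status and a trace summary.
#'
#' @param fit a [REMLFit-class].
#' @param path output file.
#' @param config optional run-config list included (with its hash).
#' @export
writeReport <- function(fit, path, config = NULL) {
  stopifnot(is(fit, "REMLFit"))
  h <- fit@heritability
  rep <- list(
    tool = "gdblup", version = .pkgVersion(),
    components = list(sigmaA = fit@vc@sigmaA, sigmaD = fit@vc@sigmaD,
                      sigmaE = fit@vc@sigmaE),
    heritabilities = list(h2a = h@h2a, h2d = h@h2d, H2 = h@H2,
                          sigmaP = h@sigmaP),
    se = as.list(fit@se),
    converged = fit@converged,
    algorithm = fit@algorithm,
    formulation = fit@formulation,
    iterations = nrow(fit@trace),
    finalLogLik = if (nrow(fit@trace)) fit@trace$logLik[nrow(fit@trace)] else NA
  )
  if (!is.null(config)) {
    rep$config <- config
    rep$configHash <- .configHash(config)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read/write a run configuration (YAML)
#'
#' A run configuration is a named list (input paths, GRM definition,
#' formulation, algorithm, MAF threshold, tolerances, maximum iterations,
#' seed, output prefix). The round trip config -> file -> config is the
#' identity.
#'
#' @param config named list.
#' @param path YAML file path.
#' @return `readRunConfig` returns the named list.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is.list(config))
  tols <- unlist(config[grepl("tol", names(config), ignore.case = TRUE)])
  if (length(tols) && any(tols <= 0)) stop("all tolerances must be > 0")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
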
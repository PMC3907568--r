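#' @include mme-internal.R grm.R
NULL

#' Phenotypic covariance matrix of the conditional-expectation formulation
#'
#' `V = Z G Z' sigmaA + Z D Z' sigmaD + I sigmaE`, symmetric and positive
#' definite whenever the residual variance is positive.
#'
#' @param Z n x q incidence matrix.
#' @param pair a [RelationshipPair-class].
#' @param vc a [VarianceComponents-class].
#' @return list with `V` and its Cholesky factor `chol`.
#' @export
buildV <- function(Z, pair, vc) {
  stopifnot(is(pair, "RelationshipPair"), is(vc, "VarianceComponents"),
            ncol(Z) == nInd(pair))
  V <- vc@sigmaA * Z %*% tcrossprod(pair@G, Z) +
       vc@sigmaD * Z %*% tcrossprod(pair@D, Z) +
       diag(vc@sigmaE, nrow(Z))
  V <- (V + t(V)) / 2
  ch <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite; a positive residual variance is required"))
  if (any(diag(ch)^2 <= 1e-12 * max(diag(V))))
    stop("V is not positive definite (numerically singular); ",
         "a positive residual variance is required")
  list(V = V, chol = ch)
}

.relWarnOnce <- function(what) {
  warning("null ", what, " variance component: reliability reported as 0",
          call. = FALSE)
}

.newPredictionSet <- function(ids, aHat, dHat, bHat, relA, relD, relG,
                              observed, formulation) {
  new("PredictionSet", individualIds = ids,
      aHat = unname(aHat), dHat = unname(dHat), gHat = unname(aHat + dHat),
      relA = unname(relA), relD = unname(relD), relG = unname(relG),
      bHat = unname(bHat), observed = unname(observed),
      formulation = formulation)
}

#' GBLUP via the conditional-expectation (CE) formulation
#'
#' Solves the n x n generalized-least-squares system once:
#' `bHat = (X'V-X)+ X'V-y`, `aHat = sigmaA G Z' V^-1 (y - X bHat)`,
#' `dHat = sigmaD D Z' V^-1 (y - X bHat)`, `gHat = aHat + dHat`. The
#' relationship matrices are never inverted, so singular G or D (more
#' individuals than markers, duplicated genotypes) pose no problem.
#' Individuals without observations receive validation predictions through
#' their relationship blocks.
#'
#' Reliabilities divide the variance of each prediction by the variance of
#' the predicted effect: with `P = V^-1 - V^-1 X (X'V-X)+ X'V^-1`,
#' `rel_a,i = (sigmaA^2 G Z'PZ G)_ii / (G_ii sigmaA)` and analogously for
#' dominance; the genotypic-value reliability includes the cross term between
#' the additive and dominance predictions and divides by
#' `G_ii sigmaA + D_ii sigmaD` (the covariance between breeding value and
#' dominance deviation is null under the model).
#'
#' @param design a [DesignSet-class].
#' @param pair a [RelationshipPair-class] for the same individuals.
#' @param vc a [VarianceComponents-class] with positive residual variance.
#' @param reliability compute per-individual reliabilities (default TRUE).
#' @return A [PredictionSet-class].
#' @export
gblupCE <- function(design, pair, vc, reliability = TRUE) {
  stopifnot(is(design, "DesignSet"), is(vc, "VarianceComponents"))
  if (nInd(design) != nInd(pair))
    stop("design and relationship pair cover different numbers of individuals")
  pre <- .cePrecompute(design, pair)
  sol <- .ceSolve(pre, vc)
  Ztu <- drop(crossprod(design@Z, sol$u))
  aHat <- vc@sigmaA * drop(pair@G %*% Ztu)
  dHat <- vc@sigmaD * drop(pair@D %*% Ztu)
  q <- nInd(design)
  relA <- relD <- relG <- numeric(0)
  if (reliability) {
    PZ <- sol$P %*% design@Z
    M <- crossprod(design@Z, PZ)                # Z' P Z, q x q
    GM <- pair@G %*% M
    DM <- pair@D %*% M
    varA <- vc@sigmaA^2 * rowSums(GM * pair@G)
    varD <- vc@sigmaD^2 * rowSums(DM * pair@D)
    varG <- varA + varD + 2 * vc@sigmaA * vc@sigmaD * rowSums(GM * pair@D)
    denA <- diag(pair@G) * vc@sigmaA
    denD <- diag(pair@D) * vc@sigmaD
    relA <- ifelse(denA > 0, varA / denA, 0)
    relD <- ifelse(denD > 0, varD / denD, 0)
    relG <- ifelse(denA + denD > 0, varG / (denA + denD), 0)
    if (vc@sigmaA == 0) .relWarnOnce("additive")
    if (vc@sigmaD == 0) .relWarnOnce("dominance")
    relA <- pmin(pmax(relA, 0), 1)
    relD <- pmin(pmax(relD, 0), 1)
    relG <- pmin(pmax(relG, 0), 1)
  }
  .newPredictionSet(design@individualIds, aHat, dHat, sol$bHat,
                    relA, relD, relG, colSums(design@Z != 0) > 0, "ce")
}

#' Assemble the absorbed mixed model equations on SNP effects
#'
#' Model-2 coding uses the normalized matrices `T* = diag(s) T` whose Gram
#' matrix equals the chosen relationship matrix, so SNP-effect variances
#' coincide with the variances of breeding values and dominance deviations.
#' Absorbing the fixed effects with `S = I - X(X'X)+X'` gives
#' `[W'SW + Lambda] theta = W'Sy` with `W = Z [T_alpha*, T_delta*]` and
#' `Lambda = blockdiag(sigmaE/sigmaA I, sigmaE/sigmaD I)`. A null variance
#' component corresponds to an infinite ridge: that block is fixed at zero
#' and dropped from the system.
#'
#' @inheritParams gblupCE
#' @return list with the absorbed coefficient matrix `C`, right-hand side
#'   `rhs`, ridge parameters `lambdaAlpha`/`lambdaDelta`, the absorption
#'   projector `S`, the rank `r` of the full (pre-absorption) coefficient
#'   matrix and the rank `rankX` of X.
#' @export
assembleMME <- function(design, pair, vc) {
  stopifnot(is(design, "DesignSet"), is(vc, "VarianceComponents"))
  pre <- .qmPrecompute(design, pair)
  sol <- .qmSolve(pre, vc)
  act <- sol$act
  m <- pre$m
  C <- matrix(0, sol$Mact, sol$Mact)
  rhs <- numeric(sol$Mact)
  if (act["a"]) {
    C[sol$ia, sol$ia] <- pre$Maa + diag(sol$lamA, m)
    rhs[sol$ia] <- pre$ra
  }
  if (act["d"]) {
    C[sol$id, sol$id] <- pre$Mdd + diag(sol$lamD, m)
    rhs[sol$id] <- pre$rd
  }
  if (all(act)) {
    C[sol$ia, sol$id] <- pre$Mad
    C[sol$id, sol$ia] <- t(pre$Mad)
  }
  S <- diag(nrow(design@X)) - design@X %*% tcrossprod(pre$XtXinv, design@X)
  list(C = C, rhs = rhs,
       lambdaAlpha = sol$lamA, lambdaDelta = sol$lamD,
       S = (S + t(S)) / 2, r = sol$r, rankX = pre$rX,
       alphaHat = sol$alphaHat, deltaHat = sol$deltaHat)
}

#' GBLUP via the mixed-model-equation (QM) formulation
#'
#' Solves the absorbed SNP-effect equations (see [assembleMME()]) and
#' back-transforms: `aHat = T_alpha* alphaHat`, `dHat = T_delta* deltaHat`
#' for every coded individual (with or without observations). Reliabilities
#' come from the prediction-error-variance blocks of the inverse absorbed
#' coefficient matrix: `PEV(aHat) = sigmaE T_alpha* C^aa T_alpha*'` etc.,
#' with the cross blocks entering the genotypic-value reliability.
#' Mathematically identical to [gblupCE()].
#'
#' @inheritParams gblupCE
#' @return A [PredictionSet-class].
#' @export
gblupQM <- function(design, pair, vc, reliability = TRUE) {
  stopifnot(is(design, "DesignSet"), is(vc, "VarianceComponents"))
  if (nInd(design) != nInd(pair))
    stop("design and relationship pair cover different numbers of individuals")
  pre <- .qmPrecompute(design, pair)
  sol <- .qmSolve(pre, vc)
  aHat <- drop(pre$Ta %*% sol$alphaHat)
  dHat <- drop(pre$Td %*% sol$deltaHat)
  relA <- relD <- relG <- numeric(0)
  if (reliability) {
    q <- pre$q
    se <- vc@sigmaE
    denA <- pre$Gdiag * vc@sigmaA
    denD <- pre$Ddiag * vc@sigmaD
    pevA <- pevD <- numeric(q)
    cross <- numeric(q)
    if (sol$Mact > 0) {
      Tfull <- cbind(if (sol$act["a"]) pre$Ta, if (sol$act["d"]) pre$Td)
      TCi <- Tfull %*% sol$Ci
      pevFull <- se * rowSums(TCi * Tfull)
      if (sol$act["a"])
        pevA <- se * rowSums((pre$Ta %*% sol$Ci[sol$ia, sol$ia, drop = FALSE]) * pre$Ta)
      if (sol$act["d"])
        pevD <- se * rowSums((pre$Td %*% sol$Ci[sol$id, sol$id, drop = FALSE]) * pre$Td)
    } else {
      pevFull <- numeric(q)
    }
    varA <- if (sol$act["a"]) denA - pevA else numeric(q)
    varD <- if (sol$act["d"]) denD - pevD else numeric(q)
    varG <- (denA + denD) - pevFull
    relA <- ifelse(denA > 0, varA / denA, 0)
    relD <- ifelse(denD > 0, varD / denD, 0)
    relG <- ifelse(denA + denD > 0, varG / (denA + denD), 0)
    if (vc@sigmaA == 0) .relWarnOnce("additive")
    if (vc@sigmaD == 0) .relWarnOnce("dominance")
    relA <- pmin(pmax(relA, 0), 1)
    relD <- pmin(pmax(relD, 0), 1)
    relG <- pmin(pmax(relG, 0), 1)
  }
  .newPredictionSet(design@individualIds, aHat, dHat, sol$bHat,
                    relA, relD, relG, colSums(design@Z != 0) > 0, "qm")
}

#' GBLUP of breeding values, dominance deviations and genotypic values
#'
#' Front end choosing between the two mathematically identical formulations:
#' the conditional-expectation (CE) form, efficient when markers outnumber
#' individuals, and the SNP-effect mixed-model-equation (QM) form, efficient
#' when individuals outnumber markers. With `formulation = "auto"` the CE
#' form is used when q < 2m and the QM form otherwise.
#'
#' @inheritParams gblupCE
#' @param formulation "auto", "ce" or "qm".
#' @return A [PredictionSet-class].
#' @examples
#' set.seed(7)
#' cfg <- simConfig(nInd = 60, mQtl = 80, h2a = 0.3, h2d = 0.15)
#' sim <- simulateGenotypes(cfg)
#' truth <- simulatePhenotypes(sim$genotypes, cfg)
#' ds <- buildDesign(data.frame(id = individualIds(sim$genotypes), y = truth@y),
#'                   sim$genotypes)
#' pair <- genomicRelationship(ds, "II")
#' ps <- gblup(ds, pair, varianceComponents(0.3, 0.15, 0.55))
#' head(as.data.frame(ps))
#' @export
gblup <- function(design, pair, vc, formulation = c("auto", "ce", "qm"),
                  reliability = TRUE) {
  formulation <- match.arg(formulation)
  if (formulation == "auto")
    formulation <- chooseFormulation(nInd(design), nSnp(design))
  if (formulation == "ce") gblupCE(design, pair, vc, reliability)
  else gblupQM(design, pair, vc, reliability)
}

#' Reliabilities of the CE formulation
#'
#' Convenience wrapper returning only the reliability vectors of [gblupCE()].
#' @inheritParams gblupCE
#' @return list with `relA`, `relD`, `relG`.
#' @export
reliabilityCE <- function(design, pair, vc) {
  ps <- gblupCE(design, pair, vc, reliability = TRUE)
  list(relA = ps@relA, relD = ps@relD, relG = ps@relG)
}

#' Reliabilities of the QM formulation
#'
#' Convenience wrapper returning only the reliability vectors of [gblupQM()].
#' @inheritParams gblupCE
#' @return list with `relA`, `relD`, `relG`.
#' @export
reliabilityQM <- function(design, pair, vc) {
  ps <- gblupQM(design, pair, vc, reliability = TRUE)
  list(relA = ps@relA, relD = ps@relD, relG = ps@relG)
}

#' @describeIn PredictionSet individual identifiers
#' @param x a `PredictionSet`
#' @export
setMethod("individualIds", "PredictionSet", function(x) x@individualIds)

setMethod("show", "PredictionSet", function(object) {
  cat("PredictionSet (", object@formulation, "): ",
      length(object@individualIds), " individuals (",
      sum(object@observed), " training, ", sum(!object@observed),
      " validation)\n", sep = "")
})

#' Coerce a PredictionSet to a data.frame
#'
#' One row per individual: id, aHat, relA, dHat, relD, gHat, relG, observed.
#' @param x a [PredictionSet-class]
#' @param row.names,optional,... ignored
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.PredictionSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(id = x@individualIds, aHat = x@aHat, dHat = x@dHat,
                   gHat = x@gHat, observed = x@observed)
  if (length(x@relA)) {
    df$relA <- x@relA; df$relD <- x@relD; df$relG <- x@relG
  }
  df
}

#' Validation subset of a prediction set
#'
#' @param ps a [PredictionSet-class]
#' @return data.frame of individuals without phenotypic observations.
#' @export
validationSet <- function(ps) {
  stopifnot(is(ps, "PredictionSet"))
  if (!any(!ps@observed)) stop("empty validation set: all individuals have observations")
  df <- as.data.frame(ps)
  df[!df$observed, , drop = FALSE]
}
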
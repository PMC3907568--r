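#' @include gblup.R
NULL

#' Construct (or extract) a VarianceComponents object
#'
#' @param sigmaA additive variance, a numeric vector of length 3
#'   `(sigmaA, sigmaD, sigmaE)`, or a [REMLFit-class] whose estimated
#'   components are returned.
#' @param sigmaD,sigmaE dominance and residual variances.
#' @return A [VarianceComponents-class].
#' @export
varianceComponents <- function(sigmaA, sigmaD = NULL, sigmaE = NULL) {
  if (is(sigmaA, "REMLFit")) return(sigmaA@vc)
  if (is.numeric(sigmaA) && length(sigmaA) == 3L && is.null(sigmaD)) {
    v <- sigmaA
    sigmaA <- v[[1]]; sigmaD <- v[[2]]; sigmaE <- v[[3]]
  }
  new("VarianceComponents", sigmaA = as.numeric(sigmaA),
      sigmaD = as.numeric(sigmaD), sigmaE = as.numeric(sigmaE))
}

#' @describeIn VarianceComponents additive variance
#' @param x a `VarianceComponents`
#' @export
setMethod("sigmaA", "VarianceComponents", function(x) x@sigmaA)
#' @describeIn VarianceComponents dominance variance
#' @export
setMethod("sigmaD", "VarianceComponents", function(x) x@sigmaD)
#' @describeIn VarianceComponents residual variance
#' @export
setMethod("sigmaE", "VarianceComponents", function(x) x@sigmaE)

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents: sigmaA =", signif(object@sigmaA, 6),
      " sigmaD =", signif(object@sigmaD, 6),
      " sigmaE =", signif(object@sigmaE, 6), "\n")
})

.vcVector <- function(vc) c(a = vc@sigmaA, d = vc@sigmaD, e = vc@sigmaE)

#' Heritabilities from variance components
#'
#' Narrow-sense `h2a = sigmaA / sigmaP`, dominance `h2d = sigmaD / sigmaP`
#' and broad-sense `H2 = h2a + h2d`, with phenotypic variance
#' `sigmaP = sigmaA + sigmaD + sigmaE`.
#'
#' @param x a [VarianceComponents-class] or [REMLFit-class].
#' @return A [HeritabilityEstimates-class].
#' @examples
#' heritability(varianceComponents(0.3, 0.15, 0.55))  # h2a 0.3, h2d 0.15
#' @export
setMethod("heritability", "VarianceComponents", function(x) {
  sp <- x@sigmaA + x@sigmaD + x@sigmaE
  if (sp <= 0) stop("all variance components are zero")
  new("HeritabilityEstimates", h2a = x@sigmaA / sp, h2d = x@sigmaD / sp,
      H2 = (x@sigmaA + x@sigmaD) / sp, sigmaP = sp)
})

setMethod("show", "HeritabilityEstimates", function(object) {
  cat("Heritabilities: h2a =", signif(object@h2a, 4),
      " h2d =", signif(object@h2d, 4),
      " H2 =", signif(object@H2, 4),
      " (sigmaP =", signif(object@sigmaP, 6), ")\n")
})

## ---------------------------------------------------------------------------
## EM steps (Henderson-Harville type, inverse-free in G and D)
## ---------------------------------------------------------------------------

## One EM update in the SNP-effect parameterization, written in CE
## quantities: sigma_i <- sigma_i + (sigma_i^2 / m) [y'P V_i P y - tr(P V_i)]
## for the additive and dominance components (m = number of SNP effects) and
## sigma_e <- sigma_e + (sigma_e^2 / n) [y'PPy - tr(P)]. Components at zero
## stay at zero (multiplicative update); negative values are clamped to the
## boundary.
.emFromCE <- function(pre, sol, vc) {
  u <- sol$u
  m <- pre$m
  n <- pre$n
  sa <- vc@sigmaA + (vc@sigmaA^2 / m) * (sum(u * (pre$Ka %*% u)) - sol$trPKa)
  sd <- vc@sigmaD + (vc@sigmaD^2 / m) * (sum(u * (pre$Kd %*% u)) - sol$trPKd)
  se <- vc@sigmaE + (vc@sigmaE^2 / n) * (sum(u * u) - sol$trP)
  varianceComponents(max(sa, 0), max(sd, 0), max(se, .Machine$double.eps))
}

## The same update written in MME quantities:
##   sigma_a <- (alpha'alpha + sigma_e tr(C^aa)) / m
##   sigma_e <- (e'e + sigma_e [r - lamA tr(C^aa) - lamD tr(C^dd)]) / n
## with r the rank of the full MME coefficient matrix (rank(X) + 2m for the
## active blocks).
.emFromQM <- function(pre, sol, vc) {
  m <- pre$m
  n <- pre$n
  se <- vc@sigmaE
  sa <- if (sol$act["a"]) (sum(sol$alphaHat^2) + se * sol$trCaa) / m else 0
  sd <- if (sol$act["d"]) (sum(sol$deltaHat^2) + se * sol$trCdd) / m else 0
  rr <- pre$rX + sol$Mact
  seNew <- (sum(sol$eHat^2) + se * (rr -
            (if (sol$act["a"]) sol$lamA * sol$trCaa else 0) -
            (if (sol$act["d"]) sol$lamD * sol$trCdd else 0))) / n
  varianceComponents(max(sa, 0), max(sd, 0), max(seNew, .Machine$double.eps))
}

#' One EM-REML update, conditional-expectation form
#'
#' A single Henderson-Harville EM update of the three variance components
#' computed through V and P (no relationship-matrix inverses). At a REML
#' stationary point the update is a fixed point.
#'
#' @inheritParams gblupCE
#' @return Updated [VarianceComponents-class].
#' @export
emStepCE <- function(design, pair, vc) {
  pre <- .cePrecompute(design, pair)
  .emFromCE(pre, .ceSolve(pre, vc), vc)
}

#' One EM-REML update, mixed-model-equation form
#'
#' The same update as [emStepCE()] computed from the absorbed SNP-effect
#' equations: `alphaHat' alphaHat`, `deltaHat' deltaHat`, the traces of the
#' inverse coefficient-matrix blocks, and the residual update through the
#' rank of the full coefficient matrix. Identical to the CE form to machine
#' precision.
#'
#' @inheritParams gblupCE
#' @return Updated [VarianceComponents-class].
#' @export
emStepQM <- function(design, pair, vc) {
  pre <- .qmPrecompute(design, pair)
  .emFromQM(pre, .qmSolve(pre, vc), vc)
}

## ---------------------------------------------------------------------------
## AI-REML engine pieces
## ---------------------------------------------------------------------------

## u = Py, v_i = V_i u and P v_i for the active components; scores
## -1/2 [tr(P V_i) - u'V_i u] and average-information entries 1/2 v_i' P v_j.
.aiQuantities <- function(pre, sol, vc, engine) {
  u <- sol$u
  if (engine == "ce") {
    va <- drop(pre$Ka %*% u)
    vd <- drop(pre$Kd %*% u)
    applyP <- function(v) drop(sol$P %*% v)
    trPKa <- sol$trPKa
    trPKd <- sol$trPKd
  } else {
    va <- drop(pre$Wa %*% crossprod(pre$Wa, u))
    vd <- drop(pre$Wd %*% crossprod(pre$Wd, u))
    applyP <- function(v) .qmApplyP(pre, sol, vc, v)
    trPKa <- .qmTrPK(pre, sol, vc, "a")
    trPKd <- .qmTrPK(pre, sol, vc, "d")
  }
  vlist <- list(a = va, d = vd, e = u)
  pv <- lapply(vlist, applyP)
  score <- c(a = -0.5 * (trPKa - sum(u * va)),
             d = -0.5 * (trPKd - sum(u * vd)),
             e = -0.5 * (sol$trP - sum(u * u)))
  AI <- matrix(0, 3, 3, dimnames = list(c("a", "d", "e"), c("a", "d", "e")))
  for (i in 1:3) for (j in i:3) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(vlist[[i]] * pv[[j]])
  }
  list(score = score, AI = AI)
}

.solveEngine <- function(pre, vc, engine) {
  if (engine == "ce") .ceSolve(pre, vc) else .qmSolve(pre, vc)
}

.emEngine <- function(pre, sol, vc, engine) {
  if (engine == "ce") .emFromCE(pre, sol, vc) else .emFromQM(pre, sol, vc)
}

## ---------------------------------------------------------------------------
## GREML driver
## ---------------------------------------------------------------------------

#' GREML estimation of additive, dominance and residual variances
#'
#' Restricted maximum likelihood via the inverse-free EM algorithm, the
#' average-information (AI) algorithm, or the default hybrid (AI steps with
#' an EM fallback whenever an AI proposal leaves the parameter space or
#' decreases the restricted likelihood). Either the conditional-expectation
#' or the mixed-model-equation engine does the linear algebra; the two are
#' mathematically identical, so `formulation = "auto"` simply picks the
#' cheaper one (CE if q < 2m, else QM).
#'
#' Components that fall below `boundary * sigmaP` are clamped to zero and
#' treated as boundary estimates. Convergence is declared when the largest
#' component change relative to the current phenotypic variance drops below
#' `tol`.
#'
#' @inheritParams gblupCE
#' @param algorithm "hybrid" (default), "em" or "ai" ("ai" is the hybrid with
#'   the same EM safeguard; pure Newton steps without a safeguard are not
#'   offered).
#' @param formulation "auto", "ce" or "qm".
#' @param init optional [VarianceComponents-class] starting values; default
#'   splits the phenotypic variance evenly across the three components.
#' @param maxIter maximum number of iterations (default 1000).
#' @param tol convergence tolerance on the relative component change
#'   (default 1e-8).
#' @param boundary components below `boundary * sigmaP` are set to zero
#'   (default 1e-8).
#' @param verbose print per-iteration progress.
#' @return A [REMLFit-class].
#' @export
greml <- function(design, pair, algorithm = c("hybrid", "em", "ai"),
                  formulation = c("auto", "ce", "qm"), init = NULL,
                  maxIter = 1000, tol = 1e-8, boundary = 1e-8,
                  verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  formulation <- match.arg(formulation)
  stopifnot(is(design, "DesignSet"), is(pair, "RelationshipPair"))
  if (formulation == "auto")
    formulation <- chooseFormulation(nInd(design), nSnp(design))
  engine <- formulation
  pre <- if (engine == "ce") .cePrecompute(design, pair)
         else .qmPrecompute(design, pair)
  vy <- stats::var(design@y)
  if (is.null(init)) init <- varianceComponents(vy / 3, vy / 3, vy / 3)
  stopifnot(is(init, "VarianceComponents"))
  vc <- init
  useAI <- algorithm %in% c("hybrid", "ai")
  sol <- .solveEngine(pre, vc, engine)
  trace <- vector("list", maxIter)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    step <- "em"
    vcNew <- NULL
    if (useAI) {
      aiq <- .aiQuantities(pre, sol, vc, engine)
      v <- .vcVector(vc)
      sp <- sum(v)
      ## a component parked at zero re-enters when its score is positive
      ## (the restricted likelihood would increase off the boundary)
      reopen <- v[1:2] == 0 & aiq$score[c("a", "d")] > 0
      if (any(reopen)) {
        v[1:2][reopen] <- 1e-6 * sp
        vc <- varianceComponents(v[1], v[2], v[3])
        sol <- .solveEngine(pre, vc, engine)
        aiq <- .aiQuantities(pre, sol, vc, engine)
      }
      cand <- .aiPropose(aiq, v)
      if (!is.null(cand)) {
        ## accept the Newton proposal (possibly clamped to the boundary by
        ## .aiPropose) if it does not decrease the likelihood; otherwise
        ## step-halve towards the current point before giving up on AI
        for (tfrac in c(1, 0.5, 0.25, 0.1)) {
          trial <- v + tfrac * (cand - v)
          if (any(trial[1:2] < 0) || trial[3] <= 0) next
          vcTry <- varianceComponents(trial[1], trial[2], trial[3])
          solTry <- tryCatch(.solveEngine(pre, vcTry, engine),
                             error = function(e) NULL)
          if (!is.null(solTry) && solTry$logLik >= sol$logLik - 1e-10) {
            vcNew <- vcTry
            solNew <- solTry
            step <- "ai"
            break
          }
        }
      }
    }
    if (is.null(vcNew)) {
      vcNew <- .emEngine(pre, sol, vc, engine)
      solNew <- NULL
    }
    ## boundary absorption: tiny components are genuine zeros
    v <- .vcVector(vcNew)
    sp <- sum(v)
    v[1:2][v[1:2] < boundary * sp] <- 0
    vcNew <- varianceComponents(v[1], v[2], v[3])
    deltaRel <- max(abs(.vcVector(vcNew) - .vcVector(vc))) / max(sp, .Machine$double.eps)
    if (is.null(solNew)) solNew <- .solveEngine(pre, vcNew, engine)
    trace[[it]] <- data.frame(iter = it, sigmaA = vcNew@sigmaA,
                              sigmaD = vcNew@sigmaD, sigmaE = vcNew@sigmaE,
                              logLik = solNew$logLik, delta = deltaRel,
                              step = step)
    if (verbose)
      message(sprintf("it %3d [%s] sa=%.6g sd=%.6g se=%.6g ll=%.6f",
                      it, step, vcNew@sigmaA, vcNew@sigmaD, vcNew@sigmaE,
                      solNew$logLik))
    vc <- vcNew
    sol <- solNew
    if (deltaRel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GREML did not converge in ", maxIter, " iterations; ",
            "returning the last iterate")
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  se <- .gremlSE(pre, sol, vc, engine)
  new("REMLFit", vc = vc, heritability = heritability(vc), se = se,
      trace = trace, converged = converged, algorithm = algorithm,
      formulation = formulation)
}

## Active-set Newton proposal from the average-information matrix: solve for
## the free (positive) components; components proposed negative are clamped
## to the boundary and the step re-solved for the remainder. The residual
## variance is never clamped. Returns the proposed component vector or NULL.
.aiPropose <- function(aiq, v) {
  free <- c(v[1] > 0, v[2] > 0, TRUE)
  for (round in 1:3) {
    delta <- tryCatch(
      solve(aiq$AI[free, free, drop = FALSE], aiq$score[free]),
      error = function(e) NULL)
    if (is.null(delta)) return(NULL)
    prop <- v
    prop[!free] <- 0
    prop[free] <- v[free] + delta
    neg <- free & prop < 0
    neg[3] <- FALSE
    if (!any(neg)) return(prop)
    free <- free & !neg
  }
  NULL
}

## Standard errors from the inverse AI matrix at convergence; heritability
## SEs by the delta method. NA for components estimated at the boundary.
.gremlSE <- function(pre, sol, vc, engine) {
  out <- c(sigmaA = NA_real_, sigmaD = NA_real_, sigmaE = NA_real_,
           h2a = NA_real_, h2d = NA_real_, H2 = NA_real_)
  aiq <- tryCatch(.aiQuantities(pre, sol, vc, engine), error = function(e) NULL)
  if (is.null(aiq)) return(out)
  free <- c(vc@sigmaA > 0, vc@sigmaD > 0, TRUE)
  Vfull <- matrix(0, 3, 3)
  covFree <- tryCatch(solve(aiq$AI[free, free, drop = FALSE]),
                      error = function(e) NULL)
  if (is.null(covFree)) return(out)
  Vfull[free, free] <- covFree
  out[1:3] <- ifelse(c(free), sqrt(pmax(diag(Vfull), 0)), NA_real_)
  v <- .vcVector(vc)
  sp <- sum(v)
  ## d h2a / d(sa, sd, se), etc.
  Ja <- c(sp - v[1], -v[1], -v[1]) / sp^2
  Jd <- c(-v[2], sp - v[2], -v[2]) / sp^2
  Jh <- Ja + Jd
  out["h2a"] <- if (free[1]) sqrt(max(drop(Ja %*% Vfull %*% Ja), 0)) else NA_real_
  out["h2d"] <- if (free[2]) sqrt(max(drop(Jd %*% Vfull %*% Jd), 0)) else NA_real_
  out["H2"] <- sqrt(max(drop(Jh %*% Vfull %*% Jh), 0))
  out
}

#' Restricted log-likelihood of a component setting
#'
#' Up to one additive constant shared by both formulations, so values are
#' comparable across CE and QM and across iterations.
#'
#' @inheritParams gblupCE
#' @param formulation "ce" or "qm".
#' @return scalar log-likelihood.
#' @export
remlLogLik <- function(design, pair, vc, formulation = c("ce", "qm")) {
  formulation <- match.arg(formulation)
  pre <- if (formulation == "ce") .cePrecompute(design, pair)
         else .qmPrecompute(design, pair)
  .solveEngine(pre, vc, formulation)$logLik
}

#' @describeIn REMLFit heritability estimates
#' @param x a `REMLFit`
#' @export
setMethod("heritability", "REMLFit", function(x) x@heritability)
#' @describeIn REMLFit additive variance
#' @export
setMethod("sigmaA", "REMLFit", function(x) x@vc@sigmaA)
#' @describeIn REMLFit dominance variance
#' @export
setMethod("sigmaD", "REMLFit", function(x) x@vc@sigmaD)
#' @describeIn REMLFit residual variance
#' @export
setMethod("sigmaE", "REMLFit", function(x) x@vc@sigmaE)

setMethod("show", "REMLFit", function(object) {
  cat("REMLFit (", object@algorithm, ", ", object@formulation, " engine, ",
      nrow(object@trace), " iterations, ",
      if (object@converged) "converged" else "NOT converged", ")\n", sep = "")
  show(object@vc)
  show(object@heritability)
  cat("  SE:", paste(names(object@se), signif(object@se, 3),
                     sep = "=", collapse = "  "), "\n")
})
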
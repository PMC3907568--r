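## Internal mixed-model machinery shared by GBLUP and GREML.
##
## Two engines implement the same model
##   y = X b + Z a + Z d + e,  a ~ N(0, G sa), d ~ N(0, D sd), e ~ N(0, I se)
## CE works with V = Z G Z' sa + Z D Z' sd + I se (n x n); QM works with the
## absorbed mixed model equations on SNP effects (2m x 2m). Neither inverts
## G or D, so both run unchanged when the relationship matrices are singular.

## Moore-Penrose inverse of a symmetric PSD matrix via eigenvalue
## thresholding (relative tolerance), with positive-part log-determinant.
.mpinv <- function(M, tol = 1e-10) {
  if (nrow(M) == 0L)
    return(list(inv = M, rank = 0L, logpdet = 0))
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  thr <- tol * max(e$values, 0)
  pos <- e$values > max(thr, .Machine$double.eps)
  inv <- if (any(pos)) {
    Up <- e$vectors[, pos, drop = FALSE]
    Up %*% (t(Up) / e$values[pos])
  } else matrix(0, nrow(M), ncol(M))
  list(inv = inv, rank = sum(pos), logpdet = sum(log(e$values[pos])))
}

.activeComponents <- function(vc) c(a = vc@sigmaA > 0, d = vc@sigmaD > 0)

## ---------------------------------------------------------------------------
## CE engine
## ---------------------------------------------------------------------------

.cePrecompute <- function(design, pair) {
  stopifnot(nInd(design) == nInd(pair))
  Z <- design@Z
  list(
    y = design@y, X = design@X, Z = Z,
    G = pair@G, D = pair@D,
    Ka = Z %*% tcrossprod(pair@G, Z),
    Kd = Z %*% tcrossprod(pair@D, Z),
    n = length(design@y), q = nInd(design), m = nSnp(design)
  )
}

## Factor V for the current components and form P, u = P y and the
## restricted log-likelihood -0.5 [log|V| + log|X'V-X|+ + y'Py].
.ceSolve <- function(pre, vc) {
  n <- pre$n
  V <- vc@sigmaA * pre$Ka + vc@sigmaD * pre$Kd + diag(vc@sigmaE, n)
  cholV <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite (is the residual variance positive?)"))
  Vi <- chol2inv(cholV)
  ViX <- Vi %*% pre$X
  XtViX <- crossprod(pre$X, ViX)
  Bx <- .mpinv(XtViX)
  Viy <- Vi %*% pre$y
  bHat <- drop(Bx$inv %*% crossprod(pre$X, Viy))
  u <- drop(Viy - ViX %*% (Bx$inv %*% crossprod(pre$X, Viy)))
  P <- Vi - ViX %*% tcrossprod(Bx$inv, ViX)
  P <- (P + t(P)) / 2
  logdetV <- 2 * sum(log(diag(cholV)))
  yPy <- sum(pre$y * u)
  list(
    V = V, cholV = cholV, P = P, u = u, bHat = bHat,
    rX = Bx$rank,
    logLik = -0.5 * (logdetV + Bx$logpdet + yPy),
    yPy = yPy,
    trP = sum(diag(P)),
    trPKa = sum(P * pre$Ka),
    trPKd = sum(P * pre$Kd)
  )
}

## ---------------------------------------------------------------------------
## QM engine
## ---------------------------------------------------------------------------

## Data-dependent pieces that do not change across REML iterations.
## S = I - X (X'X)+ X' is the absorption projector; all products with S are
## stored so S itself is never formed.
.qmPrecompute <- function(design, pair) {
  stopifnot(nInd(design) == nInd(pair))
  tc <- normalizedCoding(pair, design)
  X <- design@X
  Z <- design@Z
  Wa <- Z %*% tc$Talpha
  Wd <- Z %*% tc$Tdelta
  XtX <- crossprod(X)
  Bx <- .mpinv(XtX)
  projS <- function(v) v - X %*% (Bx$inv %*% crossprod(X, v))
  SWa <- projS(Wa)
  SWd <- projS(Wd)
  Sy <- drop(projS(design@y))
  list(
    y = design@y, X = design@X, Z = Z,
    Ta = tc$Talpha, Td = tc$Tdelta,
    Gdiag = diag(pair@G), Ddiag = diag(pair@D),
    Wa = Wa, Wd = Wd, SWa = SWa, SWd = SWd, Sy = Sy,
    Maa = crossprod(Wa, SWa), Mad = crossprod(Wa, SWd), Mdd = crossprod(Wd, SWd),
    ra = crossprod(Wa, Sy), rd = crossprod(Wd, Sy),
    ySy = sum(design@y * Sy),
    XtXinv = Bx$inv, rX = Bx$rank, logpdetXtX = Bx$logpdet,
    n = length(design@y), q = nInd(design), m = nSnp(design)
  )
}

## Assemble and solve the absorbed MME [W'SW + Lambda] theta = W'Sy for the
## active variance components; return solutions, inverse-block traces, the
## residual e = y - X bhat - W theta (= se * P y), and the restricted
## log-likelihood matching the CE engine's constant.
.qmSolve <- function(pre, vc) {
  act <- .activeComponents(vc)
  m <- pre$m
  se <- vc@sigmaE
  if (se <= 0) stop("residual variance must be positive")
  lamA <- if (act["a"]) se / vc@sigmaA else Inf
  lamD <- if (act["d"]) se / vc@sigmaD else Inf
  blocks <- c(if (act["a"]) "a", if (act["d"]) "d")
  Mact <- m * length(blocks)
  if (Mact > 0) {
    C <- matrix(0, Mact, Mact)
    rhs <- numeric(Mact)
    ia <- if (act["a"]) seq_len(m) else integer()
    id <- if (act["d"]) (if (act["a"]) m else 0L) + seq_len(m) else integer()
    if (act["a"]) {
      C[ia, ia] <- pre$Maa + diag(lamA, m)
      rhs[ia] <- pre$ra
    }
    if (act["d"]) {
      C[id, id] <- pre$Mdd + diag(lamD, m)
      rhs[id] <- pre$rd
    }
    if (act["a"] && act["d"]) {
      C[ia, id] <- pre$Mad
      C[id, ia] <- t(pre$Mad)
    }
    cholC <- chol(C)
    theta <- drop(backsolve(cholC, backsolve(cholC, rhs, transpose = TRUE)))
    Ci <- chol2inv(cholC)
    logdetC <- 2 * sum(log(diag(cholC)))
  } else {
    theta <- numeric(0)
    Ci <- matrix(0, 0, 0)
    cholC <- NULL
    logdetC <- 0
    ia <- id <- integer()
  }
  alphaHat <- if (act["a"]) theta[ia] else numeric(m) * 0
  deltaHat <- if (act["d"]) theta[id] else numeric(m) * 0
  if (!act["a"]) alphaHat <- numeric(m)
  if (!act["d"]) deltaHat <- numeric(m)
  fitted <- numeric(pre$n)
  if (act["a"]) fitted <- fitted + drop(pre$SWa %*% alphaHat)
  if (act["d"]) fitted <- fitted + drop(pre$SWd %*% deltaHat)
  eHat <- pre$Sy - fitted                       # = se * P y
  bHat <- drop(pre$XtXinv %*% crossprod(pre$X, pre$y -
           (if (act["a"]) drop(pre$Wa %*% alphaHat) else 0) -
           (if (act["d"]) drop(pre$Wd %*% deltaHat) else 0)))
  trCaa <- if (act["a"]) sum(diag(Ci)[ia]) else NA_real_
  trCdd <- if (act["d"]) sum(diag(Ci)[id]) else NA_real_
  yPy <- (pre$ySy - (if (Mact > 0) sum(rhs * theta) else 0)) / se
  ## restricted log-likelihood, same additive constant as the CE engine:
  ## -2 ll = (n - rX - Mact) log se + m log sa + m log sd + log|C|
  ##         + log|X'X|+ + y'Py
  ll <- -0.5 * ((pre$n - pre$rX - Mact) * log(se) +
                (if (act["a"]) m * log(vc@sigmaA) else 0) +
                (if (act["d"]) m * log(vc@sigmaD) else 0) +
                logdetC + pre$logpdetXtX + yPy)
  ## trace identities (se * tr(P) and tr(P V_i) without forming P)
  trP <- (pre$n - pre$rX - Mact +
          (if (act["a"]) lamA * trCaa else 0) +
          (if (act["d"]) lamD * trCdd else 0)) / se
  list(
    act = act, m = m, Mact = Mact, ia = ia, id = id,
    lamA = lamA, lamD = lamD,
    cholC = cholC, Ci = Ci, theta = theta,
    alphaHat = alphaHat, deltaHat = deltaHat,
    eHat = eHat, u = eHat / se, bHat = bHat,
    trCaa = trCaa, trCdd = trCdd, trP = trP,
    yPy = yPy, logLik = ll, r = pre$rX + Mact
  )
}

## Apply P to a vector using the absorbed system:
## P v = [S v - SW C^{-1} W'S v] / se
.qmApplyP <- function(pre, sol, vc, v) {
  Sv <- drop(v - pre$X %*% (pre$XtXinv %*% crossprod(pre$X, v)))
  if (sol$Mact > 0) {
    wv <- c(if (sol$act["a"]) drop(crossprod(pre$SWa, v)),
            if (sol$act["d"]) drop(crossprod(pre$SWd, v)))
    x <- backsolve(sol$cholC, backsolve(sol$cholC, wv, transpose = TRUE))
    if (sol$act["a"]) Sv <- Sv - drop(pre$SWa %*% x[sol$ia])
    if (sol$act["d"]) Sv <- Sv - drop(pre$SWd %*% x[sol$id])
  }
  Sv / vc@sigmaE
}

## tr(P Z G Z') and tr(P Z D Z') in the QM engine. For an active component
## the inverse-block identity is used; for an inactive one the explicit
## projected-trace formula (still inverse-free in G/D).
.qmTrPK <- function(pre, sol, vc, which = c("a", "d")) {
  which <- match.arg(which)
  s2 <- if (which == "a") vc@sigmaA else vc@sigmaD
  if (s2 > 0) {
    trC <- if (which == "a") sol$trCaa else sol$trCdd
    return((sol$m * s2 - vc@sigmaE * trC) / s2^2)
  }
  SW <- if (which == "a") pre$SWa else pre$SWd
  M0 <- if (which == "a") pre$Maa else pre$Mdd
  tot <- sum(diag(M0))
  if (sol$Mact > 0) {
    Wm <- rbind(
      if (sol$act["a"]) crossprod(pre$SWa, SW),
      if (sol$act["d"]) crossprod(pre$SWd, SW))
    x <- backsolve(sol$cholC, backsolve(sol$cholC, Wm, transpose = TRUE))
    tot <- tot - sum(Wm * x)
  }
  tot / vc@sigmaE
}
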
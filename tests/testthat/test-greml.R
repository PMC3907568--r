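test_that("heritabilities follow from the variance-component ratios", {
  h <- heritability(varianceComponents(1, 0, 1))
  expect_equal(h@h2a, 0.5)
  expect_equal(h@h2d, 0)
  expect_equal(h@H2, 0.5)
  h2 <- heritability(varianceComponents(0.3, 0.15, 0.55))
  expect_equal(h2@H2, 0.45)
  expect_equal(h2@sigmaP, 1)
  expect_error(heritability(varianceComponents(0, 0, 0)), "zero")
})

test_that("EM updates agree between the CE and QM forms", {
  set.seed(201)
  for (shape in list(c(8, 16), c(14, 14), c(26, 9))) {
    inst <- randomInstance(shape[1], shape[2],
                           definition = sample(c("I", "II", "III"), 1))
    e1 <- emStepCE(inst$ds, inst$pair, inst$vc)
    e2 <- emStepQM(inst$ds, inst$pair, inst$vc)
    expect_lt(relErr(sigmaA(e1), sigmaA(e2)), 1e-8)
    expect_lt(relErr(sigmaD(e1), sigmaD(e2)), 1e-8)
    expect_lt(relErr(sigmaE(e1), sigmaE(e2)), 1e-8)
    ## and so does the restricted likelihood, including its constant
    expect_lt(abs(remlLogLik(inst$ds, inst$pair, inst$vc, "ce") -
                  remlLogLik(inst$ds, inst$pair, inst$vc, "qm")), 1e-8)
  }
})

test_that("a component started at zero stays at zero under EM", {
  set.seed(211)
  inst <- randomInstance(10, 15)
  vc0 <- varianceComponents(0, 0.5, 1)
  e <- emStepCE(inst$ds, inst$pair, vc0)
  expect_equal(sigmaA(e), 0)
  e2 <- emStepQM(inst$ds, inst$pair, vc0)
  expect_equal(sigmaA(e2), 0)
})

test_that("the converged solution is an EM fixed point", {
  set.seed(221)
  inst <- simInstance(120, 80, 0.35, 0.2, seed = 221)
  fit <- greml(inst$ds, inst$pair, algorithm = "hybrid", tol = 1e-11)
  expect_true(fit@converged)
  vcStar <- fit@vc
  e <- emStepCE(inst$ds, inst$pair, vcStar)
  expect_lt(relErr(c(sigmaA(e), sigmaD(e), sigmaE(e)),
                   c(sigmaA(vcStar), sigmaD(vcStar), sigmaE(vcStar))), 1e-6)
  ## pure EM heads to the same stationary point
  fitEM <- suppressWarnings(
    greml(inst$ds, inst$pair, algorithm = "em", tol = 1e-8, maxIter = 3000))
  expect_lt(relErr(c(sigmaA(fitEM), sigmaD(fitEM), sigmaE(fitEM)),
                   c(sigmaA(vcStar), sigmaD(vcStar), sigmaE(vcStar))), 1e-3)
})

test_that("the restricted likelihood never decreases along EM iterations", {
  set.seed(231)
  inst <- simInstance(80, 120, 0.3, 0.2, seed = 231)
  fit <- suppressWarnings(
    greml(inst$ds, inst$pair, algorithm = "em", maxIter = 60, tol = 0))
  expect_true(all(diff(fit@trace$logLik) > -1e-8))
  ## also through the QM engine (q > m shape)
  inst2 <- simInstance(90, 30, 0.3, 0.2, seed = 232)
  fit2 <- suppressWarnings(
    greml(inst2$ds, inst2$pair, algorithm = "em", maxIter = 60, tol = 0))
  expect_equal(fit2@formulation, "qm")
  expect_true(all(diff(fit2@trace$logLik) > -1e-8))
})

test_that("a single-SNP EM update matches a scalar hand computation", {
  set.seed(241)
  counts <- cbind(stats::rbinom(12, 2, 0.4))
  gm <- GenotypeMatrix(counts)
  ph <- data.frame(id = individualIds(gm), y = stats::rnorm(12))
  ds <- buildDesign(ph, gm)
  pair <- genomicRelationship(ds, "II")
  vc <- varianceComponents(0.7, 0, 0.9)
  ## scalar absorbed system for the additive SNP effect
  n <- 12
  tstar <- drop(normalizedCoding(pair, ds)$Talpha)
  S <- diag(n) - matrix(1 / n, n, n)
  w <- drop(ds@Z %*% tstar)
  lam <- 0.9 / 0.7
  Cs <- sum(w * (S %*% w)) + lam
  alpha <- sum(w * (S %*% ph$y)) / Cs
  ehat <- drop(S %*% ph$y) - drop(S %*% w) * alpha
  saNew <- (alpha^2 + 0.9 / Cs) / 1
  seNew <- (sum(ehat^2) + 0.9 * (1 + 1 - lam / Cs)) / n
  e <- emStepQM(ds, pair, vc)
  expect_equal(sigmaA(e), saNew)
  expect_equal(sigmaE(e), seNew)
  expect_equal(sigmaD(e), 0)
})

test_that("tr of the inverse additive block decreases as the ridge grows", {
  set.seed(251)
  inst <- randomInstance(20, 6)
  trs <- sapply(c(2, 1, 0.5, 0.25), function(sa) {
    mme <- assembleMME(inst$ds, inst$pair,
                       varianceComponents(sa, inst$vc@sigmaD, inst$vc@sigmaE))
    sum(diag(solve(mme$C))[1:6])
  })
  expect_true(all(diff(trs) < 0))   # lambda increases along the sequence
})

test_that("AI-REML converges to the EM stationary equations", {
  set.seed(261)
  inst <- simInstance(100, 70, 0.3, 0.25, seed = 261)
  fit <- greml(inst$ds, inst$pair, algorithm = "ai", tol = 1e-9)
  expect_true(fit@converged)
  e <- emStepCE(inst$ds, inst$pair, fit@vc)
  expect_lt(relErr(c(sigmaA(e), sigmaD(e), sigmaE(e)),
                   c(sigmaA(fit), sigmaD(fit), sigmaE(fit))), 1e-6)
  expect_true(all(fit@trace$sigmaA >= 0))
  expect_lte(nrow(fit@trace), 1000)
  ## standard errors are finite for interior estimates
  expect_true(all(is.finite(fit@se[c("sigmaA", "sigmaD", "sigmaE")])))
})

test_that("dominance-only data drive the additive component to the boundary", {
  set.seed(271)
  inst <- simInstance(400, 150, 0, 0.35, seed = 271)
  fit <- greml(inst$ds, inst$pair, tol = 1e-7)
  expect_lt(heritability(fit)@h2a, 0.02)
  expect_gt(heritability(fit)@h2d, 0.2)
})

test_that("unnormalized codings shrink variance estimates as markers grow", {
  ## the pathology the default normalization prevents: with raw T T' Gram
  ## matrices the estimated genetic variances scale like 1/m
  set.seed(281)
  fitAt <- function(m, definition) {
    inst <- simInstance(100, m, 0.4, 0, seed = 280 + m, definition = definition)
    fit <- greml(inst$ds, inst$pair, tol = 1e-7)
    sigmaA(fit)
  }
  rawSmall <- fitAt(50, "unnormalized")
  rawBig <- fitAt(400, "unnormalized")
  expect_lt(rawBig, rawSmall / 3)
  normSmall <- fitAt(50, "II")
  normBig <- fitAt(400, "II")
  expect_gt(normBig, normSmall / 3)   # stable order of magnitude
})

test_that("the greml driver honours the formulation rule and records a trace", {
  set.seed(291)
  inst <- simInstance(120, 30, 0.3, 0.1, seed = 291)
  fit <- greml(inst$ds, inst$pair)
  expect_equal(fit@formulation, "qm")   # q = 120 >= 2m = 60
  expect_true(all(c("iter", "sigmaA", "sigmaD", "sigmaE", "logLik", "delta",
                    "step") %in% names(fit@trace)))
  fitCE <- greml(inst$ds, inst$pair, formulation = "ce", tol = 1e-8)
  expect_lt(relErr(c(sigmaA(fit), sigmaD(fit), sigmaE(fit)),
                   c(sigmaA(fitCE), sigmaD(fitCE), sigmaE(fitCE))), 1e-5)
})
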
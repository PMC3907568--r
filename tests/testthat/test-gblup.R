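test_that("buildV assembles the phenotypic covariance matrix", {
  ## hand instance: Z = I2, G = [[1, .5], [.5, 1]], D = I2, vc = (2, 1, 3)
  ## V = 2 G + D + 3 I = [[6, 1], [1, 6]]
  pair <- new("RelationshipPair", G = matrix(c(1, .5, .5, 1), 2),
              D = diag(2), definition = "II", kAlpha = 1, kDelta = 1,
              scaleAlpha = c(1, 1), scaleDelta = c(1, 1),
              individualIds = c("a", "b"))
  v <- buildV(diag(2), pair, varianceComponents(2, 1, 3))
  expect_equal(v$V, matrix(c(6, 1, 1, 6), 2))
  expect_equal(v$V, t(v$V))
  ## null genetic variances collapse V to I sigmaE
  v0 <- buildV(diag(2), pair, varianceComponents(0, 0, 3))
  expect_equal(v0$V, diag(3, 2))
  ## sigmaE = 0 with singular genomic part is not factorizable
  pairSing <- new("RelationshipPair", G = matrix(1, 2, 2), D = matrix(1, 2, 2),
                  definition = "II", kAlpha = 1, kDelta = 1,
                  scaleAlpha = c(1, 1), scaleDelta = c(1, 1),
                  individualIds = c("a", "b"))
  expect_error(buildV(diag(2), pairSing, varianceComponents(1, 1, 0)),
               "positive definite")
})

test_that("null variance components zero the matching predictions", {
  set.seed(101)
  inst <- randomInstance(12, 20)
  ps <- suppressWarnings(
    gblupCE(inst$ds, inst$pair, varianceComponents(0, 0.4, 0.8)))
  expect_equal(ps@aHat, rep(0, 12))
  expect_equal(ps@relA, rep(0, 12))
  expect_false(all(ps@dHat == 0))
  expect_equal(ps@gHat, ps@dHat)
})

test_that("the BLUE of fixed effects matches an independent dense GLS solve", {
  skip_if_not_installed("MASS")
  set.seed(111)
  inst <- randomInstance(15, 30, repeatedRecords = TRUE)
  ps <- gblupCE(inst$ds, inst$pair, inst$vc, reliability = FALSE)
  V <- buildV(inst$ds@Z, inst$pair, inst$vc)$V
  X <- inst$ds@X
  Vi <- solve(V)
  bOracle <- drop(MASS::ginv(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% inst$ds@y)
  expect_lt(relErr(ps@bHat, bOracle), 1e-8)
})

test_that("CE and QM formulations are identical across shapes, definitions and degeneracies", {
  set.seed(121)
  cases <- expand.grid(shape = c("q<m", "q=m", "q>m"),
                       def = c("I", "II", "III"),
                       twist = c("plain", "dup", "rankX"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    dims <- switch(cases$shape[k], "q<m" = c(8, 18), "q=m" = c(12, 12),
                   "q>m" = c(24, 9))
    inst <- randomInstance(dims[1], dims[2], definition = cases$def[k],
                           dupRows = cases$twist[k] == "dup",
                           rankDefX = cases$twist[k] == "rankX")
    a <- gblupCE(inst$ds, inst$pair, inst$vc)
    b <- gblupQM(inst$ds, inst$pair, inst$vc)
    expect_lt(relErr(a@bHat, b@bHat), 1e-8)
    expect_lt(relErr(a@aHat, b@aHat), 1e-8)
    expect_lt(relErr(a@dHat, b@dHat), 1e-8)
    expect_lt(relErr(a@gHat, b@gHat), 1e-8)
    expect_lt(relErr(a@relA, b@relA), 1e-8)
    expect_lt(relErr(a@relD, b@relD), 1e-8)
    expect_lt(relErr(a@relG, b@relG), 1e-8)
  }
})

test_that("gblup front end routes by the q < 2m rule", {
  set.seed(131)
  inst <- randomInstance(20, 6)   # q >= 2m: QM
  expect_equal(gblup(inst$ds, inst$pair, inst$vc)@formulation, "qm")
  inst2 <- randomInstance(6, 20)
  expect_equal(gblup(inst2$ds, inst2$pair, inst2$vc)@formulation, "ce")
})

test_that("reliabilities stay in [0, 1] and approach 1 as genetic variance dominates", {
  set.seed(141)
  ## enough individuals that fixed-effect uncertainty does not cap the limit
  inst <- randomInstance(100, 150, definition = "III")
  rels <- sapply(c(0.5, 5, 50, 5000), function(s) {
    ps <- gblupCE(inst$ds, inst$pair, varianceComponents(s, 0.2, 1))
    expect_true(all(ps@relA >= 0 & ps@relA <= 1))
    mean(ps@relA)
  })
  expect_true(all(diff(rels) > 0))
  expect_gt(rels[4], 0.95)
  ## no-information limit: residual variance dominating drives them to 0
  psNoise <- gblupCE(inst$ds, inst$pair, varianceComponents(1e-6, 1e-6, 1))
  expect_lt(mean(psNoise@relG), 0.01)
})

test_that("the absorption projector annihilates X and is idempotent", {
  set.seed(151)
  inst <- randomInstance(14, 10, rankDefX = TRUE)
  mme <- assembleMME(inst$ds, inst$pair, inst$vc)
  expect_lt(max(abs(mme$S %*% inst$ds@X)), 1e-10)
  expect_lt(max(abs(mme$S %*% mme$S - mme$S)), 1e-10)
  expect_equal(mme$C, t(mme$C))
  expect_equal(mme$rankX, 2)                      # herd factor, duplicated col
  expect_equal(mme$r, mme$rankX + nrow(mme$C))
})

test_that("a one-SNP system matches a scalar hand solve", {
  ## m = 1, q = 2, intercept-only; dominance disabled. After absorbing the
  ## intercept the MME is scalar: (w'Sw + lam) alpha = w'Sy.
  counts <- rbind(a = 2L, b = 0L)
  gm <- GenotypeMatrix(counts)
  ph <- data.frame(id = c("a", "b"), y = c(3, 1))
  ds <- buildDesign(ph, gm)
  pair <- genomicRelationship(ds, "II")
  vc <- varianceComponents(0.8, 0, 0.5)
  tc <- normalizedCoding(pair, ds)
  w <- drop(ds@Z %*% tc$Talpha)
  S <- diag(2) - matrix(0.5, 2, 2)
  lam <- 0.5 / 0.8
  alphaHand <- sum(w * (S %*% ph$y)) / (sum(w * (S %*% w)) + lam)
  ps <- suppressWarnings(gblupQM(ds, pair, vc))
  expect_equal(ps@aHat, unname(drop(tc$Talpha)) * alphaHand)
  expect_lt(relErr(ps@aHat, suppressWarnings(gblupCE(ds, pair, vc))@aHat), 1e-10)
})

test_that("permuting SNP order leaves QM predictions unchanged", {
  set.seed(161)
  inst <- randomInstance(18, 8)
  perm <- sample(nSnp(inst$gm))
  gmP <- inst$gm[, perm]
  ph <- data.frame(id = individualIds(inst$gm), y = inst$ds@y[seq_len(18)])
  dsP <- buildDesign(ph, gmP, fixed = ~1)
  ds0 <- buildDesign(ph, inst$gm, fixed = ~1)
  pairP <- genomicRelationship(dsP, "II")
  pair0 <- genomicRelationship(ds0, "II")
  a <- gblupQM(ds0, pair0, inst$vc)
  b <- gblupQM(dsP, pairP, inst$vc)
  expect_lt(relErr(a@aHat, b@aHat), 1e-10)
  expect_lt(relErr(a@relG, b@relG), 1e-10)
})

test_that("validation individuals are predicted through relationship blocks", {
  set.seed(171)
  ## duplicate-genotype identity: under Definition III a validation individual
  ## with a training individual's genotypes gets that individual's GBLUP
  counts <- hweCounts(20, 40)
  counts <- rbind(counts, counts[1, ])
  rownames(counts) <- c(sprintf("t%02d", 1:20), "vdup")
  gm <- suppressMessages(GenotypeMatrix(counts))
  ph <- data.frame(id = sprintf("t%02d", 1:20), y = rnorm(20))
  ds <- buildDesign(ph, gm)
  pair <- genomicRelationship(ds, "III")
  for (fo in c("ce", "qm")) {
    ps <- gblup(ds, pair, varianceComponents(0.6, 0.3, 0.7), formulation = fo)
    expect_false(ps@observed[21])
    expect_equal(ps@aHat[21], ps@aHat[1])
    expect_equal(ps@relG[21], ps@relG[1])
  }
  ## CE and QM agree on the validation block too
  a <- gblupCE(ds, pair, varianceComponents(0.6, 0.3, 0.7))
  b <- gblupQM(ds, pair, varianceComponents(0.6, 0.3, 0.7))
  expect_lt(relErr(a@aHat[!a@observed], b@aHat[!b@observed]), 1e-8)
  expect_error(validationSet(gblupCE(buildDesign(
    data.frame(id = sprintf("t%02d", 1:20), y = ph$y), gm[1:20, ]),
    genomicRelationship(gm[1:20, ], "III"),
    varianceComponents(0.6, 0.3, 0.7))), "empty validation")
})

test_that("an unrelated validation individual gets a near-null prediction", {
  ## manufactured pair: validation individual orthogonal to everyone
  set.seed(181)
  q <- 6
  G <- diag(q); G[1:5, 1:5] <- 0.3; diag(G) <- 1
  pair <- new("RelationshipPair", G = G, D = diag(q), definition = "III",
              kAlpha = NA_real_, kDelta = NA_real_,
              scaleAlpha = rep(1, q), scaleDelta = rep(1, q),
              individualIds = letters[1:q])
  Z <- cbind(diag(5), 0)
  ds <- new("DesignSet", y = rnorm(5), X = cbind(rep(1, 5)), Z = Z,
            Talpha = matrix(0, q, 1), Tdelta = matrix(0, q, 1),
            individualIds = letters[1:q], freqs = 0.5)
  ps <- gblupCE(ds, pair, varianceComponents(1, 0.5, 1), reliability = FALSE)
  expect_equal(ps@aHat[6], 0)
  expect_equal(ps@gHat[6], 0)
})

test_that("GBLUP is invariant to Definition I vs II when components are rescaled", {
  set.seed(191)
  inst <- randomInstance(12, 30)
  p1 <- genomicRelationship(inst$ds, "I")
  p2 <- genomicRelationship(inst$ds, "II")
  ## G_I = G_II * (kII/kI): scaling the components by kI/kII makes the two
  ## models identical, so the normalization has no effect on GBLUP
  sA <- inst$vc@sigmaA; sD <- inst$vc@sigmaD; vc1 <- inst$vc
  f_a <- p1@kAlpha / p2@kAlpha
  f_d <- p1@kDelta / p2@kDelta
  psI <- gblupCE(inst$ds, p1, varianceComponents(sA * f_a, sD * f_d, vc1@sigmaE),
                 reliability = FALSE)
  psII <- gblupCE(inst$ds, p2, varianceComponents(sA, sD, vc1@sigmaE),
                  reliability = FALSE)
  expect_lt(relErr(psI@aHat, psII@aHat), 1e-10)
  expect_lt(relErr(psI@gHat, psII@gHat), 1e-10)
})
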
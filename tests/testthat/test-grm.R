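test_that("Definition I divides by the expected HWE diagonal variance", {
  ## one SNP, p = 0.5 in-sample, counts (2, 0): T_alpha = (1, -1),
  ## k_alpha = 2 * 0.5 * 0.5 = 0.5, so G = [[2, -2], [-2, 2]]
  gm <- GenotypeMatrix(rbind(a = 2, b = 0))
  pair <- genomicRelationship(gm, "I")
  expect_equal(unname(additiveRelationship(pair)),
               matrix(c(2, -2, -2, 2), 2))
  expect_equal(pair@kAlpha, 0.5)
  expect_equal(pair@kDelta, 0.25)
})

test_that("identical genotype rows give off-diagonals equal to the diagonal", {
  set.seed(21)
  inst <- randomInstance(10, 30, dupRows = TRUE)
  for (def in c("I", "II", "III")) {
    pair <- genomicRelationship(inst$ds, def)
    G <- additiveRelationship(pair)
    D <- dominanceRelationship(pair)
    expect_equal(G[1, 2], G[1, 1])
    expect_equal(D[1, 2], D[1, 1])
  }
})

test_that("Definition I diagonals have expectation 1 under HWE (Monte-Carlo)", {
  set.seed(31)
  freqs <- stats::runif(400, 0.1, 0.9)
  counts <- hweCounts(600, 400, freqs)
  gm <- suppressMessages(GenotypeMatrix(counts, freqs = freqs))
  pair <- genomicRelationship(gm, "I")
  ## mean diagonal over 600 HWE individuals, coding at the true frequencies
  expect_equal(mean(diag(additiveRelationship(pair))), 1, tolerance = 0.02)
  expect_equal(mean(diag(dominanceRelationship(pair))), 1, tolerance = 0.05)
})

test_that("Definition II has mean diagonal exactly 1; Definition III unit diagonals", {
  set.seed(41)
  inst <- randomInstance(25, 12)   # q > m: singular matrices welcome
  p2 <- genomicRelationship(inst$ds, "II")
  expect_equal(mean(diag(additiveRelationship(p2))), 1)
  expect_equal(mean(diag(dominanceRelationship(p2))), 1)
  p3 <- genomicRelationship(inst$ds, "III")
  expect_equal(unname(diag(additiveRelationship(p3))), rep(1, 25))
  expect_equal(unname(diag(dominanceRelationship(p3))), rep(1, 25))
  expect_true(all(abs(additiveRelationship(p3)) <= 1 + 1e-12))
  expect_true(all(abs(dominanceRelationship(p3)) <= 1 + 1e-12))
  ## single individual (external frequencies): Definition II is [[1]]
  g1 <- GenotypeMatrix(rbind(a = c(2, 1, 0, 1)), freqs = c(0.5, 0.3, 0.4, 0.6))
  p1 <- genomicRelationship(g1, "II")
  expect_equal(unname(additiveRelationship(p1)), matrix(1))
})

test_that("all definitions yield symmetric positive semidefinite matrices", {
  set.seed(51)
  for (shape in list(c(8, 30), c(20, 20), c(30, 8))) {
    inst <- randomInstance(shape[1], shape[2])
    for (def in c("I", "II", "III")) {
      pair <- genomicRelationship(inst$ds, def)
      for (M in list(additiveRelationship(pair), dominanceRelationship(pair))) {
        expect_equal(M, t(M))
        ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
        expect_gt(min(ev), -1e-8 * max(ev))
      }
    }
  }
})

test_that("Definitions II and III coincide when all raw diagonals are equal", {
  ## complement genotypes at p = 0.5 SNPs: equal diagonals by symmetry
  set.seed(61)
  row1 <- rep_len(c(0L, 1L, 2L, 1L), 40)
  counts <- rbind(a = row1, b = 2L - row1)   # in-sample p = 0.5 at every SNP
  gm <- GenotypeMatrix(counts)
  p2 <- genomicRelationship(gm, "II")
  p3 <- genomicRelationship(gm, "III")
  expect_equal(additiveRelationship(p2), additiveRelationship(p3))
  expect_equal(dominanceRelationship(p2), dominanceRelationship(p3))
})

test_that("Definition I equals Definition II when observed and expected variances agree", {
  set.seed(71)
  inst <- randomInstance(12, 40)
  p1 <- genomicRelationship(inst$ds, "I")
  p2 <- genomicRelationship(inst$ds, "II")
  ratio <- p1@kAlpha / p2@kAlpha
  expect_equal(additiveRelationship(p1) * ratio, additiveRelationship(p2))
})

test_that("normalized codings reproduce the relationship matrices exactly", {
  set.seed(81)
  inst <- randomInstance(15, 25)
  for (def in c("I", "II", "III")) {
    pair <- genomicRelationship(inst$ds, def)
    tc <- normalizedCoding(pair, inst$ds)
    expect_equal(tcrossprod(tc$Talpha), additiveRelationship(pair),
                 ignore_attr = TRUE)
    expect_equal(tcrossprod(tc$Tdelta), dominanceRelationship(pair),
                 ignore_attr = TRUE)
  }
})

test_that("gene-dropped families reproduce pedigree expectations by class", {
  set.seed(91)
  cfg <- simConfig(nSires = 40, damsPerSire = 2, offspringPerDam = 2,
                   nUnrelated = 40, mQtl = 3000, h2a = 0.3, h2d = 0.1,
                   seed = 91)
  sim <- simulateGenotypes(cfg)
  pair <- genomicRelationship(sim$genotypes, "III")
  rs <- relationshipSummary(pair, sim$pairClasses)
  get <- function(mat, cl, col) rs[rs$matrix == mat & rs$class == cl, col]
  expect_equal(get("additive", "full-sib", "mean"), 0.5, tolerance = 0.03)
  expect_equal(get("additive", "half-sib", "mean"), 0.25, tolerance = 0.04)
  expect_equal(get("dominance", "full-sib", "mean"), 0.25, tolerance = 0.03)
  expect_equal(get("dominance", "half-sib", "mean"), 0, tolerance = 0.03)
  expect_equal(get("additive", "unrelated", "mean"), 0, tolerance = 0.02)
  expect_equal(get("dominance", "unrelated", "mean"), 0, tolerance = 0.02)
})

test_that("relationshipSummary validates labels and flags outlier pairs", {
  set.seed(95)
  cfg <- simConfig(nSires = 20, damsPerSire = 1, offspringPerDam = 2,
                   nUnrelated = 2, mQtl = 800, h2a = 0.3, h2d = 0.1, seed = 95)
  sim <- simulateGenotypes(cfg)
  pair <- genomicRelationship(sim$genotypes, "III")
  bad <- data.frame(id1 = "nope", id2 = individualIds(sim$genotypes)[1],
                    class = "full-sib")
  expect_error(relationshipSummary(pair, bad), "unknown")
  ## mislabel an unrelated pair as full-sib: it should stand out as an outlier
  cls <- sim$pairClasses
  fake <- cls$class == "unrelated" & grepl("unr", cls$id1) & grepl("unr", cls$id2)
  cls$class[which(fake)[1]] <- "full-sib"
  rs <- relationshipSummary(pair, cls, zThreshold = 3)
  expect_gte(rs[rs$matrix == "additive" & rs$class == "full-sib", "nOutlier"], 1)
})

test_that("Definition III rejects an individual with no informative genotypes", {
  ## an all-heterozygous individual at in-sample p = 0.5 SNPs has x - 2p = 0
  ## everywhere, hence a zero raw additive diagonal
  counts <- rbind(a = c(1L, 1L), b = c(0L, 2L), c = c(2L, 0L))
  gm <- GenotypeMatrix(counts)
  expect_error(genomicRelationship(gm, "III"), "a")
})
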
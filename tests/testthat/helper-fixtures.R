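## Shared fixtures: everything is generated in code under fixed seeds.

## Largest elementwise difference relative to the overall scale of the
## compared quantities (1 at minimum, so near-zero vectors compare absolutely).
relErr <- function(a, b) {
  max(abs(a - b)) / max(1, max(abs(a)), max(abs(b)))
}

## HWE genotype matrix with known allele frequencies.
hweCounts <- function(q, m, freqs = stats::runif(m, 0.2, 0.8)) {
  matrix(stats::rbinom(q * m, 2L, rep(freqs, each = q)), q, m)
}

## A random mixed-model instance exercising a chosen shape. Returns the
## design, relationship pair and a random positive component setting.
randomInstance <- function(q, m, definition = "II", dupRows = FALSE,
                           rankDefX = FALSE, repeatedRecords = FALSE) {
  counts <- hweCounts(q, m)
  if (dupRows && q >= 2) counts[2, ] <- counts[1, ]
  gm <- suppressMessages(GenotypeMatrix(counts))
  herd <- factor(rep_len(c("h1", "h2"), q))
  ph <- data.frame(id = individualIds(gm), y = stats::rnorm(q), herd = herd)
  if (repeatedRecords) {
    extra <- ph[seq_len(min(3, q)), ]
    extra$y <- extra$y + stats::rnorm(nrow(extra))
    ph <- rbind(ph, extra)
  }
  ds <- buildDesign(ph, gm, fixed = ~herd)
  if (rankDefX) {
    X <- cbind(ds@X, dup = ds@X[, 1])
    ds <- suppressWarnings(
      new("DesignSet", y = ds@y, X = X, Z = ds@Z, Talpha = ds@Talpha,
          Tdelta = ds@Tdelta, individualIds = ds@individualIds,
          freqs = ds@freqs))
  }
  pair <- genomicRelationship(ds, definition)
  vc <- varianceComponents(stats::runif(1, 0.2, 1.5),
                           stats::runif(1, 0.1, 1),
                           stats::runif(1, 0.5, 1.5))
  list(ds = ds, pair = pair, vc = vc, gm = gm)
}

## Simulated data set ready for GREML/GBLUP.
simInstance <- function(nInd, mQtl, h2a, h2d, seed, definition = "II", ...) {
  cfg <- simConfig(nInd = nInd, mQtl = mQtl, h2a = h2a, h2d = h2d,
                   seed = seed, ...)
  sim <- simulateGenotypes(cfg)
  truth <- simulatePhenotypes(sim$genotypes, cfg)
  ds <- buildDesign(phenotypeTable(sim$genotypes, truth), sim$genotypes)
  list(ds = ds, pair = genomicRelationship(ds, definition), truth = truth,
       gm = sim$genotypes, sim = sim)
}
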
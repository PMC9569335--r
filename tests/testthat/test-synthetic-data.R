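test_that("genotype simulation is deterministic and respects the LD structure", {
  cfg <- simulationConfig(seed = 21, nIndividuals = 5000, nVariants = 100,
                          blockSize = 10, rhoLD = 0)
  p1 <- simulateGenotypePanel(cfg)
  p2 <- simulateGenotypePanel(cfg)
  expect_identical(genotypes(p1), genotypes(p2))
  expect_true(all(genotypes(p1) %in% 0:2))
  f <- colMeans(genotypes(p1)) / 2
  expect_true(all(pmin(f, 1 - f) > 0))

  # rho = 0: between-variant r^2 is noise-level on random pairs
  set.seed(1)
  pairs <- cbind(sample(100, 100, TRUE), sample(100, 100, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  r2 <- apply(pairs, 1, function(ij) pairwiseR2(p1, ij[1], ij[2]))
  expect_lt(max(r2), 0.05)
})

test_that("high within-block correlation yields strong adjacent LD", {
  r2adj <- vapply(1:10, function(s) {
    cfg <- simulationConfig(seed = s, nIndividuals = 5000, nVariants = 20,
                            blockSize = 10, rhoLD = 0.99)
    p <- simulateGenotypePanel(cfg)
    pairwiseR2(p, 1, 2)   # same-block adjacent pair
  }, numeric(1))
  expect_true(all(r2adj > 0.5))
})

test_that("analytic summary statistics follow the chi-square model", {
  cfg <- simulationConfig(seed = 31, nIndividuals = 100, nVariants = 20000,
                          blockSize = 20, plantedTau = c(active = 0))
  panel <- simulateGenotypePanel(cfg)
  active <- annotationSet("active",
    GRanges("chr1", IRanges(1, genomeLength(cfg) / 4)))
  lds <- partitionedLdScores(panel, list(active = active), windowBp = 1)

  # global null: mean chi-square ~ 1
  st0 <- simulateSummaryStats(panel, list(active = active), cfg,
                              mode = "analytic", ldscores = lds)
  expect_lt(abs(mean(st0$CHISQ) - 1), 0.05)
  expect_identical(names(st0)[1:11], sumstatColumns())

  # N = 0: no-association limit, central chi-square regardless of tau
  cfgN0 <- cfg; cfgN0$gwasN <- 0; cfgN0$plantedTau <- c(active = 1e-4)
  stN0 <- simulateSummaryStats(panel, list(active = active), cfgN0,
                               mode = "analytic", ldscores = lds)
  expect_lt(abs(mean(stN0$CHISQ) - 1), 0.05)

  # planted tau: mean chi-square higher inside the annotation, 10 seeds
  member <- annotateVariants(panel, active) == 1
  higher <- vapply(1:10, function(s) {
    cfgS <- cfg; cfgS$seed <- s; cfgS$plantedTau <- c(active = 5e-6)
    st <- simulateSummaryStats(panel, list(active = active), cfgS,
                               mode = "analytic", ldscores = lds)
    mean(st$CHISQ[member]) > mean(st$CHISQ[!member])
  }, logical(1))
  expect_true(all(higher))
  cfgS <- cfg; cfgS$seed <- 99; cfgS$plantedTau <- c(active = 5e-6)
  st <- simulateSummaryStats(panel, list(active = active), cfgS,
                             mode = "analytic", ldscores = lds)
  wt <- wilcox.test(st$CHISQ[member], st$CHISQ[!member],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)

  # impossible heritability rejected
  cfgBad <- cfg; cfgBad$plantedTau <- c(active = 1)
  expect_error(simulateSummaryStats(panel, list(active = active), cfgBad,
                                    mode = "analytic", ldscores = lds),
               "heritability")
})

test_that("phenotype mode conserves planted heritability", {
  cfg <- simulationConfig(seed = 41, nIndividuals = 2000, nVariants = 20000,
                          blockSize = 20,
                          plantedTau = c(active = 0.3 / 5000))
  panel <- simulateGenotypePanel(cfg)
  active <- annotationSet("active",
    GRanges("chr1", IRanges(1, genomeLength(cfg) / 4)))
  st <- simulateSummaryStats(panel, list(active = active), cfg,
                             mode = "phenotype")
  h2planted <- sum(annotateVariants(panel, active)) * 0.3 / 5000
  expect_lt(abs(attr(st, "h2Genetic") - h2planted) / h2planted, 0.1)
  expect_equal(unique(st$N), cfg$nIndividuals)
})

test_that("peak matrix simulation plants recoverable specificity", {
  # no planted signal: no peak scores far above its cross-state mean
  cfg0 <- simulationConfig(seed = 51, nVariants = 5000, nPeaks = 500,
                           nCellStates = 4, specificityFraction = 0)
  psm0 <- simulatePeakMatrix(cfg0)
  sc <- specificityScore(psm0)
  expect_lt(max(sc / rowMeans(sc)), 2)

  # peak intervals pairwise disjoint, determinism
  expect_equal(length(reduce(granges(rowRanges(psm0)))), nrow(psm0))
  psm0b <- simulatePeakMatrix(cfg0)
  expect_identical(assay(psm0, "signal"), assay(psm0b, "signal"))

  # planted peaks land in the top decile of their state's ranks, 10 seeds
  frac <- vapply(1:10, function(s) {
    cfg <- simulationConfig(seed = s, nVariants = 5000, nPeaks = 1000,
                            nCellStates = 4, specificityFraction = 0.05)
    psm <- simulatePeakMatrix(cfg)
    nr <- specificityRank(psm)
    planted <- rowData(psm)$plantedState
    idx <- which(!is.na(planted) & planted == "state2")
    mean(nr[idx, "state2"] > 0.9)
  }, numeric(1))
  expect_true(all(frac >= 0.9))
})

test_that("risk-variant planting respects the enrichment probability", {
  cfg <- simulationConfig(seed = 61, nVariants = 5000, nPeaks = 500,
                          nCellStates = 4, specificityFraction = 0.1,
                          plantedEnrichmentPi = 1, nLeads = 30)
  psm <- simulatePeakMatrix(cfg)
  leads <- plantRiskVariants(psm, "state1", cfg)
  planted <- rowData(psm)$plantedState
  target <- rowRanges(psm)[!is.na(planted) & planted == "state1"]
  expect_true(all(overlapsAny(leads, target)))
  expect_identical(leads, plantRiskVariants(psm, "state1", cfg))

  cfgBad <- cfg; cfgBad$specificityFraction <- 0
  psmFlat <- simulatePeakMatrix(cfgBad)
  expect_error(plantRiskVariants(psmFlat, "state1", cfgBad), "degenerate")
  expect_error(plantRiskVariants(psm, "nostate", cfg), "unknown target")
})
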
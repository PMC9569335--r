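# Shared small analytic-mode dataset for the regression tests.
sldscFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(seed = 101, nIndividuals = 400,
                              nVariants = 4000, blockSize = 25,
                              plantedTau = c(active = 2e-5))
      panel <- simulateGenotypePanel(cfg)
      seg <- simulateSegmentation(cfg)
      active <- mergeActiveStates(seg)
      total <- annotationSet("total",
        GRanges("chr1", IRanges(1, genomeLength(cfg))))
      lds <- partitionedLdScores(panel, list(active = active, total = total),
                                 windowBp = 50000L)
      stats <- simulateSummaryStats(panel, list(active = active), cfg,
                                    mode = "analytic", ldscores = lds)
      cache <<- list(cfg = cfg, panel = panel, active = active,
                     lds = lds, stats = stats)
    }
    cache
  }
})

test_that("the regression equals an independent normal-equations solve", {
  fx <- sldscFixture()
  fit <- fitSldsc(fx$stats, fx$lds, modelAnnotations = c("active", "total"),
                  nBlocks = 50, weights = "none")
  X <- cbind(1, ldScores(fx$lds) * fx$stats$N)
  beta <- solve(crossprod(X), crossprod(X, fx$stats$CHISQ))
  cf <- coefficientTable(fit)
  expect_equal(fit@intercept, beta[1], tolerance = 1e-8)
  expect_equal(cf$tau, as.numeric(beta[-1]), tolerance = 1e-8)
  expect_true(all(cf$se > 0))
  expect_equal(cf$p, pnorm(cf$z, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("null data recover a zero coefficient and unit intercept", {
  fx <- sldscFixture()
  cfg0 <- fx$cfg; cfg0$plantedTau <- c(active = 0); cfg0$seed <- 202
  st0 <- simulateSummaryStats(fx$panel, list(active = fx$active), cfg0,
                              mode = "analytic", ldscores = fx$lds)
  fit <- fitSldsc(st0, fx$lds, modelAnnotations = "active", nBlocks = 100)
  cf <- coefficientTable(fit)
  expect_lt(abs(cf$tau), 3 * cf$se)
  expect_lt(abs(fit@intercept - 1), 3 * fit@interceptSE)
})

test_that("weighted and unweighted fits both recover the planted coefficient", {
  fx <- sldscFixture()
  for (w in c("ldsc", "none")) {
    fit <- fitSldsc(fx$stats, fx$lds, modelAnnotations = "active",
                    nBlocks = 100, weights = w)
    cf <- coefficientTable(fit)
    expect_lt(abs(cf$tau - 2e-5), 3 * cf$se)
  }
})

test_that("degenerate model inputs are reported", {
  fx <- sldscFixture()
  # collinear columns named in the error
  sc <- ldScores(fx$lds)
  dup <- new("PartitionedLdScoreTable",
             scores = cbind(sc, copy = sc[, "active"]),
             variants = variantRanges(fx$lds), window = ldWindow(fx$lds),
             panelId = "panel")
  expect_error(fitSldsc(fx$stats, dup,
                        modelAnnotations = c("active", "copy")),
               "collinear")
  # too few variants: block count reduced with a warning
  sub <- fx$stats[1:150, ]
  expect_warning(fitSldsc(sub, fx$lds, modelAnnotations = "active",
                          nBlocks = 100), "reducing jackknife blocks")
  # missing annotation column
  expect_error(fitSldsc(fx$stats, fx$lds, modelAnnotations = "missing"),
               "missing")
})

test_that("conditional fits reduce to the plain fit and attenuate shadow signal", {
  fx <- sldscFixture()
  plain <- fitSldsc(fx$stats, fx$lds, modelAnnotations = "active",
                    nBlocks = 100)
  cond0 <- fitConditional(fx$stats, fx$lds, "active", character(),
                          nBlocks = 100)
  expect_equal(coefficientTable(cond0)$tau, coefficientTable(plain)$tau,
               tolerance = 1e-12)
  expect_identical(cond0@target, "active")
  expect_error(fitConditional(fx$stats, fx$lds, "active", "active"),
               "conditioning set")

  # conditioning on a base-disjoint, LD-independent annotation leaves the
  # target essentially unchanged
  set.seed(7)
  member <- annotateVariants(fx$panel, fx$active)
  far <- as.numeric(member == 0 & runif(4000) < 0.2)
  lds2 <- partitionedLdScores(fx$panel,
    list(active = fx$active, far = far), windowBp = 50000L)
  un <- fitSldsc(fx$stats, lds2, modelAnnotations = "active", nBlocks = 100)
  co <- fitConditional(fx$stats, lds2, "active", "far", nBlocks = 100)
  tUn <- coefficientTable(un); tCo <- coefficientTable(co)
  i <- match("active", tCo$annotation)
  expect_lt(abs(tCo$tau[i] - tUn$tau), tUn$se)
})

test_that("coefficient difference test matches the closed form", {
  mk <- function(tau, se) {
    new("RegressionResult",
        coefficients = data.frame(annotation = "a", tau = tau, se = se,
                                  z = tau / se,
                                  p = pmin(pmax(pnorm(tau / se,
                                    lower.tail = FALSE), 1e-12), 1 - 1e-12)),
        intercept = 1, interceptSE = 0.1,
        jackknife = matrix(0, 2, 2), nVariants = 10L, nBlocks = 2L,
        target = NA_character_, weighted = TRUE)
  }
  eq <- coefficientDifferenceTest(mk(2e-6, 1e-6), mk(2e-6, 1e-6), "a")
  expect_equal(unname(eq["z"]), 0)
  expect_equal(unname(eq["p"]), 0.5)

  ex <- coefficientDifferenceTest(mk(2e-6, 1e-6), mk(0, 1e-6), "a")
  expect_equal(unname(ex["z"]), sqrt(2), tolerance = 1e-5)
  expect_equal(unname(ex["p"]), 0.0786, tolerance = 1e-3)

  sw <- coefficientDifferenceTest(mk(0, 1e-6), mk(2e-6, 1e-6), "a")
  expect_equal(unname(sw["z"]), -unname(ex["z"]))
  expect_equal(unname(sw["p"]), 1 - unname(ex["p"]), tolerance = 1e-12)

  expect_error(coefficientDifferenceTest(mk(0, 1), mk(0, 1), "b"),
               "not in model")
})

test_that("heritability summaries scale correctly and recover planted h2", {
  fx <- sldscFixture()
  fit <- fitSldsc(fx$stats, fx$lds, modelAnnotations = "active",
                  nBlocks = 100)
  sizes <- c(active = sum(annotateVariants(fx$panel, fx$active)))
  h <- heritabilitySummary(fit, sizes)
  expect_equal(unname(h["h2"]),
               sum(coefficientTable(fit)$tau * sizes))

  # scale identity: doubling |C| with tau halved leaves h2 unchanged
  half <- fit
  half@coefficients$tau <- half@coefficients$tau / 2
  half@jackknife[, -1] <- half@jackknife[, -1] / 2
  h2 <- heritabilitySummary(half, 2 * sizes)
  expect_equal(unname(h2["h2"]), unname(h["h2"]), tolerance = 1e-12)
  expect_equal(unname(h2["z"]), unname(h["z"]), tolerance = 1e-9)

  # phenotype-mode recovery of a planted total h2 within 3 SE
  cfgP <- simulationConfig(seed = 301, nIndividuals = 2000,
                           nVariants = 10000, blockSize = 25,
                           plantedTau = c(active = 0))
  panelP <- simulateGenotypePanel(cfgP)
  activeP <- annotationSet("active",
    GRanges("chr1", IRanges(1, genomeLength(cfgP) / 4)))
  nAct <- sum(annotateVariants(panelP, activeP))
  cfgP$plantedTau <- c(active = 0.3 / nAct)
  stP <- simulateSummaryStats(panelP, list(active = activeP), cfgP,
                              mode = "phenotype")
  ldsP <- partitionedLdScores(panelP, list(active = activeP),
                              windowBp = 50000L)
  fitP <- fitSldsc(stP, ldsP, modelAnnotations = "active", nBlocks = 100)
  hP <- heritabilitySummary(fitP, c(active = nAct))
  expect_lt(abs(unname(hP["h2"]) - 0.3), 3 * unname(hP["se"]))

  expect_error(heritabilitySummary(fit, c(other = 5)), "missing annotation")
})

test_that("jackknife standard errors shrink like 1/sqrt(n)", {
  sizes <- c(2500L, 5000L, 10000L, 20000L)
  meanSe <- vapply(sizes, function(m) {
    ses <- vapply(1:3, function(s) {
      cfg <- simulationConfig(seed = 400 + s, nIndividuals = 300,
                              nVariants = m, blockSize = 25,
                              plantedTau = c(active = 5e-6))
      panel <- simulateGenotypePanel(cfg)
      active <- annotationSet("active",
        GRanges("chr1", IRanges(1, genomeLength(cfg) / 4)))
      lds <- partitionedLdScores(panel, list(active = active),
                                 windowBp = 50000L)
      st <- simulateSummaryStats(panel, list(active = active), cfg,
                                 mode = "analytic", ldscores = lds)
      coefficientTable(fitSldsc(st, lds, modelAnnotations = "active",
                                nBlocks = 100))$se
    }, numeric(1))
    mean(ses)
  }, numeric(1))
  slope <- coef(lm(log(meanSe) ~ log(sizes)))[2]
  expect_lt(abs(slope + 0.5), 0.15)
})
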
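test_that("specificity scores follow the normalization chain", {
  # one-hot row: score 1 in its state; constant row: 1/sqrt(S) everywhere
  sig <- rbind(c(10, 0, 0, 0),
               c(5, 5, 5, 5),
               matrix(runif(40, 1, 2), 10, 4))
  colnames(sig) <- paste0("state", 1:4)
  psm <- makePeakMatrix(sig, quantileNormalize = FALSE, dropBottom = 0)
  sc <- specificityScore(psm)
  expect_equal(unname(sc[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(sc[2, ]), rep(1 / 2, 4))   # 1/sqrt(4)
  # per peak the squared scores sum to one
  expect_equal(unname(rowSums(sc^2)), rep(1, nrow(sc)))
  # the one-hot peak is the most state1-specific
  expect_equal(unname(specificityRank(psm)[1, "state1"]), 1)

  # ranks equal a sort oracle per state, and normalized ranks average to
  # (N+1)/2N exactly
  set.seed(19)
  big <- matrix(rlnorm(800), 200, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  p2 <- makePeakMatrix(big, dropBottom = 0)
  rk <- specificityRank(p2, normalized = FALSE)
  sc2 <- specificityScore(p2)
  for (s in colnames(sc2))
    expect_equal(unname(rk[, s]),
                 unname(rank(sc2[, s], ties.method = "first")))
  N <- nrow(p2)
  expect_equal(unname(colMeans(specificityRank(p2))),
               rep((N + 1) / (2 * N), 4))

  # all-zero rows are dropped with a warning; bottom decile is removed
  sigZ <- rbind(sig, 0)
  expect_warning(pz <- makePeakMatrix(sigZ, quantileNormalize = FALSE,
                                      dropBottom = 0), "all-zero")
  expect_equal(nrow(pz), nrow(sig))
  p3 <- makePeakMatrix(big, dropBottom = 0.1)
  expect_equal(nrow(p3), 180L)
})

test_that("variant-peak overlap deduplicates peaks and is half-open at BED ends", {
  sig <- matrix(runif(40, 1, 2), 10, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  # peak i occupies BED (1000*i, 1000*i + 100), i.e. 1-based 1000i+1..1000i+100
  psm <- makePeakMatrix(sig, starts = seq_len(10) * 1000 + 1, width = 100,
                        dropBottom = 0)
  v <- GRanges("chr1", IRanges(c(1050, 1080, 1100, 1101, 5000), width = 1),
               variant = paste0("v", 1:5), lead = paste0("l", 1:5))
  ov <- overlapVariants(psm, v)
  # v1, v2 inside peak 1; v3 at the last covered base; v4 at the BED end
  # coordinate (outside); v5 in no peak
  expect_setequal(ov$variant, c("v1", "v2", "v3"))
  expect_equal(length(attr(ov, "peaks")), 1L)
  expect_equal(unique(ov$peak), rownames(specificityScore(psm))[1])

  # random placement vs a linear-scan oracle
  set.seed(23)
  pos <- sample.int(12000, 300)
  vr <- GRanges("chr1", IRanges(pos, width = 1),
                variant = paste0("r", seq_along(pos)))
  ovR <- overlapVariants(psm, vr)
  starts <- start(rowRanges(psm)); ends <- end(rowRanges(psm))
  oracle <- vapply(pos, function(p) any(p >= starts & p <= ends),
                   logical(1))
  expect_setequal(ovR$variant, paste0("r", which(oracle)))
})

test_that("the enrichment test matches the discrete-uniform null", {
  # N = 100 peaks, one overlapped peak with the top rank: exact p = 1/100
  set.seed(29)
  sig <- matrix(rlnorm(600), 100, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  psm <- makePeakMatrix(sig, quantileNormalize = FALSE, dropBottom = 0)
  nr <- specificityRank(psm)
  top <- rownames(nr)[nr[, "s3"] == 1]   # the most s3-specific peak
  expect_length(top, 1L)
  exact <- cheersTest(psm, top, states = "s3", method = "exact")
  expect_equal(enrichmentTable(exact)$p, 0.01)
  normal <- cheersTest(psm, top, states = "s3")
  expect_gt(enrichmentTable(normal)$p, 0)    # reported alongside

  # exhaustive overlap: mean rank hits the null mean exactly, Z = 0
  all <- cheersTest(psm, rownames(specificityScore(psm)))
  tab <- enrichmentTable(all)
  expect_equal(tab$mean_rank, rep((100 + 1) / 200, 6))
  expect_equal(tab$z, rep(0, 6))
  expect_equal(tab$p, rep(0.5, 6), tolerance = 0.005)

  # Bonferroni column respects the family size
  expect_equal(tab$p_bonferroni, pmin(1, tab$p * 6), tolerance = 1e-12)
  expect_error(cheersTest(psm, top, mBonferroni = 2), "family size")

  # zero overlap: untestable, not an error
  none <- suppressMessages(cheersTest(psm, character()))
  expect_true(all(is.na(enrichmentTable(none)$p)))

  # exact tail matches full enumeration on frozen tiny cases
  ex <- epienrich:::exactRankSumTail
  expect_equal(ex(2, 4, 6), 0.375)
  expect_equal(ex(3, 5, 9), 0.576)
  expect_equal(ex(1, 100, 100), 0.01)

  # Monte-Carlo null agrees with the exact null
  mc <- cheersTest(psm, top, states = "s3", method = "montecarlo",
                   nMc = 200000L, seed = 5)
  expect_lt(abs(enrichmentTable(mc)$p - 0.01), 0.005)
})

test_that("the stimulation contrast matches the closed form", {
  mk <- function(meanRank, n = 30L, N = 1000L) {
    new("CheersResult",
        table = data.frame(state = "s", n_peaks = n, mean_rank = meanRank,
                           z = 0, p = 0.5, p_bonferroni = 1),
        nPeaksTotal = N,
        overlaps = data.frame(peak = character(), variant = character(),
                              lead = character()),
        method = "normal")
  }
  # sigma_n = sqrt((10^6 - 1) / (12 * 10^6 * 30)) = 0.052702
  out <- stimulationContrast(mk(0.9), mk(0.8), "s")
  expect_equal(unname(out["z"]), 1.3417, tolerance = 1e-4)
  expect_equal(unname(out["p"]), 0.0899, tolerance = 1e-3)

  eq <- stimulationContrast(mk(0.7), mk(0.7), "s")
  expect_equal(unname(eq["z"]), 0)
  expect_equal(unname(eq["p"]), 0.5)

  sw <- stimulationContrast(mk(0.8), mk(0.9), "s")
  expect_equal(unname(sw["z"]), -unname(out["z"]))
  expect_equal(unname(sw["p"]), 1 - unname(out["p"]), tolerance = 1e-12)

  expect_error(stimulationContrast(mk(0.9), mk(0.8, n = 10L), "s"),
               "incomparable")
})

test_that("Bonferroni adjustment is the capped product", {
  expect_equal(bonferroniAdjust(0.01, m = 19), 0.19)
  expect_equal(bonferroniAdjust(0.2, m = 19), 1)
  p <- runif(10)
  expect_true(all(bonferroniAdjust(p) >= p))
  expect_error(bonferroniAdjust(runif(5), m = 3), "family size")
})
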
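test_that("sharing counts decompose the overlapped peaks into disjoint cells", {
  sh <- sharingCounts(list(A = c("p1", "p2"), B = "p2"))
  cells <- setNames(sh$cells$count, sh$cells$pattern)
  expect_equal(unname(cells["A"]), 1)        # unique to A
  expect_equal(unname(cells["A&B"]), 1)      # shared
  expect_false("B" %in% names(cells))        # nothing unique to B

  one <- sharingCounts(list(A = c("p1", "p2", "p3")))
  expect_equal(one$cells$count, 3)

  # four disorders vs brute-force set algebra
  set.seed(31)
  universe <- paste0("pk", 1:60)
  sets <- lapply(1:4, function(i) sample(universe, sample(5:30, 1)))
  names(sets) <- LETTERS[1:4]
  sh4 <- sharingCounts(sets)
  expect_equal(sum(sh4$cells$count), length(unique(unlist(sets))))
  for (pk in unique(unlist(sets))) {
    pat <- paste(names(sets)[vapply(sets, function(s) pk %in% s,
                                    logical(1))], collapse = "&")
    expect_true(sh4$membership[pk, strsplit(pat, "&")[[1]][1]])
    expect_equal(sum(sh4$cells$count[sh4$cells$pattern == pat] > 0), 1)
  }
})

test_that("discordant peak sets are selective, disjoint and oracle-consistent", {
  set.seed(37)
  sig <- matrix(rlnorm(1200), 200, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  psm <- makePeakMatrix(sig, dropBottom = 0)
  nr <- specificityRank(psm)
  selective <- rownames(nr)[apply(nr, 1, max) > 0.9]
  expect_gt(length(selective), 0)

  ovA <- data.frame(peak = sample(rownames(nr), 40), variant = "v",
                    lead = "l")
  ovB <- data.frame(peak = sample(rownames(nr), 40), variant = "v",
                    lead = "l")
  d <- discordantPeaks(psm, ovA, ovB)
  expect_length(intersect(d$onlyA, d$onlyB), 0)
  expect_setequal(d$onlyA,
                  setdiff(intersect(ovA$peak, selective),
                          intersect(ovB$peak, selective)))
  expect_setequal(d$onlyB,
                  setdiff(intersect(ovB$peak, selective),
                          intersect(ovA$peak, selective)))

  same <- discordantPeaks(psm, ovA, ovA)
  expect_length(same$onlyA, 0)
  expect_length(same$onlyB, 0)
})

test_that("peak element classification applies the one-base-pair rule", {
  promoter <- annotationSet("promoter", GRanges("chr1", IRanges(1000, 2000)))
  enhancer <- annotationSet("enhancer", GRanges("chr1", IRanges(2001, 3000)))
  classes <- list(promoter = promoter, enhancer = enhancer)
  peaks <- GRanges("chr1", IRanges(c(1100, 1950, 5000), c(1200, 2100, 5100)))
  names(peaks) <- c("inside", "spanning", "outside")
  lab <- classifyPeakElements(peaks, classes)
  expect_equal(lab$inside, "promoter")
  expect_setequal(lab$spanning, c("promoter", "enhancer"))
  expect_length(lab$outside, 0)

  pr <- classifyPeakElements(peaks, classes,
                             priority = c("promoter", "enhancer"))
  expect_equal(unname(pr), c("promoter", "promoter", NA))

  # random peaks vs per-base oracle
  set.seed(41)
  rp <- GRanges("chr1", IRanges(sample.int(9000, 100), width = 50))
  names(rp) <- paste0("p", 1:100)
  labR <- classifyPeakElements(rp, classes)
  for (i in seq_along(rp)) {
    for (cl in names(classes)) {
      cov <- perBaseCover(annotationRanges(classes[[cl]]), 10000L)
      touches <- any(cov[start(rp)[i]:end(rp)[i]])
      expect_equal(cl %in% labR[[i]], touches)
    }
  }
})

test_that("Spearman reconstruction reproduces the printed statistics", {
  # S = 16, n = 9: rho prints as 0.87, exact two-sided p prints as 0.005
  r1 <- spearmanFromS(16, 9)
  expect_equal(round(r1$rho, 2), 0.87)
  expect_equal(round(r1$p, 3), 0.005)
  # S = 120 is the null expectation n(n^2-1)/6: rho 0, p 1
  r2 <- spearmanFromS(120, 9)
  expect_equal(r2$rho, 0)
  expect_equal(r2$p, 1)
  # S = 116: rho prints as 0.03, p as 0.9
  r3 <- spearmanFromS(116, 9)
  expect_equal(round(r3$rho, 2), 0.03)
  expect_equal(round(r3$p, 1), 0.9)
})

test_that("exact Spearman p agrees with cor.test and basic identities hold", {
  x <- 1:9
  y <- c(3, 2, 1, 6, 5, 4, 7, 8, 9)   # S = 16
  r <- spearmanExact(x, y, nBoot = 0)
  expect_equal(r$S, 16)
  expect_equal(r$rho, 1 - 6 * 16 / (9 * 80))
  ct <- cor.test(x, y, method = "spearman")
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)

  # random cases, n in 5..7, against cor.test's exact p
  set.seed(43)
  for (i in 1:15) {
    n <- sample(5:7, 1)
    xs <- rnorm(n); ys <- rnorm(n)
    mine <- spearmanExact(xs, ys, nBoot = 0)
    ref <- cor.test(xs, ys, method = "spearman")
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # symmetry and monotone-transform invariance
    expect_equal(spearmanExact(ys, xs, nBoot = 0)$rho, mine$rho)
    expect_equal(spearmanExact(exp(xs), ys, nBoot = 0)$rho, mine$rho)
  }

  # identical rankings: S = 0, rho = 1, exact two-sided p = 2/n!
  id <- spearmanExact(1:6, 2 * (1:6), nBoot = 0)
  expect_equal(id$S, 0)
  expect_equal(id$rho, 1)
  expect_equal(id$p, 2 / factorial(6))

  # ties: warning and fallback to the general formula
  expect_warning(tied <- spearmanExact(c(1, 1, 2, 3, 4),
                                       c(2, 1, 3, 4, 5), nBoot = 0),
                 "ties")
  expect_equal(tied$method, "ties")
  expect_equal(tied$rho,
               suppressWarnings(cor(c(1, 1, 2, 3, 4), c(2, 1, 3, 4, 5),
                                    method = "spearman")))

  expect_error(spearmanExact(1:2, 1:2), "at least 3")
  expect_error(spearmanExact(c(1, NA, 3), 1:3), "missing")
})

test_that("the bootstrap CI is seeded, reproducible and covers the truth", {
  set.seed(47)
  x <- rnorm(9); y <- x + rnorm(9)
  a <- spearmanExact(x, y, nBoot = 2000, seed = 9)
  b <- spearmanExact(x, y, nBoot = 2000, seed = 9)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] <= a$rho && a$rho <= a$ci[2])

  # coverage at n = 9 on correlated bivariate-normal pairs; the population
  # Spearman rho of (z + e1, 0.5 z + e2) is (6/pi) asin(r/2) with Pearson
  # r = 0.5 / sqrt(2 * 1.25)
  rhoPop <- 6 / pi * asin(0.5 / sqrt(2 * 1.25) / 2)
  set.seed(53)
  hits <- vapply(1:500, function(i) {
    z <- rnorm(9); xi <- z + rnorm(9); yi <- 0.5 * z + rnorm(9)
    ci <- spearmanExact(xi, yi, nBoot = 400, seed = i)$ci
    ci[1] <= rhoPop && rhoPop <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
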
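.mkSE <- function(counts, day = NULL, cl = "A", rep = NULL) {
  n <- ncol(counts)
  if (is.null(day)) day <- rep(0, n)
  if (is.null(rep)) rep <- seq_len(n)
  colnames(counts) <- sprintf("%s_rep%d_day%d", cl, rep, day)
  ScreenExperiment(counts, cellLine = rep(cl, n), replicate = rep, day = day)
}

test_that("control-median normalization is exact and ratio-preserving", {
  set.seed(1)
  counts <- matrix(rpois(300, 800), 50, 6,
                   dimnames = list(paste0("g", 1:50), NULL))
  ctl <- paste0("g", 1:10)
  counts[1:10, 1] <- 500   # control median 500 in sample 1
  se <- .mkSE(counts, day = c(0, 0, 8, 8, 22, 22), rep = c(1, 2, 1, 2, 1, 2))
  norm <- SummarizedExperiment::assay(normalizeToControls(se, ctl, 1000))
  for (j in 1:6) expect_equal(median(norm[ctl, j]), 1000)
  # sample with control median 500 was exactly doubled
  expect_equal(norm[, 1], counts[, 1] * 2)
  # a sample already at control median 1000 is unchanged
  counts2 <- counts; counts2[1:10, 2] <- 1000
  se2 <- .mkSE(counts2, day = c(0, 0, 8, 8, 22, 22), rep = c(1, 2, 1, 2, 1, 2))
  norm2 <- SummarizedExperiment::assay(normalizeToControls(se2, ctl, 1000))
  expect_equal(norm2[, 2], counts2[, 2])
  # within-sample ratios preserved
  expect_equal(unname(norm[20, 3] / norm[30, 3]),
               unname(counts[20, 3] / counts[30, 3]))
  # degenerate inputs
  zero <- counts; zero[1:10, 4] <- 0
  se3 <- .mkSE(zero, day = c(0, 0, 8, 8, 22, 22), rep = c(1, 2, 1, 2, 1, 2))
  expect_error(normalizeToControls(se3, ctl), "zero median")
  expect_error(normalizeToControls(se, character(0)), "non-empty")
  expect_error(normalizeToControls(se, c(ctl, "absent")), "absent")
})

test_that("TMM factors correct composition bias", {
  set.seed(2)
  base <- rpois(4000, 500) + 1
  # identical samples: both factors 1
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- paste0("g", seq_along(base))
  expect_equal(unname(tmmFactors(m)), c(1, 1), tolerance = 1e-6)
  # pure depth change, no composition change: factors stay equal
  m2 <- cbind(s1 = base, s2 = base * 4L)
  expect_equal(unname(tmmFactors(m2)[1]), unname(tmmFactors(m2)[2]),
               tolerance = 1e-6)
  # planted 5% strongly enriched guides in sample 2 (NB noise around a
  # shared abundance profile)
  mu <- rexp(4000, 1 / 500) + 50
  enrich <- rep(1, 4000); enrich[seq_len(200)] <- 10
  enriched <- seq_len(200)
  m3 <- cbind(s1 = rnbinom(4000, mu = mu, size = 30),
              s2 = rnbinom(4000, mu = mu * enrich, size = 30)) + 1L
  rownames(m3) <- paste0("g", 1:4000)
  f <- tmmFactors(m3)
  # truth: after effective-library scaling, unenriched guides line up
  eff <- colSums(m3) * f
  normed <- sweep(m3, 2, mean(eff) / eff, `*`)
  ratio <- median(normed[-enriched, 2] / normed[-enriched, 1])
  expect_lt(abs(ratio - 1), 0.02)
  # independent doubly-trimmed mean oracle for the M-value offset
  M <- log2((m3[, 2] / sum(m3[, 2])) / (m3[, 1] / sum(m3[, 1])))
  A <- 0.5 * log2((m3[, 2] / sum(m3[, 2])) * (m3[, 1] / sum(m3[, 1])))
  keep <- M >= quantile(M, 0.3) & M <= quantile(M, 0.7) &
          A >= quantile(A, 0.05) & A <= quantile(A, 0.95)
  oracle <- 2^mean(M[keep])
  expect_lt(abs((f[2] / f[1]) / oracle - 1), 0.02)
  expect_error(tmmFactors(m[, 1, drop = FALSE]), "2 samples")
})

test_that("guide log2 fold changes use matched day-0 replicates", {
  counts <- cbind(r1d0 = c(2000, 100, 2000, 2), r2d0 = c(2000, 100, 2000, 2),
                  r1d22 = c(4000, 100, 0, 2), r2d22 = c(4000, 100, 0, 2))
  rownames(counts) <- c("gUp", "gFlat", "gZero", "gSmall")
  se <- .mkSE(counts, day = c(0, 0, 22, 22), rep = c(1, 2, 1, 2))
  lfc <- guideLFC(se, pseudocount = "none")
  expect_equal(lfc$lfc[lfc$guide_id == "gUp"], 1, tolerance = 1e-12)
  expect_equal(lfc$lfc[lfc$guide_id == "gFlat"], 0)
  # zero count at day 22, day 0 = 2000, pseudocount = min nonzero (= 2):
  # log2(2/2002) ~ -9.97
  lfc2 <- guideLFC(se, pseudocount = "min.nonzero")
  expect_equal(lfc2$lfc[lfc2$guide_id == "gZero"], log2(2 / 2002),
               tolerance = 1e-9)
  # pseudocount negligible at large counts
  expect_equal(lfc2$lfc[lfc2$guide_id == "gUp"], 1, tolerance = 0.01)
})

test_that("replicate depletion test is calibrated and symmetric", {
  reps <- data.frame(guide_id = rep(c("g1", "g2"), each = 2),
                     cell_line = "A", replicate = c(1, 2, 1, 2), day = 22,
                     lfc = c(0, 0, 1.5, -1.5))
  res <- guideDepletionTest(reps)
  expect_equal(res$p[res$guide_id == "g1"], 1)
  expect_equal(res$t[res$guide_id == "g1"], 0)
  # sign flip leaves p unchanged
  flip <- reps; flip$lfc <- -flip$lfc
  expect_equal(guideDepletionTest(flip)$p, res$p)
  # zero variance with nonzero mean: floored p, flagged
  degen <- data.frame(guide_id = "g", cell_line = "A", replicate = 1:2,
                      day = 22, lfc = c(-2, -2))
  rd <- guideDepletionTest(degen)
  expect_true(rd$flag)
  expect_lt(rd$p, 1e-300)
  # null calibration: NB noise, no effect, 4 replicates
  set.seed(5)
  n <- 10000
  x0 <- matrix(rnbinom(n * 4, mu = 1000, size = 20), n, 4)
  xt <- matrix(rnbinom(n * 4, mu = 1000, size = 20), n, 4)
  lfcs <- log2(xt / x0)
  null <- data.frame(guide_id = rep(sprintf("g%05d", 1:n), 4),
                     cell_line = "A", replicate = rep(1:4, each = n),
                     day = 22, lfc = as.vector(lfcs))
  pr <- guideDepletionTest(null)
  frac <- mean(pr$p < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("fitness model recovers the exponential rate exactly when noiseless", {
  days <- c(0, 8, 15, 22)
  x <- rbind(1000 * exp(-0.1 * days))
  fit <- fitFitness(x, days)
  expect_equal(fit$alpha, -0.1, tolerance = 1e-10)
  expect_lt(fit$p, 1e-12)
  # constant counts: alpha 0, p ~ 1
  fit0 <- fitFitness(rbind(rep(500, 4)), days)
  expect_equal(fit0$alpha, 0, tolerance = 1e-12)
  expect_equal(fit0$p, 1)
  # two guides with different abundances share the slope
  x2 <- rbind(1000 * exp(-0.1 * days), 200 * exp(-0.1 * days))
  expect_equal(fitFitness(x2, days)$alpha, -0.1, tolerance = 1e-10)
  expect_error(fitFitness(matrix(0, 2, 4), days), "all-zero")
  expect_error(fitFitness(rbind(c(1000, 0, 0, 0)), days), "2 distinct timepoints")
})

test_that("fitness slope equals the normal-equations oracle", {
  set.seed(31)
  for (i in 1:20) {
    ng <- sample(2:6, 1); reps <- sample(2:3, 1)
    days <- c(0, 8, 15, 22)
    sim <- simRegionCounts(runif(1, -0.2, 0.05), nGuides = ng, reps = reps,
                           days = days)
    x <- sim$counts + 0.5
    fit <- fitFitness(x, sim$days, pseudocount = 0)
    y <- log(as.vector(x))
    g <- rep(seq_len(ng), times = length(sim$days))
    t <- rep(sim$days, each = ng)
    expect_equal(fit$alpha, unname(olsSlopeOracle(y, g, t)), tolerance = 1e-8)
  }
})

test_that("fitFitnessAll maps guides to regions per cell line", {
  lib <- makeTestLibrary(nRegions = 4, nGuides = 5, nNT = 20)
  cfg <- screenSimConfig(nRegions = 4, fracCommon = 0.5, fracLineage = 0.25,
                         seed = 17, depthSd = 0)
  sim <- simulateScreen(lib, cfg)
  nt <- grep("^NT", rownames(sim$se), value = TRUE)
  norm <- normalizeToControls(sim$se, nt)
  fit <- fitFitnessAll(norm, lib)
  expect_equal(nrow(fit), 4 * 4)
  expect_setequal(unique(fit$cell_line), cfg@cellLines)
  expect_true(all(fit$se >= 0))
  expect_true(all(fit$p >= 0 & fit$p <= 1))
  # planted common hits come out negative where planted
  tr <- sim$truth[!duplicated(sim$truth$union_id) & !is.na(sim$truth$union_id), ]
  for (uid in tr$union_id[tr$category == "common"]) {
    sub <- fit[fit$union_id == uid, ]
    expect_true(all(sub$alpha < 0))
  }
})
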
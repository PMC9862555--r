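beadTube <- function(n_cluster, n_noise, mean = 3e4, sd = 2e3, seed = 5) {
  withr::with_seed(seed, {
    m <- cbind(
      `FSC-A` = c(rnorm(n_cluster, mean, sd),
                  runif(n_noise, 0, 2.6e5)),
      `SSC-A` = c(rnorm(n_cluster, 1.5e4, 1.5e3),
                  runif(n_noise, 0, 2.6e5)))
    m <- pmin(pmax(m, 0), 262144)
    flowEventTable(m, roles = c(`FSC-A` = "FSC-A", `SSC-A` = "SSC-A"))
  })
}

test_that("bead threshold sits at the lower contour of the dominant cluster", {
  fsc_min <- findBeadThreshold(beadTube(4500, 500), seed = 1)
  expect_equal(fsc_min, 3e4 - qnorm(0.995) * 2e3, tolerance = 0.04)
  # tight cluster, zero noise: threshold within one contour step of the
  # observed cluster minimum
  tight <- beadTube(3000, 0, sd = 200)
  fm <- findBeadThreshold(tight, seed = 1)
  expect_lt(fm, 3e4)
  expect_lte(abs(fm - min(chan(tight, "FSC-A"))), qnorm(0.995) * 200)
})

test_that("a bead tube with no dominant cluster fails QC", {
  expect_error(findBeadThreshold(beadTube(0, 3000), seed = 1),
               "bead tube QC failure")
})

test_that("the BSE gate is closed on the kept side", {
  cfg <- gateConfig()
  t <- miniTube(4, fsc_a = c(2.5e5, 1e4, 5e4, 5e4),
                ssc_a = c(0.1, 2e4, 2.5e5, 2.55e5))
  mask <- bseGate(t, fsc_min = 2e4, cfg)
  expect_identical(mask, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("BSE gate keeps the planted in-gate fraction", {
  fx <- gatedSample("non-cancer", seed = 1)
  truth <- fx$truth
  in_gate_truth <- !truth$population %in% "debris"
  kept <- mean(gateMask(fx$gating, "bead_size_exclusion"))
  # debris mostly falls below the bead threshold; everything else stays
  expect_equal(kept, mean(in_gate_truth), tolerance = 0.03)
})

test_that("corner artifacts are removed when planted and untouched otherwise", {
  clean <- gatedSample("non-cancer", seed = 3)
  bse <- gateMask(clean$gating, "bead_size_exclusion")
  expect_identical(gateMask(clean$gating, "non_debris"), bse)
  planted <- gatedSample("non-cancer", seed = 3, corner_fraction = 0.05)
  bse_p <- bseGate(planted$tubes$blood, planted$gating@fscMin, gateConfig())
  res <- excludeCornerArtifacts(planted$tubes$blood, bse_p, seed = 3)
  is_corner <- planted$truth$population == "corner"
  removed <- bse_p & !res$mask
  expect_true(res$applied)
  expect_gte(sum(removed & is_corner) / sum(bse_p & is_corner), 0.95)
  expect_lte(sum(removed & !is_corner) / sum(bse_p & !is_corner), 0.01)
})

test_that("core viable gate picks the low-scatter component at the right contour", {
  cfg <- gateConfig()
  set.seed(21)
  n <- 8000
  lowsc <- cbind(rnorm(0.6 * n, 5e4, 5e3), rnorm(0.6 * n, 1.5e4, 2e3))
  highsc <- cbind(rnorm(0.4 * n, 1.3e5, 1e4), rnorm(0.4 * n, 8e4, 8e3))
  m <- rbind(lowsc, highsc)
  t <- flowEventTable(
    cbind(`FSC-H` = pmax(m[, 1], 0), `SSC-H` = pmax(m[, 2], 0)),
    roles = c(`FSC-H` = "FSC-H", `SSC-H` = "SSC-H"))
  res <- coreViableGate(t, rep(TRUE, n), cfg, seed = 1)
  is_low <- seq_len(n) <= 0.6 * n
  expect_false(res$fallback)
  expect_gte(mean(res$mask[is_low]), 0.9 * cfg$core_quantile)
  expect_lt(mean(res$mask[!is_low]), 0.10)
})

test_that("a small core population triggers the inclusive fallback quantile", {
  set.seed(22)
  n <- 8000
  m <- rbind(cbind(rnorm(0.08 * n, 3e4, 3e3), rnorm(0.08 * n, 8e3, 1e3)),
             cbind(rnorm(0.92 * n, 1.3e5, 1.2e4), rnorm(0.92 * n, 7e4, 7e3)))
  t <- flowEventTable(
    cbind(`FSC-H` = pmax(m[, 1], 0), `SSC-H` = pmax(m[, 2], 0)),
    roles = c(`FSC-H` = "FSC-H", `SSC-H` = "SSC-H"))
  res <- coreViableGate(t, rep(TRUE, n), gateConfig(), seed = 1)
  expect_true(res$fallback)
})

test_that("a single homogeneous population is captured at the core quantile", {
  set.seed(23)
  n <- 6000
  t <- flowEventTable(
    cbind(`FSC-H` = rnorm(n, 6e4, 6e3), `SSC-H` = rnorm(n, 2e4, 2.5e3)),
    roles = c(`FSC-H` = "FSC-H", `SSC-H` = "SSC-H"))
  res <- coreViableGate(t, rep(TRUE, n), gateConfig(), seed = 1)
  expect_equal(mean(res$mask), 0.90, tolerance = 0.05)
})

test_that("the tail gate matches the closed-form Gaussian position", {
  cfg <- gateConfig()
  m <- 1.5; s <- 0.3
  set.seed(24)
  t <- miniTube(20000, fvs = rnorm(20000, m, s))
  thr <- viabilityThreshold(t, rep(TRUE, 20000), cfg)
  expect_lt(abs(thr - (m + s * sqrt(2 * log(1 / cfg$tail_tolerance)))), 0.05)
  # limiting case: tolerance 1 places the threshold at the mode
  thr1 <- viabilityThreshold(t, rep(TRUE, 20000),
                             gateConfig(tail_tolerance = 1))
  expect_lt(abs(thr1 - m), 0.05)
  # raising the tolerance never raises the threshold
  thrs <- vapply(c(0.05, 0.1, 0.2, 0.5, 1),
                 function(tt) viabilityThreshold(
                   t, rep(TRUE, 20000), gateConfig(tail_tolerance = tt)), 0)
  expect_false(is.unsorted(rev(thrs)))
})

test_that("the tail gate separates well-separated live/dead modes", {
  set.seed(25)
  fvs <- c(rnorm(15000, 1.0, 0.2), rnorm(5000, 3.4, 0.25))
  t <- miniTube(20000, fvs = fvs)
  thr <- viabilityThreshold(t, rep(TRUE, 20000), gateConfig())
  expect_gt(thr, 1.0); expect_lt(thr, 3.0)
  expect_gte(mean(fvs[1:15000] <= thr), 0.99)
  expect_error(viabilityThreshold(miniTube(200, fvs = rep(2, 200)),
                                  rep(TRUE, 200), gateConfig()),
               "degenerate")
})

test_that("singlets polygon captures the ridge and rejects doublets", {
  set.seed(26)
  n_s <- 9000; n_d <- 1000
  a_s <- rlnorm(n_s, log(8e4), 0.2)
  a_d <- 2 * rlnorm(n_d, log(8e4), 0.2)
  x <- c(a_s, a_d)
  y <- c(a_s * rnorm(n_s, 0.88, 0.03), a_d / 2 * rnorm(n_d, 0.88, 0.03))
  t <- miniTube(n_s + n_d, fsc_a = pmin(x, 2.5e5), fsc_w = pmax(y, 0))
  res <- fitSingletsPolygon(t, rep(TRUE, n_s + n_d), gateConfig(), seed = 1)
  expect_length(res$tags, 0)
  expect_gte(mean(res$mask[1:n_s]), 0.95)
  expect_lte(mean(res$mask[(n_s + 1):(n_s + n_d)]), 0.10)
})

test_that("a high-SSC contaminant triggers the temporary-gate repair", {
  fx <- gatedSample("non-cancer", seed = 6, contaminant_fraction = 0.35)
  expect_true("ssc_temp_gate" %in% heuristicsApplied(fx$gating))
  expect_gte(fx$gating@singletsPolygon[1, 2], 0)
  # the repaired gate still recovers the planted singlet ridge
  vs <- gateMask(fx$gating, "viable_singlets")
  live_singlet <- fx$truth$live & fx$truth$singlet
  expect_gte(mean(vs[live_singlet]), 0.9)
  expect_lte(mean(vs[fx$truth$population == "contaminant"]), 0.10)
})

test_that("viability refinement resets the threshold for an intermediate population", {
  set.seed(27)
  n <- 10000
  fvs <- c(rnorm(0.85 * n, 1.4, 0.25), rnorm(0.15 * n, 3.0, 0.12))
  fsc <- rlnorm(n, log(8e4), 0.15)
  t <- miniTube(n, fvs = fvs, fsc_a = pmin(fsc, 2.5e5))
  res <- refineViability(t, rep(TRUE, n), threshold = 3.5, gateConfig(),
                         seed = 1)
  expect_equal(res$threshold, 2.5)
  expect_true("viability_reset" %in% res$tags)
  # at 5% the trigger fraction is not met
  fvs2 <- c(rnorm(0.95 * n, 1.4, 0.25), rnorm(0.05 * n, 3.0, 0.12))
  t2 <- miniTube(n, fvs = fvs2, fsc_a = pmin(fsc, 2.5e5))
  res2 <- refineViability(t2, rep(TRUE, n), threshold = 3.5, gateConfig(),
                          seed = 1)
  expect_equal(res2$threshold, 3.5)
  expect_length(res2$tags, 0)
  # nothing above the natural cutoff: inputs returned unchanged
  res3 <- refineViability(t, rep(TRUE, n), threshold = 2.0, gateConfig(),
                          seed = 1)
  expect_equal(res3$threshold, 2.0)
})

test_that("the full cascade nests its masks and is deterministic", {
  fx <- gatedSample("non-cancer", seed = 7, n_events = 25000L)
  g <- fx$gating
  m <- g@masks
  expect_true(all(!m$viable_singlets | m$viable))
  expect_true(all(!m$viable | m$non_debris))
  expect_true(all(!m$non_debris | m$bead_size_exclusion))
  expect_gte(gateCounts(g)[["viable_singlets"]], 10000)
  g2 <- runGating(fx$tubes, "blood", gateConfig(), seed = 7)
  expect_identical(g@masks, g2@masks)
  expect_identical(viabilityCutoff(g), viabilityCutoff(g2))
  expect_identical(g@singletsPolygon, g2@singletsPolygon)
})

test_that("an all-dead sample yields (almost) no viable singlets", {
  spec <- sampleSpec("non-cancer", n_events = 15000L,
                     fractions = c(debris = 0.05, dead = 0.88,
                                   doublet = 0.02, leukocyte = 0.02,
                                   macrophage = 0.01))
  smp <- generateSample("non-cancer", spec = spec, seed = 8)
  tubes <- smp$tubes
  tubes$blood <- logicleTube(compensate(tubes$blood, smp$spillover))
  res <- tryCatch(runGating(tubes, "blood", seed = 8), error = identity)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "gating stage")
  } else {
    expect_lt(gateCounts(res)[["viable_singlets"]], 10000)
  }
})
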
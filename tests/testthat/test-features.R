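test_that("density regions follow the printed boundary conventions", {
  # all events at exactly r = 0.5 fall in R2
  sc <- rep(1e4, 500)  # log10 = 4
  t <- miniTube(500, tcpp = rep(2, 500), ssc_a = sc)
  out <- densityRegionCounts(t, rep(TRUE, 500), "TCPP", "SSC-A")
  expect_equal(unname(out), c(0, 10000, 0))
  # boundary values land closed in R2, open outside
  r_vals <- c(0.249, 0.25, 0.45, 0.6, 0.601)
  t2 <- miniTube(5, tcpp = r_vals * 4, ssc_a = rep(1e4, 5))
  out2 <- densityRegionCounts(t2, rep(TRUE, 5), "TCPP", "SSC-A")
  expect_equal(unname(out2), c(1, 3, 1) / 5 * 10000)
})

test_that("vectorised density counts equal a per-event scalar loop", {
  set.seed(31)
  for (rep_i in 1:3) {
    n <- 1000
    sc <- rlnorm(n, log(2e4), 0.3)
    fl <- runif(n, 0, 1.2) * log10(sc)
    t <- miniTube(n, tcpp = fl, ssc_a = pmin(sc, 2.5e5))
    out <- densityRegionCounts(t, rep(TRUE, n), "TCPP", "SSC-A")
    # independent scalar tabulation
    cnt <- c(0, 0, 0)
    for (i in seq_len(n)) {
      r <- fl[i] / log10(pmin(sc, 2.5e5)[i])
      j <- if (r < 0.25) 1 else if (r <= 0.6) 2 else 3
      cnt[j] <- cnt[j] + 1
    }
    expect_equal(unname(out), cnt / n * 10000)
    expect_equal(sum(out), 10000)
  }
  expect_error(densityRegionCounts(miniTube(10), rep(FALSE, 10), "TCPP",
                                   "SSC-A"), "no viable singlets")
})

test_that("grid counts are lower-closed, conserved, and uniform when planted so", {
  # all events at (1.0, 1.0): low/low cell holds all 10,000 per-10K units
  t <- miniTube(100, cd206 = rep(1, 100), lineage = rep(1, 100))
  g <- gridCounts(t, rep(TRUE, 100), "CD206", "LINEAGE")
  expect_equal(unname(g["low", "low"]), 10000)
  expect_equal(sum(g), 10000)
  # window edges: 1.5 belongs to lowmid, 2.5 to mid, 3 to high
  t2 <- miniTube(3, cd206 = c(1.5, 2.5, 3), lineage = c(1, 1, 1))
  g2 <- gridCounts(t2, rep(TRUE, 3), "CD206", "LINEAGE")
  expect_equal(unname(c(g2["lowmid", "low"], g2["mid", "low"],
                        g2["high", "low"])), rep(10000 / 3, 3))
  # planted uniform occupancy: every cell near 625
  set.seed(32)
  n <- 40000
  rw <- function(n) {
    w <- sample(4, n, replace = TRUE)
    c(0.5, 1.5, 2.5, 3)[w] + runif(n) * c(1, 1, 0.5, 1)[w]
  }
  t3 <- miniTube(n, cd206 = rw(n), lineage = rw(n))
  g3 <- gridCounts(t3, rep(TRUE, n), "CD206", "LINEAGE")
  expect_equal(sum(g3), 10000)
  expect_true(all(abs(g3 - 625) < 4 * sqrt(625)))
})

test_that("per-10K features are invariant to duplicating every event", {
  fx <- gatedSample("non-cancer", seed = 1)
  t <- fx$tubes$blood
  vs <- gateMask(fx$gating, "viable_singlets")
  d1 <- densityRegionCounts(t, vs, "TCPP", "SSC-A")
  g1 <- gridCounts(t, vs, "CD206", "LINEAGE")
  idx <- rep(seq_len(nEvents(t)), each = 2)
  t2 <- t[idx]
  vs2 <- rep(vs, each = 2)
  expect_equal(densityRegionCounts(t2, vs2, "TCPP", "SSC-A"), d1)
  expect_equal(gridCounts(t2, vs2, "CD206", "LINEAGE"), g1)
})

test_that("eligibility boundaries follow the 10,000-singlet and 10-macrophage rules", {
  mkGating <- function(t, n_vs) {
    n <- nEvents(t)
    vs <- c(rep(TRUE, n_vs), rep(FALSE, n - n_vs))
    masks <- list(bead_size_exclusion = rep(TRUE, n),
                  non_debris = rep(TRUE, n), viable = rep(TRUE, n),
                  viable_singlets = vs)
    new("GatingResult", masks = masks, fscMin = 2e4,
        viabilityThreshold = 1.5,
        singletsPolygon = matrix(0, 4, 2), heuristics = character(),
        counts = vapply(masks, sum, integer(1)), seed = 1L)
  }
  n <- 12000
  # 9,999 viable singlets: not eligible even with plenty of macrophages
  t <- miniTube(n, cd206 = rep(3.2, n), lineage = rep(1.8, n))
  out <- extractFeatures(mkGating(t, 9999L), t, age = 60)
  expect_false(out$eligibility$enough_singlets)
  expect_false(out$eligibility$eligible)
  # exactly 9 macrophage-window events: lung not confirmed
  cd206 <- c(rep(3.2, 9), rep(0.8, n - 9))
  lin <- c(rep(1.8, 9), rep(2.7, n - 9))
  t2 <- miniTube(n, cd206 = cd206, lineage = lin)
  out2 <- extractFeatures(mkGating(t2, 10500L), t2, age = 60)
  expect_equal(out2$features[["macrophages"]], 9)
  expect_false(out2$eligibility$lung_confirmed)
  expect_false(out2$eligibility$eligible)
  # 10 macrophages and 10,000 singlets: eligible
  cd206[10] <- 3.2; lin[10] <- 1.8
  t3 <- miniTube(n, cd206 = cd206, lineage = lin)
  out3 <- extractFeatures(mkGating(t3, 10000L), t3, age = 60)
  expect_true(out3$eligibility$eligible)
})

test_that("a cancer-profile sample recovers the planted TCPP-bright rate", {
  fx <- gatedSample("cancer", seed = 9, n_events = 25000L)
  out <- extractFeatures(fx$gating, fx$tubes$blood, age = 70)
  expect_gt(out$features[["tcpp_r3_per10k"]], 320)
  expect_lt(out$features[["tcpp_r3_per10k"]], 480)
})
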
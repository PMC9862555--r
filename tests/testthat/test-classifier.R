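# cohort drawn from known logistic coefficients, for recovery oracles
logisticCohort <- function(n, beta, seed) {
  withr::with_seed(seed, {
    X <- data.frame(age = rnorm(n, 65, 8),
                    tcpp_r3_per10k = rnorm(n, 200, 80),
                    fvs_r2_per10k = rnorm(n, 700, 250),
                    cd206low_linmid_per10k = rnorm(n, 2800, 500))
    eta <- beta[1] + beta[2] * X$age + beta[3] * X$tcpp_r3_per10k +
      beta[4] * X$fvs_r2_per10k + beta[5] * X$cd206low_linmid_per10k +
      beta[6] * X$age * X$fvs_r2_per10k
    list(X = X, y = rbinom(n, 1, plogis(eta)))
  })
}

TRUE_BETA <- c(-2, 0.03, 0.008, 0.001, -5e-4, -1e-5)

test_that("probability is the inverse logit of the five-term linear predictor", {
  zero <- new("SputumClassifier",
              coefficients = setNames(rep(0, 6), sputumFlow:::MODEL_TERMS),
              se = setNames(rep(1, 6), sputumFlow:::MODEL_TERMS),
              p = setNames(rep(1, 6), sputumFlow:::MODEL_TERMS),
              cutoff = 0.5)
  f <- c(age = 65, tcpp_r3_per10k = 100, fvs_r2_per10k = 500,
         cd206low_linmid_per10k = 2500)
  expect_equal(predictProbability(zero, f), 0.5)
  # linear predictor 1.386 maps to probability 0.8
  m <- zero
  m@coefficients["(Intercept)"] <- 1.386
  expect_equal(predictProbability(m, f), plogis(1.386), tolerance = 1e-12)
  expect_equal(plogis(1.386), 0.8, tolerance = 1e-3)
  # positive TCPP coefficient: probability strictly increases with tcpp_r3
  m2 <- zero
  m2@coefficients["tcpp_r3_per10k"] <- 0.01
  probs <- vapply(c(0, 100, 200, 400), function(v) {
    f2 <- f; f2["tcpp_r3_per10k"] <- v
    predictProbability(m2, f2)
  }, 0)
  expect_true(all(diff(probs) > 0))
  # a non-eligible sample is refused, never scored
  expect_error(predictProbability(m, f, eligible = FALSE), "QC failure")
})

test_that("calls use a strictly-greater-than cutoff", {
  expect_equal(classifyCall(0.28, 0.28), "non-cancer")
  expect_equal(classifyCall(0.281, 0.28), "cancer")
  expect_equal(classifyCall(0, 0.9), "non-cancer")
  expect_equal(classifyCall(1, 0.5), "cancer")
})

test_that("the fit recovers known coefficients within 3 standard errors", {
  coh <- logisticCohort(500, TRUE_BETA, seed = 41)
  m <- fitLogistic(coh$X, coh$y)
  z <- abs(modelCoefficients(m) - TRUE_BETA) / m@se
  expect_true(all(z < 3))
  # refitting the same data reproduces coefficients bit-identically
  m2 <- fitLogistic(coh$X, coh$y)
  expect_identical(modelCoefficients(m), modelCoefficients(m2))
})

test_that("monotonicity in each feature follows the coefficient signs", {
  coh <- logisticCohort(500, TRUE_BETA, seed = 42)
  m <- fitLogistic(coh$X, coh$y)
  b <- modelCoefficients(m)
  base <- c(age = 65, tcpp_r3_per10k = 200, fvs_r2_per10k = 700,
            cd206low_linmid_per10k = 2800)
  for (v in c("tcpp_r3_per10k", "cd206low_linmid_per10k")) {
    f1 <- base; f2 <- base; f2[v] <- f2[v] + 100
    d <- predictProbability(m, f2) - predictProbability(m, f1)
    expect_equal(sign(d), sign(b[[v]]))
  }
  # for fvs_r2 the effective slope is b3 + b5 * age
  f1 <- base; f2 <- base; f2["fvs_r2_per10k"] <- f2["fvs_r2_per10k"] + 100
  d <- predictProbability(m, f2) - predictProbability(m, f1)
  expect_equal(sign(d), sign(b[["fvs_r2_per10k"]] +
                               b[["age:fvs_r2_per10k"]] * 65))
})

test_that("Wald type-I error is near nominal under the null", {
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    coh <- withr::with_seed(500 + r, {
      X <- data.frame(age = rnorm(500, 65, 8),
                      tcpp_r3_per10k = rnorm(500, 200, 80),
                      fvs_r2_per10k = rnorm(500, 700, 250),
                      cd206low_linmid_per10k = rnorm(500, 2800, 500))
      list(X = X, y = rbinom(500, 1, 0.3))
    })
    m <- fitLogistic(coh$X, coh$y)
    if (m@p[["tcpp_r3_per10k"]] < 0.05) hits <- hits + 1L
  }
  # binomial 95% band around 5% of 50 replicates
  expect_lte(hits, qbinom(0.995, n_rep, 0.05))
})

test_that("perfect symmetry gives a near-zero intercept, separation is flagged", {
  # mirrored design with flipped labels: the likelihood is symmetric in the
  # intercept, so b0 should sit within its own standard error of zero
  half <- withr::with_seed(66, {
    X <- data.frame(age = rnorm(150, 0, 8),
                    tcpp_r3_per10k = rnorm(150, 0, 80),
                    fvs_r2_per10k = rnorm(150, 0, 250),
                    cd206low_linmid_per10k = rnorm(150, 0, 500))
    list(X = X, y = rbinom(150, 1, plogis(0.08 * X$age)))
  })
  X <- rbind(half$X, -half$X)
  y <- c(half$y, 1 - half$y)
  m <- fitLogistic(X, y)
  b0 <- modelCoefficients(m)[["(Intercept)"]]
  expect_lt(abs(b0), 3 * m@se[["(Intercept)"]])
  expect_lt(abs(b0), 0.2)
  # complete separation on age is flagged and handled by the ridge fallback
  Xs <- withr::with_seed(67, data.frame(
    age = c(rnorm(20, 50, 3), rnorm(20, 80, 3)),
    tcpp_r3_per10k = rnorm(40, 200, 80),
    fvs_r2_per10k = rnorm(40, 700, 250),
    cd206low_linmid_per10k = rnorm(40, 2800, 500)))
  ms <- suppressWarnings(fitLogistic(Xs, rep(c(0, 1), each = 20)))
  expect_true(ms@separationFlag)
  expect_true(all(is.finite(modelCoefficients(ms))))
  expect_error(fitLogistic(Xs[1:3, ], c(0, 1, 1)), "2 samples per class")
  Xc <- Xs; Xc$tcpp_r3_per10k <- 100
  expect_error(suppressWarnings(fitLogistic(Xc, rep(c(0, 1), 20))),
               "constant predictor")
})

test_that("stepwise selection finds the informative candidates", {
  coh <- withr::with_seed(61, {
    n <- 400
    X <- as.data.frame(matrix(rnorm(n * 8), n, 8,
                              dimnames = list(NULL, paste0("v", 1:8))))
    eta <- -1.5 + 2.2 * X$v2 + 1.8 * X$v5
    list(X = X, y = rbinom(n, 1, plogis(eta)))
  })
  sel <- stepwiseSelect(coh$X, coh$y, n_splits = 25, split_size = 100,
                        cancer_per_split = 20, seed = 3)
  expect_gte(sel$frequency[["v2"]], 0.8)
  expect_gte(sel$frequency[["v5"]], 0.8)
  expect_true(all(c("v2", "v5") %in% sel$selected))
  noise_freq <- sel$frequency[setdiff(names(sel$frequency), c("v2", "v5"))]
  expect_true(all(noise_freq < 0.5))
  # all-noise candidates: nothing selected often
  null_coh <- withr::with_seed(62, {
    X <- as.data.frame(matrix(rnorm(400 * 6), 400, 6,
                              dimnames = list(NULL, paste0("n", 1:6))))
    list(X = X, y = rbinom(400, 1, 0.25))
  })
  sel0 <- stepwiseSelect(null_coh$X, null_coh$y, n_splits = 25,
                         split_size = 100, cancer_per_split = 20, seed = 4)
  expect_true(all(sel0$frequency <= 0.30))
  # determinism for a fixed seed
  sel1 <- stepwiseSelect(coh$X, coh$y, n_splits = 1, seed = 9)
  sel2 <- stepwiseSelect(coh$X, coh$y, n_splits = 1, seed = 9)
  expect_identical(sel1, sel2)
  expect_error(stepwiseSelect(coh$X[1:50, ], coh$y[1:50], n_splits = 2),
               "infeasible")
})

test_that("ROC stepping chooses a separating cutoff and integrates correctly", {
  # perfectly separated probabilities
  p <- c(runif(50, 0, 0.3), runif(50, 0.7, 1))
  y <- rep(c(0, 1), each = 50)
  cc <- chooseCutoff(p, y)
  expect_equal(cc$auc, 1.0)
  expect_gte(cc$cutoff, max(p[y == 0]) - 1e-12)
  expect_lt(cc$cutoff, min(p[y == 1]))
  # two-point distribution
  cc2 <- chooseCutoff(rep(c(0.1, 0.9), each = 50), rep(c(0, 1), each = 50))
  expect_gte(cc2$cutoff, 0.1); expect_lt(cc2$cutoff, 0.9)
  expect_equal(cc2$auc, 1.0)
  # null probabilities: AUC near one half
  cc3 <- withr::with_seed(63, chooseCutoff(runif(1000), rbinom(1000, 1, 0.3)))
  expect_lt(abs(cc3$auc - 0.5), 0.05)
  expect_error(chooseCutoff(runif(10), rep(1, 10)), "both classes")
})

test_that("the stepped ROC AUC matches the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(64)
  y <- rbinom(300, 1, 0.3)
  p <- plogis(rnorm(300, y * 1.2))
  ours <- chooseCutoff(p, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("dropping an informative predictor never helps on average", {
  # every predictor group (including the interaction) carries real signal
  strong <- c(-1, 0.06, 0.010, 0.0015, -0.0010, -1e-4)
  deltas <- sapply(1:20, function(s) {
    coh <- logisticCohort(400, strong, seed = 700 + s)
    tab <- ablationHarness(coh$X, coh$y)
    full <- tab$total_incorrect[tab$dropped == "none"]
    tab$total_incorrect[tab$dropped != "none"] - full
  })
  expect_true(all(rowMeans(deltas) >= 0))
})

test_that("models roundtrip through JSON", {
  coh <- logisticCohort(300, TRUE_BETA, seed = 65)
  m <- fitLogistic(coh$X, coh$y, cutoff = 0.28)
  path <- withr::local_tempfile(fileext = ".json")
  writeModel(m, path)
  m2 <- readModel(path)
  expect_equal(modelCoefficients(m2), modelCoefficients(m))
  expect_equal(modelCutoff(m2), 0.28)
})
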
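test_that("confusion rates match the development-cohort counts", {
  r <- confusionRates(tp = 23, fn = 5, tn = 107, fp = 15)
  expect_equal(unname(round(r[c("sensitivity", "specificity", "accuracy",
                                "ppv", "npv")], 3)),
               c(0.821, 0.877, 0.867, 0.605, 0.955))
  expect_equal(unname(confusionRates(1, 0, 1, 0)), rep(1, 5))
  r0 <- confusionRates(0, 1, 0, 1)
  expect_equal(unname(r0[c("sensitivity", "specificity")]), c(0, 0))
  expect_error(confusionRates(0, 0, 5, 5), "sensitivity")
})

test_that("Wilson intervals reproduce the published limits and prop.test", {
  expect_equal(unname(round(wilsonCI(23, 28), 2)), c(0.64, 0.92))
  expect_equal(unname(round(wilsonCI(107, 122), 2)), c(0.81, 0.92))
  expect_equal(wilsonCI(0, 10)[["lo"]], 0)
  # stats::prop.test without continuity correction is the Wilson interval
  for (kn in list(c(23, 28), c(107, 122), c(3, 10), c(55, 60))) {
    ref <- prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(unname(wilsonCI(kn[1], kn[2])), as.numeric(ref),
                 tolerance = 1e-10)
  }
  expect_error(wilsonCI(5, 3))
  # width shrinks monotonically with n at fixed k/n
  widths <- vapply(c(10, 40, 160, 640), function(n)
    diff(wilsonCI(round(0.8 * n), n)), 0)
  expect_true(all(diff(widths) < 0))
})

test_that("prevalence-adjusted predictive values match the published table", {
  sens <- 23 / 28; spec <- 107 / 122
  pv_hr <- predictiveValues(sens, spec, prevalence = 0.0083)
  expect_equal(unname(round(pv_hr[["ppv"]], 2)), 0.05)
  pv_ld <- predictiveValues(sens, spec, prevalence = 0.029,
                            n1 = 28, n0 = 122)
  expect_equal(unname(round(pv_ld[["ppv"]], 2)), 0.17)
  expect_equal(unname(round(pv_ld[["npv"]], 2)), 0.99)
  ci <- attr(pv_ld, "ppv_ci")
  expect_equal(unname(round(ci, 2)), c(0.11, 0.25))
  # an uninformative test returns the prevalence itself
  expect_equal(predictiveValues(0.5, 0.5, 0.2)[["ppv"]], 0.2)
  expect_error(predictiveValues(0.8, 0.9, 0), "strictly")
  # at the dataset prevalence, Bayes PPV/NPV equal the raw-count versions
  r <- confusionRates(23, 5, 107, 15)
  pv <- predictiveValues(r[["sensitivity"]], r[["specificity"]],
                         prevalence = 28 / 150)
  expect_equal(pv[["ppv"]], r[["ppv"]], tolerance = 1e-12)
  expect_equal(pv[["npv"]], r[["npv"]], tolerance = 1e-12)
})

test_that("PDLR is the sensitivity over false-positive-rate quotient", {
  expect_equal(pdlr(0.5, 0.5), 1.0)
  expect_equal(pdlr(0.9, 0.1), 1.0)
  expect_equal(round(pdlr(23 / 28, 107 / 122), 2), 6.68)
  expect_warning(v <- pdlr(0.8, 1), "infinite")
  expect_identical(v, Inf)
})

test_that("the ATS minimal-accuracy rule reproduces the policy examples", {
  expect_equal(round(atsMinPdlr(0.038, 0.048), 2), 1.28)
  expect_equal(round(atsMinPdlr(1 / 500, 0.0083), 2), 4.18)
  expect_equal(round(atsMinPdlr(1 / 400, 0.0083), 2), 3.34)
  expect_equal(atsMinPdlr(0.5, 0.5), 1.0)
  expect_error(atsMinPdlr(0, 0.5))
  # the development assay clears the intermediate-nodule threshold
  expect_true(pdlr(23 / 28, 107 / 122) >= atsMinPdlr(0.038, 0.048))
})

test_that("bootstrap AUC matches the binormal closed form", {
  expect_equal(unname(aucBootstrapCI(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
                                     n_boot = 100, seed = 1)),
               c(1, 1, 1))
  # AUC is a rank statistic: invariant under monotone transforms
  set.seed(71)
  y <- rep(c(0, 1), each = 1000)
  s <- c(rnorm(1000, 0), rnorm(1000, 1))
  a1 <- aucBootstrapCI(s, y, n_boot = 200, seed = 2)
  a2 <- aucBootstrapCI(plogis(3 * s), y, n_boot = 200, seed = 2)
  expect_equal(a1, a2, tolerance = 1e-12)
  # binormal scores at d = 1: AUC = pnorm(1/sqrt(2))
  expect_lt(abs(a1[["auc"]] - pnorm(1 / sqrt(2))), 0.02)
  expect_true(a1[["lo"]] <= a1[["auc"]] && a1[["auc"]] <= a1[["hi"]])
  expect_error(aucBootstrapCI(runif(10), rep(0, 10), 100), "both classes")
})

test_that("training-split combinatorics give the exact binomial coefficient", {
  expect_equal(trainingSplitCount(28, 20), 3108105)
  expect_gt(trainingSplitCount(28, 20), 3e6)
  expect_equal(trainingSplitCount(7, 0), 1)
  expect_equal(trainingSplitCount(7, 7), 1)
  expect_error(trainingSplitCount(5, 6), "cannot draw")
})

test_that("the diagnostic report is internally consistent and exportable", {
  set.seed(72)
  y <- rep(c(0, 1), c(122, 28))
  p <- plogis(rnorm(150, -1 + 2.5 * y))
  calls <- classifyCall(p, 0.5)
  rep <- diagnosticReport(calls, y, probabilities = p, n_boot = 200,
                          seed = 1)
  with(as.list(rep$counts), {
    expect_equal(tp + fn, 28)
    expect_equal(tn + fp, 122)
  })
  r2 <- confusionRates(rep$counts[["tp"]], rep$counts[["fn"]],
                       rep$counts[["tn"]], rep$counts[["fp"]])
  expect_equal(rep$rates, r2)
  expect_true(all(vapply(rep$ci, function(ci)
    ci[["lo"]] <= ci[["hi"]], TRUE)))
  path <- withr::local_tempfile(fileext = ".csv")
  writeDiagnosticCSV(rep, path)
  tab <- read.csv(path)
  expect_true("pdlr" %in% tab$metric)
  expect_output(print(rep), "DiagnosticReport")
})
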
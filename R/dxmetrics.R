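#' Confusion-matrix rates
#'
#' @param tp,fn,tn,fp non-negative confusion counts (cancer = positive).
#' @return named numeric: sensitivity, specificity, accuracy, ppv, npv.
#' @examples
#' confusionRates(tp = 23, fn = 5, tn = 107, fp = 15)
#' @export
confusionRates <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn == 0) stop("undefined sensitivity: no condition-positive samples")
  if (tn + fp == 0) stop("undefined specificity: no condition-negative samples")
  if (tp + fp == 0) stop("undefined ppv: no positive calls")
  if (tn + fn == 0) stop("undefined npv: no negative calls")
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fn + tn + fp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes; \code{n} trials; \code{confidence} coverage (0.95).
#' @param n trials.
#' @param confidence coverage level.
#' @return named numeric \code{c(lo, hi)}.
#' @examples
#' round(wilsonCI(23, 28), 2)  # 0.64 0.92
#' @export
wilsonCI <- function(k, n, confidence = 0.95) {
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n, n > 0")
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(center - half, 0), hi = min(center + half, 1))
}

#' Prevalence-adjusted predictive values
#'
#' Bayes-theorem PPV and NPV at an external prevalence, with logit-scale
#' confidence intervals in the style of Mercaldo et al. (variance from the
#' study's sensitivity/specificity counts; a zero cell falls back to a 0.5
#' continuity correction).
#'
#' @param sensitivity,specificity test operating characteristics in (0, 1).
#' @param prevalence external disease prevalence in (0, 1).
#' @param n1,n0 optional condition-positive / condition-negative sample
#'   sizes behind the sensitivity and specificity; when supplied,
#'   logit-scale CIs are returned as attributes \code{"ppv_ci"} and
#'   \code{"npv_ci"}.
#' @param confidence coverage level for the CIs.
#' @return named numeric \code{c(ppv, npv)} (with CI attributes when n1/n0
#'   given).
#' @examples
#' predictiveValues(23/28, 107/122, prevalence = 0.029)
#' @export
predictiveValues <- function(sensitivity, specificity, prevalence,
                             n1 = NULL, n0 = NULL, confidence = 0.95) {
  if (any(c(sensitivity, specificity, prevalence) <= 0) ||
      any(c(sensitivity, specificity, prevalence) >= 1))
    stop("sensitivity, specificity and prevalence must lie strictly in (0, 1)")
  se <- sensitivity; sp <- specificity; p <- prevalence
  ppv <- se * p / (se * p + (1 - sp) * (1 - p))
  npv <- sp * (1 - p) / (sp * (1 - p) + (1 - se) * p)
  out <- c(ppv = ppv, npv = npv)
  if (!is.null(n1) && !is.null(n0)) {
    z <- qnorm(1 - (1 - confidence) / 2)
    cc <- function(k, n) if (k == 0 || k == n) (k + 0.5) / (n + 1) else k / n
    se_c <- cc(round(se * n1), n1); sp_c <- cc(round(sp * n0), n0)
    v_ppv <- (1 - se_c) / (se_c * n1) + sp_c / ((1 - sp_c) * n0)
    v_npv <- se_c / ((1 - se_c) * n1) + (1 - sp_c) / (sp_c * n0)
    lg <- function(x, v) plogis(qlogis(x) + c(-1, 1) * z * sqrt(v))
    attr(out, "ppv_ci") <- setNames(lg(ppv, v_ppv), c("lo", "hi"))
    attr(out, "npv_ci") <- setNames(lg(npv, v_npv), c("lo", "hi"))
  }
  out
}

#' Positive diagnostic likelihood ratio
#'
#' @param sensitivity,specificity rates in [0, 1], specificity < 1 for a
#'   finite value.
#' @return sensitivity / (1 - specificity); \code{Inf} (with a warning) at
#'   specificity 1.
#' @export
pdlr <- function(sensitivity, specificity) {
  if (specificity >= 1) {
    warning("specificity = 1: PDLR is infinite")
    return(Inf)
  }
  sensitivity / (1 - specificity)
}

#' ATS minimal-accuracy PDLR threshold
#'
#' The American Thoracic Society policy statement puts the minimal useful
#' accuracy of a diagnostic biomarker at PDLR >= ((1 - prevalence) /
#' prevalence) x (R / (1 - R)), where R is the harm/benefit threshold above
#' which invasive follow-up is worthwhile.
#'
#' @param prevalence disease prevalence in (0, 1).
#' @param R harm threshold in (0, 1).
#' @return the minimal PDLR.
#' @examples
#' round(atsMinPdlr(0.038, 0.048), 2)   # 1.28
#' round(atsMinPdlr(1/500, 0.0083), 2)  # 4.18
#' @export
atsMinPdlr <- function(prevalence, R) {
  if (prevalence <= 0 || prevalence >= 1 || R <= 0 || R >= 1)
    stop("prevalence and R must lie strictly in (0, 1)")
  (1 - prevalence) / prevalence * (R / (1 - R))
}

# rank-based (Mann-Whitney) AUC; equals the trapezoid ROC area with ties
# counted half
rankAUC <- function(probabilities, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(probabilities)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' Trapezoid AUC with a percentile interval over class-stratified bootstrap
#' resamples.
#'
#' @param probabilities model outputs; \code{labels} binary truth.
#' @param labels binary truth (1 = cancer).
#' @param n_boot bootstrap replicates (>= 100; default 2000).
#' @param confidence coverage level.
#' @param seed integer seed.
#' @return named numeric \code{c(auc, lo, hi)}.
#' @export
aucBootstrapCI <- function(probabilities, labels, n_boot = 2000L,
                           confidence = 0.95, seed = 1L) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  stopifnot(n_boot >= 100L)
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  auc <- rankAUC(probabilities, y)
  boots <- withSeed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    rankAUC(probabilities[idx], y[idx])
  }, 0))
  qs <- quantile(boots, c((1 - confidence) / 2, 1 - (1 - confidence) / 2),
                 names = FALSE)
  c(auc = auc, lo = qs[1L], hi = qs[2L])
}

#' Exact count of distinct cancer strata for training splits
#'
#' The binomial coefficient C(n, k): how many distinct ways the cancer
#' samples of a cohort can populate a fixed-size training split - a lower
#' bound on the number of distinct training sets.
#'
#' @param n_cancer_total cancer samples available.
#' @param n_cancer_per_split cancer samples per training split.
#' @return exact integer-valued numeric.
#' @examples
#' trainingSplitCount(28, 20)  # 3108105
#' @export
trainingSplitCount <- function(n_cancer_total, n_cancer_per_split) {
  n <- n_cancer_total; k <- n_cancer_per_split
  if (k > n) stop("cannot draw ", k, " cancer samples from ", n)
  if (k < 0 || n < 0) stop("counts must be non-negative")
  round(choose(n, k))
}

#' Assemble a diagnostic accuracy report
#'
#' Confusion counts, rates with Wilson CIs, bootstrap AUC, PPV/NPV at the
#' dataset prevalence and at external prevalences (Mercaldo-style logit
#' CIs), and the PDLR - the full Table-of-performance layout.
#'
#' @param calls character vector of \code{"cancer"}/\code{"non-cancer"}
#'   calls (or logical).
#' @param labels binary truth (1 = cancer).
#' @param probabilities optional model outputs for the AUC block.
#' @param external_prevalences named numeric of additional prevalences.
#' @param n_boot,seed bootstrap settings.
#' @return list of class \code{"DiagnosticReport"}.
#' @export
diagnosticReport <- function(calls, labels, probabilities = NULL,
                             external_prevalences = c(
                               high_risk = 0.0083, ldct_positive = 0.029),
                             n_boot = 2000L, seed = 1L) {
  y <- as.integer(as.logical(labels))
  pos <- if (is.character(calls)) calls == "cancer" else as.logical(calls)
  tp <- sum(pos & y == 1L); fn <- sum(!pos & y == 1L)
  tn <- sum(!pos & y == 0L); fp <- sum(pos & y == 0L)
  r <- confusionRates(tp, fn, tn, fp)
  n1 <- tp + fn; n0 <- tn + fp
  rep <- list(
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
    rates = r,
    ci = list(sensitivity = wilsonCI(tp, n1),
              specificity = wilsonCI(tn, n0),
              accuracy = wilsonCI(tp + tn, n1 + n0)),
    pdlr = suppressWarnings(pdlr(r[["sensitivity"]], r[["specificity"]])),
    prevalence = n1 / (n1 + n0),
    predictive = lapply(external_prevalences, function(p) tryCatch(
      predictiveValues(r[["sensitivity"]], r[["specificity"]], p,
                       n1 = n1, n0 = n0),
      # degenerate (perfect) rates: report the Bayes limit without CIs
      error = function(e) c(
        ppv = if (r[["specificity"]] >= 1) 1 else
          r[["sensitivity"]] * p /
            (r[["sensitivity"]] * p + (1 - r[["specificity"]]) * (1 - p)),
        npv = if (r[["sensitivity"]] >= 1) 1 else
          r[["specificity"]] * (1 - p) /
            (r[["specificity"]] * (1 - p) + (1 - r[["sensitivity"]]) * p)))))
  if (!is.null(probabilities))
    rep$auc <- aucBootstrapCI(probabilities, y, n_boot = n_boot, seed = seed)
  class(rep) <- "DiagnosticReport"
  rep
}

#' @export
print.DiagnosticReport <- function(x, ...) {
  cat("DiagnosticReport\n")
  with(as.list(x$counts), cat(sprintf(
    "  tp=%d fn=%d tn=%d fp=%d (prevalence %.3f)\n", tp, fn, tn, fp,
    x$prevalence)))
  for (nm in c("sensitivity", "specificity", "accuracy")) {
    ci <- x$ci[[nm]]
    cat(sprintf("  %-12s %.2f (%.2f-%.2f)\n", nm, x$rates[[nm]],
                ci[["lo"]], ci[["hi"]]))
  }
  if (!is.null(x$auc))
    cat(sprintf("  %-12s %.2f (%.2f-%.2f)\n", "AUC", x$auc[["auc"]],
                x$auc[["lo"]], x$auc[["hi"]]))
  cat(sprintf("  PDLR         %.2f\n", x$pdlr))
  for (nm in names(x$predictive)) {
    pv <- x$predictive[[nm]]
    cat(sprintf("  PPV/NPV at %s prevalence: %.2f / %.2f\n", nm,
                pv[["ppv"]], pv[["npv"]]))
  }
  invisible(x)
}

#' Export a diagnostic report as a performance-table CSV
#'
#' @param rep a \code{"DiagnosticReport"}; \code{path} output path.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDiagnosticCSV <- function(rep, path) {
  fmt_ci <- function(v, ci) sprintf("%.2f (%.2f-%.2f)", v, ci[["lo"]],
                                    ci[["hi"]])
  rows <- data.frame(
    metric = c("sensitivity", "specificity", "accuracy",
               if (!is.null(rep$auc)) "auc",
               paste0("ppv_", c("dataset", names(rep$predictive))),
               paste0("npv_", c("dataset", names(rep$predictive))),
               "pdlr"),
    value = c(fmt_ci(rep$rates[["sensitivity"]], rep$ci$sensitivity),
              fmt_ci(rep$rates[["specificity"]], rep$ci$specificity),
              fmt_ci(rep$rates[["accuracy"]], rep$ci$accuracy),
              if (!is.null(rep$auc))
                fmt_ci(rep$auc[["auc"]], c(lo = rep$auc[["lo"]],
                                           hi = rep$auc[["hi"]])),
              sprintf("%.2f", c(rep$rates[["ppv"]],
                                vapply(rep$predictive, `[`, 0, "ppv"))),
              sprintf("%.2f", c(rep$rates[["npv"]],
                                vapply(rep$predictive, `[`, 0, "npv"))),
              sprintf("%.2f", rep$pdlr)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
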
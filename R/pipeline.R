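#' Run the full per-sample pipeline
#'
#' Executes the end-to-end flow for one sample: file/readability QC,
#' flow-rate cleaning on the Time channel, de-novo spillover derivation from
#' the single-stain controls, compensation and logicle transformation of the
#' assay tubes, the automated gating cascade, eligibility QC (at least
#' 10,000 viable singlets and at least 10 lung-macrophage-window events),
#' feature extraction, and - only when every QC diamond passes - the model
#' probability and the cancer/non-cancer call.  Any QC failure
#' short-circuits with a structured report naming the failed stage; a
#' QC-failed sample never receives a call.
#'
#' @param tubes named list of tubes: either \linkS4class{FlowEventTable}s
#'   (as from [generateSample()]) or FCS file paths, with elements
#'   \code{beads}, \code{unstained}, \code{controls} (named list per
#'   fluorescence role), \code{blood} and optionally \code{epithelial}.
#' @param age age in years.
#' @param model a \linkS4class{SputumClassifier}, or NULL for gating/features
#'   only.
#' @param cfg a [gateConfig()].
#' @param map channel role map used when \code{tubes} holds file paths.
#' @param logicle_params logicle parameters.
#' @param flow_bins,flow_k flow-rate QC settings.
#' @param seed integer seed.
#' @return a \code{"SampleReport"} list: \code{qc} (per-diamond status),
#'   \code{gating} summary, \code{features}, \code{eligibility},
#'   \code{probability}, \code{cutoff}, \code{call} (NA unless eligible and
#'   a model was supplied), \code{heuristics}, \code{seed}, \code{version}.
#' @export
runSample <- function(tubes, age, model = NULL, cfg = gateConfig(),
                      map = channelDialect("lsr2"),
                      logicle_params = logicleParams(),
                      flow_bins = 100L, flow_k = 5, seed = 1L) {
  report <- list(qc = list(), call = NA_character_,
                 probability = NA_real_, cutoff = NA_real_,
                 seed = seed,
                 version = as.character(utils::packageVersion("sputumFlow")))
  fail <- function(diamond, msg) {
    report$qc[[diamond]] <- list(pass = FALSE, message = msg)
    report$failed_at <- diamond
    structure(report, class = "SampleReport")
  }
  # -- diamond 1: readable, complete files ---------------------------------
  res <- tryCatch({
    loadTube <- function(x, required) {
      if (is.character(x)) readFCS(x, map, required = required) else x
    }
    tubes$beads <- loadTube(tubes$beads, c("FSC-A", "SSC-A"))
    tubes$unstained <- loadTube(tubes$unstained,
                                c(SCATTER_ROLES, "TIME", BLOOD_FLUOR_ROLES))
    tubes$controls <- lapply(tubes$controls, loadTube,
                             required = BLOOD_FLUOR_ROLES)
    tubes$blood <- loadTube(tubes$blood,
                            c(SCATTER_ROLES, "TIME", BLOOD_FLUOR_ROLES))
    if (!is.null(tubes$epithelial))
      tubes$epithelial <- loadTube(tubes$epithelial,
                                   c(SCATTER_ROLES, "TIME", EPI_FLUOR_ROLES))
    tubes
  }, error = function(e) e)
  if (inherits(res, "error"))
    return(fail("file_qc", conditionMessage(res)))
  tubes <- res
  report$qc$file_qc <- list(pass = TRUE)
  # -- diamond 2: flow-rate anomalies --------------------------------------
  res <- tryCatch({
    fc <- cleanFlowRate(tubes$blood, flow_bins, flow_k)
    tubes$blood <- tubes$blood[fc$mask]
    flow_reports <- list(blood = fc$report)
    if (!is.null(tubes$epithelial)) {
      fce <- cleanFlowRate(tubes$epithelial, flow_bins, flow_k)
      tubes$epithelial <- tubes$epithelial[fce$mask]
      flow_reports$epithelial <- fce$report
    }
    flow_reports
  }, error = function(e) e)
  if (inherits(res, "error"))
    return(fail("flow_rate_qc", conditionMessage(res)))
  report$qc$flow_rate_qc <- list(pass = TRUE, reports = res)
  # -- compensation + logicle ----------------------------------------------
  res <- tryCatch({
    s <- deriveSpillover(tubes$controls, tubes$unstained,
                         seed = childSeed(seed, 31))
    blood <- logicleTube(compensate(tubes$blood, s),
                         BLOOD_FLUOR_ROLES, logicle_params)
    epi <- if (!is.null(tubes$epithelial)) {
      se <- s; dimnames(se) <- list(EPI_FLUOR_ROLES, EPI_FLUOR_ROLES)
      logicleTube(compensate(tubes$epithelial, se),
                  EPI_FLUOR_ROLES, logicle_params)
    }
    list(s = s, blood = blood, epi = epi)
  }, error = function(e) e)
  if (inherits(res, "error"))
    return(fail("compensation", conditionMessage(res)))
  report$spillover <- res$s
  tubes$blood <- res$blood
  tubes$epithelial <- res$epi
  # -- gating ---------------------------------------------------------------
  g <- tryCatch(runGating(tubes, "blood", cfg, seed = seed),
                error = function(e) e)
  if (inherits(g, "error"))
    return(fail("gating", conditionMessage(g)))
  report$gating <- list(counts = gateCounts(g), fsc_min = g@fscMin,
                        viability_threshold = viabilityCutoff(g),
                        polygon = g@singletsPolygon)
  report$heuristics <- heuristicsApplied(g)
  # -- diamond 3: eligibility ----------------------------------------------
  fx <- tryCatch(extractFeatures(g, tubes$blood, age), error = function(e) e)
  if (inherits(fx, "error"))
    return(fail("eligibility", conditionMessage(fx)))
  report$features <- fx$features
  report$eligibility <- fx$eligibility
  if (!is.null(tubes$epithelial)) {
    epi_grid <- tryCatch({
      ge <- runGating(tubes, "epithelial", cfg, seed = childSeed(seed, 41))
      gridCounts(tubes$epithelial, gateMask(ge, "viable_singlets"),
                 "EPCAM", "PANCK")
    }, error = function(e) NULL)
    report$epithelial_grid <- epi_grid
  }
  if (!fx$eligibility$eligible) {
    why <- c(if (!fx$eligibility$enough_singlets)
      "fewer than 10,000 viable singlets",
      if (!fx$eligibility$lung_confirmed)
        "fewer than 10 lung-macrophage events")
    return(fail("eligibility", paste(why, collapse = "; ")))
  }
  report$qc$eligibility <- list(pass = TRUE)
  # -- model + call ---------------------------------------------------------
  if (!is.null(model)) {
    report$probability <- predictProbability(model, fx$features,
                                             eligible = TRUE)
    report$cutoff <- modelCutoff(model)
    report$call <- classifyCall(report$probability, report$cutoff)
  }
  structure(report, class = "SampleReport")
}

#' @export
print.SampleReport <- function(x, ...) {
  cat("SampleReport\n")
  for (d in names(x$qc))
    cat(sprintf("  %-14s %s\n", d,
                if (isTRUE(x$qc[[d]]$pass)) "pass"
                else paste("FAIL:", x$qc[[d]]$message)))
  if (!is.null(x$features))
    cat("  viable singlets:", x$features[["viable_singlets"]],
        " macrophages:", x$features[["macrophages"]], "\n")
  if (!is.na(x$call))
    cat(sprintf("  probability %.3f (cutoff %.2f) -> %s\n",
                x$probability, x$cutoff, x$call))
  else cat("  no call (QC incomplete or no model)\n")
  invisible(x)
}

#' Run a cohort: predict, train, or evaluate
#'
#' \code{predict} scores each sample and, when labels are present, appends a
#' [diagnosticReport()].  \code{train} runs stepwise selection, fits the
#' logistic model on the full cohort and chooses the ROC cutoff.
#' \code{evaluate} scores and always builds the performance table.
#'
#' @param cohort either a list of per-sample tube sets with \code{ages}
#'   and optional \code{labels} (as from [generateCohort()] in
#'   \code{"fcs"} mode), or a list with a \code{features} data.frame and
#'   \code{labels} (fast feature mode).
#' @param mode \code{"predict"}, \code{"train"} or \code{"evaluate"}.
#' @param model a \linkS4class{SputumClassifier} (required for predict/evaluate).
#' @param cfg,map,seed passed to [runSample()].
#' @param n_boot bootstrap replicates for the AUC CI.
#' @return mode-dependent list; see Details.
#' @export
runCohort <- function(cohort, mode = c("predict", "train", "evaluate"),
                      model = NULL, cfg = gateConfig(),
                      map = channelDialect("lsr2"), n_boot = 500L,
                      seed = 1L) {
  mode <- match.arg(mode)
  feats <- cohortFeatures(cohort, cfg, map, seed)
  labels <- cohort$labels %||% rep(NA_integer_, nrow(feats$features))
  if (mode == "train") {
    fit <- fitLogistic(feats$features, labels)
    probs <- vapply(seq_len(nrow(feats$features)), function(i)
      predictProbability(fit, feats$features[i, , drop = FALSE]), 0)
    cc <- chooseCutoff(probs[!is.na(labels)], labels[!is.na(labels)])
    fit@cutoff <- cc$cutoff
    return(list(model = fit, cutoff = cc$cutoff, auc = cc$auc,
                roc = cc$roc, features = feats$features,
                reports = feats$reports))
  }
  if (is.null(model)) stop("mode '", mode, "' requires a fitted model")
  probs <- vapply(seq_len(nrow(feats$features)), function(i)
    predictProbability(model, feats$features[i, , drop = FALSE]), 0)
  calls <- classifyCall(probs, modelCutoff(model))
  out <- list(probabilities = probs, calls = calls,
              features = feats$features, reports = feats$reports)
  labelled <- !is.na(labels)
  if (any(labelled) && (mode == "evaluate" || all(labelled)))
    out$diagnostics <- diagnosticReport(calls[labelled], labels[labelled],
                                        probabilities = probs[labelled],
                                        n_boot = n_boot,
                                        seed = childSeed(seed, 77))
  out
}

# features from either fast mode (precomputed) or full tube sets
cohortFeatures <- function(cohort, cfg, map, seed) {
  if (!is.null(cohort$features))
    return(list(features = cohort$features, reports = NULL))
  if (is.null(cohort$samples)) stop("cohort must carry $features or $samples")
  reports <- lapply(seq_along(cohort$samples), function(i) {
    runSample(cohort$samples[[i]]$tubes, age = cohort$ages[i],
              model = NULL, cfg = cfg, map = map,
              seed = childSeed(seed, i))
  })
  bad <- vapply(reports, function(r) !is.null(r$failed_at), TRUE)
  if (any(bad))
    stop("QC-failed samples in cohort: ",
         paste(which(bad), collapse = ", "))
  feats <- as.data.frame(do.call(rbind, lapply(reports, `[[`, "features")))
  list(features = feats, reports = reports)
}
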
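#' @import methods
NULL

RAW_FULL_SCALE <- 262144  # 18-bit instrument full scale

#' FlowEventTable: per-tube event matrix with channel roles and scale state
#'
#' The central event container: a numeric matrix (rows = events, columns =
#' channels) together with a role map (logical role such as \code{"FSC-A"} or
#' \code{"FVS510"} to instrument channel name) and a per-channel scale flag
#' (\code{"raw"}, \code{"compensated"} or \code{"logicle"}).  Scatter and Time
#' channels always remain raw; fluorescence channels move from raw through
#' compensated to logicle as the pipeline progresses.
#'
#' @slot exprs numeric matrix of per-event channel values.
#' @slot roles named character vector, role -> instrument channel name.
#' @slot scale named character vector, channel name -> scale flag.
#' @slot clipped integer count of raw values clipped to the instrument range
#'   at construction (logged, not silently hidden).
#'
#' @seealso [flowEventTable()], [chan()], [nEvents()]
#' @export
setClass("FlowEventTable",
  representation(exprs = "matrix", roles = "character",
                 scale = "character", clipped = "integer"),
  prototype(clipped = 0L))

setValidity("FlowEventTable", function(object) {
  m <- object@exprs
  msgs <- character()
  if (is.null(colnames(m))) msgs <- c(msgs, "exprs must have channel colnames")
  if (!all(is.finite(m))) msgs <- c(msgs, "all event values must be finite")
  bad_role <- setdiff(object@roles, colnames(m))
  if (length(bad_role))
    msgs <- c(msgs, paste0("role maps to unknown channel: ",
                           paste(bad_role, collapse = ", ")))
  if (anyDuplicated(object@roles))
    msgs <- c(msgs, "two roles map to the same channel")
  if (!all(names(object@scale) %in% colnames(m)))
    msgs <- c(msgs, "scale flags refer to unknown channels")
  tm <- object@roles["TIME"]
  if (!is.na(tm) && tm %in% colnames(m) && nrow(m) > 1L &&
      is.unsorted(m[, tm], strictly = FALSE))
    msgs <- c(msgs, "Time channel must be non-decreasing")
  raw_ch <- names(object@scale)[object@scale == "raw"]
  raw_ch <- setdiff(raw_ch, object@roles["TIME"])  # clock ticks are unbounded
  if (length(raw_ch)) {
    rv <- m[, raw_ch, drop = FALSE]
    if (length(rv) && (min(rv) < 0 || max(rv) > RAW_FULL_SCALE))
      msgs <- c(msgs, "raw channel values outside [0, 262144]")
  }
  if (length(msgs)) msgs else TRUE
})

#' GatingResult: nested gate masks, thresholds and heuristics log
#'
#' Result of the automated gating cascade on one assay tube.  Masks are
#' logical vectors over the tube's events and are strictly nested:
#' \code{viable_singlets} within \code{viable} within \code{non_debris}
#' within \code{bead_size_exclusion}.
#'
#' @slot masks named list of logical masks, one per gate stage.
#' @slot fscMin numeric, bead-derived lower FSC-A limit.
#' @slot viabilityThreshold numeric, logicle FVS510 cutoff (viable = below).
#' @slot singletsPolygon numeric matrix (vertices x 2) in the singlets
#'   channel pair, vertex order lower-left, lower-right, top-right, top-left.
#' @slot heuristics character vector of applied-heuristic tags.
#' @slot counts named integer vector of events per stage.
#' @slot seed integer seed used for mixture initialisation (NA if none).
#' @export
setClass("GatingResult",
  representation(masks = "list", fscMin = "numeric",
                 viabilityThreshold = "numeric", singletsPolygon = "matrix",
                 heuristics = "character", counts = "integer",
                 seed = "integer"))

setValidity("GatingResult", function(object) {
  need <- c("bead_size_exclusion", "non_debris", "viable", "viable_singlets")
  if (!all(need %in% names(object@masks)))
    return(paste("masks must contain:", paste(need, collapse = ", ")))
  m <- object@masks
  if (any(m$non_debris & !m$bead_size_exclusion))
    return("non_debris not nested in bead_size_exclusion")
  if (any(m$viable & !m$non_debris))
    return("viable not nested in non_debris")
  if (any(m$viable_singlets & !m$viable))
    return("viable_singlets not nested in viable")
  for (s in need)
    if (object@counts[[s]] != sum(m[[s]]))
      return(paste("counts inconsistent with mask:", s))
  TRUE
})

#' SputumClassifier: logistic cancer/non-cancer classifier coefficients
#'
#' Fitted logistic model over the four predictors (age, the two
#' fluorescence-to-scatter density counts, the CD206-low/lineage-mid grid
#' count) plus the age x FVS510-density interaction, with Wald statistics and
#' the operating cutoff.
#'
#' @slot coefficients named numeric: intercept, age, tcpp_r3_per10k,
#'   fvs_r2_per10k, cd206low_linmid_per10k, age:fvs_r2_per10k.
#' @slot se named numeric standard errors.
#' @slot p named numeric Wald p-values.
#' @slot cutoff numeric in [0, 1]; probability above it calls cancer.
#' @slot separationFlag logical; TRUE when the fit showed complete separation
#'   and a ridge-penalised fallback produced the coefficients.
#' @slot meta list of training metadata (n, class counts, seed).
#' @export
setClass("SputumClassifier",
  representation(coefficients = "numeric", se = "numeric", p = "numeric",
                 cutoff = "numeric", separationFlag = "logical",
                 meta = "list"),
  prototype(cutoff = 0.5, separationFlag = FALSE, meta = list()))

setValidity("SputumClassifier", function(object) {
  if (!all(is.finite(object@coefficients))) return("coefficients must be finite")
  if (length(object@cutoff) != 1L || object@cutoff < 0 || object@cutoff > 1)
    return("cutoff must be a single value in [0, 1]")
  TRUE
})
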
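#' Construct a FlowEventTable
#'
#' Builds the per-tube event container from a numeric matrix of events by
#' channels.  Raw-scale values outside the 18-bit instrument range
#' \eqn{[0, 262144]} are clipped and the clip count recorded.
#'
#' @param exprs numeric matrix, rows = events, columns = channels
#'   (colnames required).
#' @param roles named character vector mapping logical roles (e.g.
#'   \code{"FSC-A"}, \code{"FVS510"}, \code{"TIME"}) to channel names.
#' @param scale named character vector of per-channel scale flags; defaults
#'   to \code{"raw"} for every channel.
#' @param x a \code{FlowEventTable}.
#' @param role a logical role name present in the role map.
#' @param ... unused.
#' @return \code{flowEventTable()} returns a \linkS4class{FlowEventTable};
#'   \code{events()} the event matrix; \code{chan()} one channel as a numeric
#'   vector addressed by role; \code{nEvents()} the number of rows.
#' @examples
#' m <- cbind(`FSC-A` = c(1e4, 2e4), `SSC-A` = c(5e3, 6e3), Time = c(1, 2))
#' et <- flowEventTable(m, roles = c(`FSC-A` = "FSC-A", `SSC-A` = "SSC-A",
#'                                   TIME = "Time"))
#' nEvents(et)
#' chan(et, "FSC-A")
#' @export
flowEventTable <- function(exprs, roles, scale = NULL) {
  stopifnot(is.matrix(exprs), is.numeric(exprs))
  if (is.null(colnames(exprs))) stop("event matrix must have channel colnames")
  if (is.null(scale))
    scale <- setNames(rep("raw", ncol(exprs)), colnames(exprs))
  clipped <- 0L
  raw_ch <- setdiff(names(scale)[scale == "raw"], roles["TIME"])
  if (length(raw_ch)) {
    sub <- exprs[, raw_ch, drop = FALSE]
    out <- sub < 0 | sub > RAW_FULL_SCALE
    if (any(out)) {
      clipped <- sum(out)
      exprs[, raw_ch] <- pmin(pmax(sub, 0), RAW_FULL_SCALE)
    }
  }
  new("FlowEventTable", exprs = exprs, roles = roles, scale = scale,
      clipped = clipped)
}

#' @rdname flowEventTable
#' @export
setMethod("events", "FlowEventTable", function(x, ...) x@exprs)

#' @rdname flowEventTable
#' @export
setMethod("channels", "FlowEventTable", function(x, ...) colnames(x@exprs))

#' @rdname flowEventTable
#' @export
setMethod("nEvents", "FlowEventTable", function(x) nrow(x@exprs))

#' @rdname flowEventTable
#' @export
setMethod("chan", "FlowEventTable", function(x, role) {
  ch <- x@roles[role]
  if (is.na(ch) || !length(ch))
    stop("role not mapped for this tube: ", role)
  x@exprs[, ch]
})

#' @rdname flowEventTable
#' @export
setMethod("channelScale", "FlowEventTable", function(x, role) {
  ch <- x@roles[role]
  if (is.na(ch)) stop("role not mapped: ", role)
  unname(x@scale[ch])
})

hasRole <- function(x, role) !is.na(x@roles[role]) && role %in% names(x@roles)

#' @export
setMethod("show", "FlowEventTable", function(object) {
  cat("FlowEventTable:", nrow(object@exprs), "events x",
      ncol(object@exprs), "channels\n")
  cat("  roles:", paste(names(object@roles), "->", object@roles,
                        collapse = ", "), "\n")
  sc <- table(object@scale)
  cat("  scale:", paste(names(sc), sc, sep = "=", collapse = ", "), "\n")
  if (object@clipped > 0L)
    cat("  note:", object@clipped, "raw values clipped to instrument range\n")
})

#' @export
setMethod("[", "FlowEventTable", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) stop("channel subsetting not supported; subset events only")
  initialize(x, exprs = x@exprs[i, , drop = FALSE])
})

#' @rdname gatingAccessors
#' @param x,stage a \code{GatingResult} and a gate stage name (one of
#'   \code{"bead_size_exclusion"}, \code{"non_debris"}, \code{"viable"},
#'   \code{"viable_singlets"}).
#' @name gatingAccessors
#' @export
setMethod("gateMask", "GatingResult", function(x, stage) {
  if (!stage %in% names(x@masks)) stop("unknown gate stage: ", stage)
  x@masks[[stage]]
})

#' @rdname gatingAccessors
#' @export
setMethod("gateCounts", "GatingResult", function(x) x@counts)

#' @rdname gatingAccessors
#' @export
setMethod("heuristicsApplied", "GatingResult", function(x) x@heuristics)

#' @rdname gatingAccessors
#' @export
setMethod("viabilityCutoff", "GatingResult", function(x) x@viabilityThreshold)

#' @export
setMethod("show", "GatingResult", function(object) {
  cat("GatingResult\n")
  cat("  fsc_min:", format(object@fscMin, digits = 5),
      " viability threshold (logicle):",
      format(object@viabilityThreshold, digits = 4), "\n")
  for (s in names(object@counts))
    cat(sprintf("  %-20s %d\n", s, object@counts[[s]]))
  if (length(object@heuristics))
    cat("  heuristics:", paste(object@heuristics, collapse = ", "), "\n")
})

#' Accessors for SputumClassifier
#'
#' @param object a \linkS4class{SputumClassifier}.
#' @return \code{modelCoefficients()} the named coefficient vector;
#'   \code{modelCutoff()} the operating probability cutoff.
#' @name sputumClassifier
NULL

#' @rdname sputumClassifier
#' @export
setMethod("modelCoefficients", "SputumClassifier", function(object) object@coefficients)

#' @rdname sputumClassifier
#' @export
setMethod("modelCutoff", "SputumClassifier", function(object) object@cutoff)

#' @export
setMethod("show", "SputumClassifier", function(object) {
  cat("SputumClassifier (logistic cancer/non-cancer classifier)\n")
  tab <- data.frame(coef = object@coefficients, se = object@se,
                    wald_p = object@p)
  print(round(tab, 5))
  cat("cutoff:", object@cutoff, "\n")
  if (object@separationFlag)
    cat("note: complete separation detected; ridge-penalised fallback used\n")
})
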
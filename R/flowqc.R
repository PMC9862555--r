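#' Remove flow-rate anomalies using the Time channel
#'
#' Bubbles and clogs during acquisition show up as transient spikes or
#' dropouts in event rate.  Acquisition time is split into equal-width bins;
#' a bin whose event count deviates from the median bin count by more than
#' \code{k} robust deviations (MAD) is flagged and all its events masked out.
#'
#' @param t a \linkS4class{FlowEventTable} with a mapped Time channel.
#' @param bin_count number of equal-width time bins (default 100).
#' @param k robust-deviation multiplier (default 5).
#' @return list with \code{mask} (logical, TRUE = keep) and \code{report}, a
#'   list holding \code{bins_total}, \code{bins_removed},
#'   \code{events_removed} and \code{removed_intervals} (two-column matrix of
#'   time start/end).
#' @examples
#' tm <- sort(runif(5000, 0, 100))
#' et <- flowEventTable(cbind(Time = tm, `FSC-A` = runif(5000, 0, 1e5)),
#'                      roles = c(TIME = "Time", `FSC-A` = "FSC-A"))
#' cleanFlowRate(et)$report$bins_removed
#' @export
cleanFlowRate <- function(t, bin_count = 100L, k = 5) {
  stopifnot(bin_count >= 2L, k > 0)
  tv <- chan(t, "TIME")
  span <- diff(range(tv))
  if (!is.finite(span) || span <= 0) stop("Time channel has no span")
  breaks <- seq(min(tv), max(tv), length.out = bin_count + 1L)
  bin <- findInterval(tv, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = bin_count)
  med <- median(counts)
  dev <- mad(counts, center = med)
  if (dev < .Machine$double.eps) dev <- max(sqrt(med), 1)  # Poisson floor
  bad <- abs(counts - med) > k * dev
  if (all(bad)) stop("sample unusable - unstable acquisition")
  mask <- !bad[bin]
  ivs <- if (any(bad)) {
    idx <- which(bad)
    cbind(time_start = breaks[idx], time_end = breaks[idx + 1L])
  } else matrix(numeric(), 0, 2,
                dimnames = list(NULL, c("time_start", "time_end")))
  list(mask = mask,
       report = list(bins_total = bin_count, bins_removed = sum(bad),
                     events_removed = sum(!mask), removed_intervals = ivs))
}
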
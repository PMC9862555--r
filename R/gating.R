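#' Gating configuration
#'
#' Defaults follow the published cascade: scatter upper limits of
#' \eqn{2.5 \times 10^5} (events above are dead), a temporary SSC-A limit of
#' \eqn{5 \times 10^4} for singlets-gate repair, a 10\% tail tolerance for
#' the viability gate, a 0.90 density-contour quantile for the core viable
#' gate with a 0.99 fallback when it captures < 10\% of events, and a
#' natural viability cutoff of 2.5 on the logicle scale used when an
#' intermediate population (> 10\% of singlets) sits below the tail-gate
#' threshold.
#'
#' @param bse_upper upper FSC-A/SSC-A limit of the bead size exclusion gate.
#' @param ssc_temp_limit SSC-A limit for the temporary singlets-repair gate.
#' @param tail_tolerance density fraction of the dominant mode at which the
#'   viability tail gate is placed.
#' @param core_quantile,core_quantile_fallback density-contour quantiles of
#'   the core viable gate.
#' @param core_min_fraction minimum fraction of non-debris events the core
#'   gate must capture before the fallback quantile is used.
#' @param viability_natural_cutoff logicle value used when the viability
#'   threshold is reset.
#' @param intermediate_pop_trigger fraction of singlets between the natural
#'   cutoff and the threshold that triggers the reset.
#' @param bead_contour two-sided coverage of the bead cluster used to place
#'   its lower FSC-A boundary.
#' @param singlets_channels character pair for the singlets gate; the
#'   default is FSC area against width (area against height is the
#'   supported alternative).
#' @param singlets_band_k MAD multiplier of the singlets residual band.
#' @param mixture_components components of the scatter mixture fits.
#' @return a list of class \code{"GateConfig"}.
#' @export
gateConfig <- function(bse_upper = 2.5e5, ssc_temp_limit = 5e4,
                       tail_tolerance = 0.10, core_quantile = 0.90,
                       core_quantile_fallback = 0.99,
                       core_min_fraction = 0.10,
                       viability_natural_cutoff = 2.5,
                       intermediate_pop_trigger = 0.10,
                       bead_contour = 0.99,
                       singlets_channels = c("FSC-A", "FSC-W"),
                       singlets_band_k = 5,
                       mixture_components = 3L) {
  fr <- c(tail_tolerance, core_quantile, core_quantile_fallback,
          core_min_fraction, intermediate_pop_trigger, bead_contour)
  if (any(fr <= 0 | fr > 1)) stop("gate fractions must lie in (0, 1]")
  if (bse_upper <= 0) stop("bse_upper must be positive")
  structure(as.list(environment()), class = "GateConfig")
}

# Robust scatter mixture: fit on a subsample, classify all events.
# Deterministic given the seed (subsampling is the only randomness; the
# model-based EM uses hierarchical initialisation).
scatterMixture <- function(xy, G, seed = NULL, max_fit = 2000L) {
  idx <- fitSubsample(nrow(xy), max_fit, seed)
  fit <- withSeed(seed, suppressWarnings(
    mclust::Mclust(xy[idx, , drop = FALSE], G = G, verbose = FALSE)))
  if (is.null(fit)) return(NULL)
  cls <- if (nrow(xy) > length(idx))
    predict(fit, xy)$classification else fit$classification
  list(fit = fit, class = cls)
}

#' Anchor the minimum FSC-A at the 5-micron bead cluster
#'
#' A two-dimensional cluster fit on FSC-A vs SSC-A of the bead tube
#' identifies the dominant bead peak; the lower FSC-A boundary of its
#' \code{bead_contour} coverage ellipse becomes the sample's minimum FSC-A,
#' excluding smaller particulates and debris downstream.
#'
#' @param beads bead-tube \linkS4class{FlowEventTable}.
#' @param cfg a [gateConfig()].
#' @param seed integer seed for mixture initialisation.
#' @return the lower FSC-A limit (numeric).
#' @export
findBeadThreshold <- function(beads, cfg = gateConfig(), seed = 1L) {
  xy <- cbind(chan(beads, "FSC-A"), chan(beads, "SSC-A"))
  mix <- scatterMixture(xy, G = 1:cfg$mixture_components, seed = seed)
  if (is.null(mix)) stop("bead tube QC failure: cluster fit failed")
  sizes <- tabulate(mix$class, nbins = mix$fit$G)
  dom <- which.max(sizes)
  if (sizes[dom] / nrow(xy) < 0.20)
    stop("bead tube QC failure: no dominant bead cluster (largest holds ",
         round(100 * sizes[dom] / nrow(xy)), "% of events)")
  in_dom <- mix$class == dom
  mu <- mean(xy[in_dom, 1L])
  sdv <- max(sd(xy[in_dom, 1L]), 1e-6)  # guard against a zero-variance fit
  if (sdv > 0.15 * RAW_FULL_SCALE)
    stop("bead tube QC failure: dominant cluster too dispersed ",
         "(no bead peak)")
  z <- qnorm(1 - (1 - cfg$bead_contour) / 2)
  max(mu - z * sdv, 0)
}

#' Bead size exclusion (BSE) gate
#'
#' Keeps events with \code{fsc_min <= FSC-A <= bse_upper} and
#' \code{SSC-A <= bse_upper}.  All bounds are closed on the kept side.
#'
#' @param t assay tube.
#' @param fsc_min bead-derived lower FSC-A limit.
#' @param cfg a [gateConfig()].
#' @return logical mask (TRUE = keep).
#' @export
bseGate <- function(t, fsc_min, cfg = gateConfig()) {
  fsc <- chan(t, "FSC-A"); ssc <- chan(t, "SSC-A")
  fsc >= fsc_min & fsc <= cfg$bse_upper & ssc <= cfg$bse_upper
}

#' Exclude the detached corner-artifact population
#'
#' Some tubes show a spurious population in the lower-right corner of
#' FSC-H vs SSC-H (very high height, near-zero side scatter height).  It is
#' detected as a mixture component whose FSC-H centroid lies in the top
#' quartile of the FSC-H range while its SSC-H centroid falls below the 5th
#' percentile of in-gate SSC-H; its classified events are removed.  When no
#' such component exists the mask is returned unchanged.  The result is the
#' "non-debris" population.
#'
#' @param t assay tube; \code{mask_in} the BSE mask.
#' @param mask_in logical mask of events entering this gate.
#' @param cfg a [gateConfig()].
#' @param seed integer seed.
#' @return list with \code{mask} and logical \code{applied}.
#' @export
excludeCornerArtifacts <- function(t, mask_in, cfg = gateConfig(), seed = 1L) {
  fh <- chan(t, "FSC-H"); sh <- chan(t, "SSC-H")
  idx <- which(mask_in)
  if (length(idx) < 50L) return(list(mask = mask_in, applied = FALSE))
  xy <- cbind(fh[idx], sh[idx])
  # one extra component so a detached artifact can earn its own cluster
  mix <- scatterMixture(xy, G = 1:(cfg$mixture_components + 1L), seed = seed)
  if (is.null(mix)) return(list(mask = mask_in, applied = FALSE))
  rng <- range(xy[, 1L])
  fh_hi <- rng[1L] + 0.75 * diff(rng)
  sh_lo <- quantile(xy[, 2L], 0.05)
  mu <- mix$fit$parameters$mean
  corner <- which(mu[1L, ] >= fh_hi & mu[2L, ] <= sh_lo)
  if (!length(corner)) return(list(mask = mask_in, applied = FALSE))
  drop <- mix$class %in% corner
  if (all(drop))
    warning("corner-artifact component holds all in-gate events")
  mask <- mask_in
  mask[idx[drop]] <- FALSE
  list(mask = mask, applied = TRUE)
}

#' Temporary core viable gate
#'
#' Fits a scatter mixture on FSC-H vs SSC-H of non-debris events and keeps
#' the \code{core_quantile} density contour (Mahalanobis ellipse) of the
#' component with the lowest SSC-H centroid - the subpopulation most likely
#' to hold viable singlet cells (relatively small in scatter area and
#' height).  If the gate captures less than \code{core_min_fraction} of
#' non-debris events it is re-run more inclusively at
#' \code{core_quantile_fallback}.
#'
#' @inheritParams excludeCornerArtifacts
#' @param non_debris logical non-debris mask.
#' @return list with \code{mask} and \code{fallback} (logical).
#' @export
coreViableGate <- function(t, non_debris, cfg = gateConfig(), seed = 1L) {
  idx <- which(non_debris)
  if (!length(idx)) stop("viability pre-gate failure: no non-debris events")
  xy <- cbind(chan(t, "FSC-H")[idx], chan(t, "SSC-H")[idx])
  mix <- scatterMixture(xy, G = 1:cfg$mixture_components, seed = seed)
  if (is.null(mix)) stop("viability pre-gate failure: mixture did not converge")
  mu <- mix$fit$parameters$mean
  pro <- mix$fit$parameters$pro
  # among components holding a non-trivial share of events, take the one
  # lowest in SSC-H (small in scatter area and height = likely live cells)
  cand <- which(pro >= 0.05)
  if (!length(cand)) cand <- seq_along(pro)
  comp <- cand[which.min(mu[2L, cand])]
  sig <- mix$fit$parameters$variance$sigma
  cv <- if (length(dim(sig)) == 3L) sig[, , comp] else sig
  d2 <- stats::mahalanobis(xy, mu[, comp], cv)
  gate_at <- function(q) d2 <= qchisq(q, df = 2L)
  keep <- gate_at(cfg$core_quantile)
  fallback <- FALSE
  if (mean(keep) < cfg$core_min_fraction) {
    keep <- gate_at(cfg$core_quantile_fallback)
    fallback <- TRUE
  }
  if (!any(keep)) stop("viability pre-gate failure: empty core viable gate")
  mask <- logical(length(non_debris))
  mask[idx[keep]] <- TRUE
  list(mask = mask, fallback = fallback)
}

#' Automatic tail gate on the viability stain
#'
#' Places the viability threshold where the kernel density of logicle FVS510
#' over core viable singlets first falls to \code{tail_tolerance} times the
#' dominant-mode density, searching rightwards from the mode.  Viable events
#' lie to the left of (at or below) the threshold.
#'
#' @param t assay tube with logicle-scale FVS510.
#' @param core_viable_singlets logical mask of core viable singlet events.
#' @param cfg a [gateConfig()].
#' @return the threshold (logicle decades).
#' @export
viabilityThreshold <- function(t, core_viable_singlets, cfg = gateConfig()) {
  v <- chan(t, "FVS510")[core_viable_singlets]
  if (length(v) < 100L)
    stop("viability tail gate needs >= 100 core viable singlets, got ",
         length(v))
  if (sd(v) < 1e-8) stop("degenerate FVS510 signal (zero variance)")
  den <- density(v, bw = "nrd0", n = 1024L)
  mode_i <- which.max(den$y)
  target <- cfg$tail_tolerance * den$y[mode_i]
  right <- seq(mode_i, length(den$x))
  hit <- right[den$y[right] <= target]
  if (!length(hit)) return(max(den$x))
  den$x[hit[1L]]
}

# Quadrilateral around the singlet ridge in the configured channel pair.
# The singlet ridge runs through the origin (pulse height/width track pulse
# area), so its slope is the median per-event y/x ratio - robust to the
# doublet cloud, which sits at half the ridge ratio.  The band is +/- k *
# MAD of the residuals.  Deterministic; a dominant off-ridge population
# still skews it, which is what the repair heuristics detect.
singletsPolygonFit <- function(x, y, cfg, seed = NULL) {
  ok <- x > 1
  slope <- if (any(ok)) median(y[ok] / x[ok]) else 0
  center <- c(median(x), median(y))
  res <- y - (center[2L] + slope * (x - center[1L]))
  off <- median(res)
  half <- cfg$singlets_band_k * max(mad(res), 1e-6)
  x_lo <- max(min(x), 0)
  x_hi <- cfg$bse_upper
  line_y <- function(xx, d) center[2L] + off + d + slope * (xx - center[1L])
  poly <- rbind(
    c(x_lo, line_y(x_lo, -half)),            # lower left
    c(x_hi, line_y(x_hi, -half)),            # lower right
    c(cfg$bse_upper, cfg$bse_upper),         # forced top right
    c(x_lo, line_y(x_lo, half)))             # top left
  colnames(poly) <- c("x", "y")
  poly
}

polygonMalformed <- function(poly) {
  poly[1L, 2L] < 0 || poly[4L, 2L] > poly[2L, 2L]
}

#' Fit the singlets gate polygon with automatic repair
#'
#' Fits a quadrilateral around the singlet ridge in the configured channel
#' pair (FSC area vs width by default) by a robust principal-axis fit with a
#' MAD band, forcing the top-right corner to \code{(bse_upper, bse_upper)}
#' so the upper diagonal is included.  If the polygon is malformed (lower
#' left corner below zero, or top-left point higher than the lower-right
#' point) the fit is repeated on the subset with
#' \code{SSC-A <= ssc_temp_limit} and the repaired polygon applied to the
#' full population.
#'
#' @param t assay tube.
#' @param viable logical mask of events the gate is fitted on.
#' @param cfg a [gateConfig()].
#' @param seed integer seed.
#' @return list with \code{polygon} (4 x 2 matrix), \code{mask} (singlets
#'   within \code{viable}) and \code{tags} (character heuristics).
#' @export
fitSingletsPolygon <- function(t, viable, cfg = gateConfig(), seed = 1L) {
  if (sum(viable) < 100L)
    stop("singlets gate failure: fewer than 100 events to fit on")
  cx <- chan(t, cfg$singlets_channels[1L])
  cy <- chan(t, cfg$singlets_channels[2L])
  idx <- which(viable)
  poly <- singletsPolygonFit(cx[idx], cy[idx], cfg, seed)
  tags <- character()
  if (polygonMalformed(poly)) {
    ssc <- chan(t, "SSC-A")
    sub <- idx[ssc[idx] <= cfg$ssc_temp_limit]
    if (length(sub) < 100L) stop("singlets gate failure: repair subset empty")
    poly <- singletsPolygonFit(cx[sub], cy[sub], cfg, childSeed(seed, 2))
    tags <- "ssc_temp_gate"
    if (polygonMalformed(poly)) stop("singlets gate failure: refit malformed")
  }
  mask <- logical(length(viable))
  mask[idx] <- pointsInPolygon(cx[idx], cy[idx], poly)
  list(polygon = poly, mask = mask, tags = tags)
}

#' Refine the viability threshold against an intermediate population
#'
#' When more than \code{intermediate_pop_trigger} of singlets carry logicle
#' FVS510 between the natural cutoff (2.5) and the tail-gate threshold, and
#' a two-component mixture confirms a distinct upper component, the
#' threshold is reset to the natural cutoff and the singlets polygon refit
#' on the restricted viable population.
#'
#' @param t assay tube; \code{singlets} current viable-singlets mask.
#' @param singlets logical mask of current viable singlets.
#' @param threshold current viability threshold.
#' @param cfg a [gateConfig()].
#' @param seed integer seed.
#' @return list with \code{threshold}, \code{singlets}, \code{polygon}
#'   (NULL when unchanged) and \code{tags}.
#' @export
refineViability <- function(t, singlets, threshold, cfg = gateConfig(),
                            seed = 1L) {
  unchanged <- list(threshold = threshold, singlets = singlets,
                    polygon = NULL, tags = character())
  nat <- cfg$viability_natural_cutoff
  if (threshold <= nat) return(unchanged)
  v <- chan(t, "FVS510")
  sv <- v[singlets]
  frac <- mean(sv > nat & sv <= threshold)
  if (!is.finite(frac) || frac <= cfg$intermediate_pop_trigger)
    return(unchanged)
  fit <- withSeed(seed, suppressWarnings(
    mclust::Mclust(sv[fitSubsample(length(sv), 5000L, seed)],
                   G = 1:2, modelNames = c("E", "V"), verbose = FALSE)))
  if (is.null(fit) || fit$G < 2L) return(unchanged)
  if (max(fit$parameters$mean) <= nat) return(unchanged)
  restricted <- singlets & v <= nat
  refit <- fitSingletsPolygon(t, restricted, cfg, childSeed(seed, 3))
  list(threshold = nat, singlets = refit$mask, polygon = refit$polygon,
       tags = c("viability_reset", refit$tags))
}

#' Run the full automated gating cascade on one assay tube
#'
#' Executes bead threshold, BSE gate, corner-artifact exclusion, temporary
#' core viable gate, provisional singlets gate, viability tail gate, final
#' viable mask, singlets polygon (with repair) and the intermediate-
#' population refinement, in that order.  Temporary gates (core viable,
#' provisional singlets) condition the viability threshold but are not part
#' of the final mask chain.
#'
#' @param tubes named list with at least \code{beads} and one assay tube
#'   (e.g. \code{blood}); the assay tube must carry logicle-scale FVS510.
#' @param assay name of the assay tube to gate (default \code{"blood"}).
#' @param cfg a [gateConfig()].
#' @param seed integer seed recorded in the result.
#' @return a \linkS4class{GatingResult}.
#' @export
runGating <- function(tubes, assay = "blood", cfg = gateConfig(), seed = 1L) {
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("gating stage '", name, "': ", conditionMessage(e), call. = FALSE))
  t <- tubes[[assay]]
  if (is.null(t)) stop("assay tube not found: ", assay)
  if (is.null(tubes$beads)) stop("bead tube required")
  fsc_min <- stage("bead_threshold",
                   findBeadThreshold(tubes$beads, cfg, childSeed(seed, 11)))
  bse <- stage("bse_gate", bseGate(t, fsc_min, cfg))
  heur <- character()
  ca <- stage("corner_artifacts",
              excludeCornerArtifacts(t, bse, cfg, childSeed(seed, 12)))
  if (ca$applied) heur <- c(heur, "corner_artifacts_removed")
  non_debris <- ca$mask
  core <- stage("core_viable",
                coreViableGate(t, non_debris, cfg, childSeed(seed, 13)))
  if (core$fallback) heur <- c(heur, "core_quantile_fallback")
  prov <- stage("provisional_singlets",
                fitSingletsPolygon(t, core$mask, cfg, childSeed(seed, 14)))
  thr <- stage("viability_tail_gate",
               viabilityThreshold(t, prov$mask, cfg))
  viable <- non_debris & chan(t, "FVS510") <= thr
  sing <- stage("singlets_gate",
                fitSingletsPolygon(t, viable, cfg, childSeed(seed, 15)))
  heur <- c(heur, sing$tags)
  refined <- stage("viability_refinement",
                   refineViability(t, sing$mask, thr, cfg, childSeed(seed, 16)))
  thr <- refined$threshold
  poly <- refined$polygon %||% sing$polygon
  viable <- non_debris & chan(t, "FVS510") <= thr
  vs <- refined$singlets & viable
  heur <- c(heur, refined$tags)
  masks <- list(bead_size_exclusion = bse, non_debris = non_debris,
                viable = viable, viable_singlets = vs)
  new("GatingResult", masks = masks, fscMin = fsc_min,
      viabilityThreshold = thr, singletsPolygon = poly,
      heuristics = heur,
      counts = vapply(masks, function(m) sum(m), integer(1)),
      seed = as.integer(seed))
}
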
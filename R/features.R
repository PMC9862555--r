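#' Fluorescence-to-scatter density regions (per 10,000 viable singlets)
#'
#' For each viable singlet the density ratio r = (logicle fluorescence) /
#' log10(raw scatter area) is computed and tabulated into three regions:
#' R1 (r < 0.25), R2 (0.25 <= r <= 0.6) and R3 (r > 0.6).  Counts are
#' normalised to events per 10,000 viable singlets, so the three regions sum
#' to exactly 10,000.  R2 is closed at both printed boundaries; R1 and R3
#' are open.
#'
#' @param t assay tube with logicle fluorescence and raw scatter.
#' @param singlets logical viable-singlets mask.
#' @param fluor_role fluorescence role of the numerator (e.g. \code{"TCPP"}).
#' @param scatter_role raw scatter role of the denominator (\code{"SSC-A"}
#'   or \code{"FSC-A"}).
#' @param bounds two region boundaries, default \code{c(0.25, 0.6)}.
#' @return named numeric vector \code{c(R1, R2, R3)} of per-10K counts.
#' @export
densityRegionCounts <- function(t, singlets, fluor_role, scatter_role,
                                bounds = c(0.25, 0.6)) {
  n <- sum(singlets)
  if (n == 0L) stop("no viable singlets")
  if (channelScale(t, fluor_role) != "logicle")
    stop("fluorescence must be on the logicle scale: ", fluor_role)
  sc <- chan(t, scatter_role)[singlets]
  if (any(sc <= 1))
    stop("scatter <= 1 after gating; bead size exclusion must precede ",
         "density features")
  r <- chan(t, fluor_role)[singlets] / log10(sc)
  counts <- c(R1 = sum(r < bounds[1L]),
              R2 = sum(r >= bounds[1L] & r <= bounds[2L]),
              R3 = sum(r > bounds[2L]))
  counts / n * 10000
}

GRID_WINDOWS <- c(1.5, 2.5, 3.0)
GRID_LEVELS <- c("low", "lowmid", "mid", "high")

# window index per event: low (< 1.5), lowmid [1.5, 2.5), mid [2.5, 3),
# high (>= 3); lower-closed so printed boundary values are deterministic
gridWindow <- function(v, windows = GRID_WINDOWS) {
  factor(GRID_LEVELS[findInterval(v, windows) + 1L], levels = GRID_LEVELS)
}

#' Quantized 4x4 intensity grid (per 10,000 viable singlets)
#'
#' Logicle signal on each axis is quantized into low (< 1.5), low-mid
#' (1.5-2.5), mid (2.5-3) and high (> 3) windows; events per 10,000 viable
#' singlets are tabulated over the resulting 4 x 4 grid (rows = roleX
#' windows, columns = roleY windows).  Windows are closed on their lower
#' edge.
#'
#' @param t assay tube with both roles on the logicle scale.
#' @param singlets logical viable-singlets mask.
#' @param roleX,roleY fluorescence roles of the two grid axes.
#' @param windows the three window boundaries.
#' @return 4 x 4 numeric matrix of per-10K counts (sums to 10,000).
#' @export
gridCounts <- function(t, singlets, roleX, roleY, windows = GRID_WINDOWS) {
  n <- sum(singlets)
  if (n == 0L) stop("no viable singlets")
  for (r in c(roleX, roleY))
    if (channelScale(t, r) != "logicle")
      stop("grid axis must be on the logicle scale: ", r)
  wx <- gridWindow(chan(t, roleX)[singlets], windows)
  wy <- gridWindow(chan(t, roleY)[singlets], windows)
  table(wx, wy) / n * 10000
}

#' Extract the classifier feature vector and sample eligibility
#'
#' From the gated blood tube: the per-10K count of viable singlets with
#' TCPP/log10 SSC-A density in region R3, the per-10K count with
#' FVS510/log10 FSC-A density in region R2, the per-10K count in the
#' CD206-low x lineage-mid grid cell (non-macrophage leucocytes), and the
#' raw count of events in the lung-macrophage window (CD206 mid-or-high x
#' lineage low-or-low-mid).  Eligibility requires at least 10,000 viable
#' singlets and at least 10 macrophage-window events (confirming the sample
#' originated in the lung).
#'
#' @param g a \linkS4class{GatingResult} for the blood tube.
#' @param blood the blood tube (logicle fluorescence, raw scatter).
#' @param age age in years (> 0).
#' @param lineage_mid_window character, which lineage windows make up the
#'   "mid" sector of the non-macrophage cell count.
#' @return list with \code{features} (named numeric: age, tcpp_r3_per10k,
#'   fvs_r2_per10k, cd206low_linmid_per10k, macrophages, viable_singlets)
#'   and \code{eligibility} (list: enough_singlets, lung_confirmed,
#'   eligible).
#' @export
extractFeatures <- function(g, blood, age, lineage_mid_window = "mid") {
  stopifnot(is(g, "GatingResult"), age > 0)
  vs <- gateMask(g, "viable_singlets")
  n <- sum(vs)
  enough <- n >= 10000L
  if (n == 0L) stop("no viable singlets; sample fails eligibility upstream")
  tcpp <- densityRegionCounts(blood, vs, "TCPP", "SSC-A")
  fvs <- densityRegionCounts(blood, vs, "FVS510", "FSC-A")
  grid <- gridCounts(blood, vs, "CD206", "LINEAGE")
  cd206low_linmid <- sum(grid["low", lineage_mid_window])
  mac_per10k <- sum(grid[c("mid", "high"), c("low", "lowmid")])
  macrophages <- as.integer(round(mac_per10k / 10000 * n))
  lung_ok <- macrophages >= 10L
  list(
    features = c(age = age,
                 tcpp_r3_per10k = unname(tcpp["R3"]),
                 fvs_r2_per10k = unname(fvs["R2"]),
                 cd206low_linmid_per10k = unname(cd206low_linmid),
                 macrophages = macrophages,
                 viable_singlets = n),
    eligibility = list(enough_singlets = enough, lung_confirmed = lung_ok,
                       eligible = enough && lung_ok))
}
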
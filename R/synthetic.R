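#' Synthetic sample specification
#'
#' Defines the planted populations of a synthetic multi-tube sputum sample:
#' event fractions per population, class-dependent per-10K targets for the
#' cancer-predictive features, and the known spillover applied to raw
#' fluorescence.  Scatter is lognormal on the raw scale; fluorescence is
#' normal on the logicle scale (inverted to raw before spillover).  Doublets
#' sum two singlet scatter-area draws and sit in an offset pulse-width band,
#' reproducing the off-ridge population the singlets gate must exclude.
#'
#' @param status \code{"non-cancer"} or \code{"cancer"}.
#' @param n_events events per assay tube (default 50000, comfortably above
#'   the 10,000 viable-singlet eligibility bar).
#' @param tcpp_r3_per10k target per-10K count of TCPP-bright viable
#'   singlets (class-dependent default: 60 non-cancer, 400 cancer).
#' @param fvs_r2_per10k target per-10K count of small, moderately
#'   FVS510-positive ("stressed") viable singlets (150 / 900).
#' @param fractions named event fractions of the structural populations
#'   (debris, dead, doublet, leukocyte, macrophage; the remainder are other
#'   live cells from which the feature subpopulations are carved).
#' @param corner_fraction fraction of corner-artifact events (high FSC-H,
#'   near-zero SSC-H); 0 by default.
#' @param contaminant_fraction fraction of a high-SSC-A population that
#'   skews the naive singlets fit; 0 by default.
#' @param spillover known spillover matrix over the blood fluorescence
#'   roles (epithelial roles reuse its pattern); NULL = built-in default
#'   with 4-12\% bleeds.
#' @return list of class \code{"SampleSpec"}.
#' @export
sampleSpec <- function(status = c("non-cancer", "cancer"),
                       n_events = 50000L,
                       tcpp_r3_per10k = NULL,
                       fvs_r2_per10k = NULL,
                       fractions = c(debris = 0.08, dead = 0.15,
                                     doublet = 0.08, leukocyte = 0.20,
                                     macrophage = 0.12),
                       corner_fraction = 0,
                       contaminant_fraction = 0,
                       spillover = NULL) {
  status <- match.arg(status)
  cancer <- status == "cancer"
  tcpp_r3_per10k <- tcpp_r3_per10k %||% if (cancer) 400 else 60
  fvs_r2_per10k <- fvs_r2_per10k %||% if (cancer) 900 else 150
  if (sum(fractions) + corner_fraction + contaminant_fraction >= 1)
    stop("population fractions must sum to less than 1 ",
         "(remainder = other live cells)")
  if (is.null(spillover)) {
    spillover <- diag(length(BLOOD_FLUOR_ROLES))
    dimnames(spillover) <- list(BLOOD_FLUOR_ROLES, BLOOD_FLUOR_ROLES)
    spillover["FVS510", "CD45"] <- 0.08
    spillover["LINEAGE", "CD206"] <- 0.12
    spillover["CD206", "LINEAGE"] <- 0.05
    spillover["TCPP", "CD45"] <- 0.04
  }
  structure(list(status = status, n_events = as.integer(n_events),
                 tcpp_r3_per10k = tcpp_r3_per10k,
                 fvs_r2_per10k = fvs_r2_per10k, fractions = fractions,
                 corner_fraction = corner_fraction,
                 contaminant_fraction = contaminant_fraction,
                 spillover = spillover,
                 n_beads = 5000L, n_unstained = 5000L, n_control = 2000L),
            class = "SampleSpec")
}

# per-population channel models; scatter raw-lognormal, fluorescence
# logicle-normal.  Returns a list of draw functions keyed by population.
popChannelModels <- function() {
  ln <- function(n, m, s) rlnorm(n, log(m), s)
  list(
    debris = function(n) list(
      fsc_a = ln(n, 1.1e4, 0.5), ssc_a = ln(n, 8e3, 0.5),
      fvs = rnorm(n, 1.2, 0.4), cd45 = rnorm(n, 0.8, 0.3),
      tcpp = rnorm(n, 0.7, 0.3), lineage = rnorm(n, 0.7, 0.3),
      cd206 = rnorm(n, 0.7, 0.3)),
    dead = function(n) list(
      fsc_a = ln(n, 9e4, 0.25), ssc_a = ln(n, 3.5e4, 0.35),
      fvs = rnorm(n, 3.3, 0.25), cd45 = rnorm(n, 3.0, 0.3),
      tcpp = rnorm(n, 1.8, 0.4), lineage = rnorm(n, 1.8, 0.5),
      cd206 = rnorm(n, 1.6, 0.5)),
    leukocyte = function(n) list(
      fsc_a = ln(n, 7e4, 0.15), ssc_a = ln(n, 1.8e4, 0.22),
      fvs = rnorm(n, 0.8, 0.25), cd45 = rnorm(n, 3.2, 0.2),
      tcpp = rnorm(n, 0.8, 0.25), lineage = rnorm(n, 2.72, 0.09),
      cd206 = rnorm(n, 0.8, 0.2)),
    macrophage = function(n) list(
      fsc_a = ln(n, 1.1e5, 0.18), ssc_a = ln(n, 3e4, 0.25),
      fvs = rnorm(n, 0.9, 0.25), cd45 = rnorm(n, 3.0, 0.25),
      tcpp = rnorm(n, 1.3, 0.3), lineage = rnorm(n, 1.9, 0.18),
      cd206 = rnorm(n, 3.1, 0.18)),
    other = function(n) list(
      fsc_a = ln(n, 8e4, 0.18), ssc_a = ln(n, 2e4, 0.25),
      fvs = rnorm(n, 0.8, 0.25), cd45 = rnorm(n, 2.2, 0.4),
      tcpp = rnorm(n, 0.8, 0.25), lineage = rnorm(n, 0.9, 0.25),
      cd206 = rnorm(n, 1.0, 0.3)),
    tcpp_bright = function(n) list(
      fsc_a = ln(n, 8e4, 0.18), ssc_a = ln(n, 2e4, 0.25),
      fvs = rnorm(n, 0.8, 0.25), cd45 = rnorm(n, 2.2, 0.4),
      tcpp = rnorm(n, 3.6, 0.15), lineage = rnorm(n, 0.9, 0.25),
      cd206 = rnorm(n, 1.0, 0.3)),
    stressed = function(n) list(
      fsc_a = ln(n, 2.7e4, 0.04), ssc_a = ln(n, 1.2e4, 0.2),
      fvs = rnorm(n, 1.165, 0.03), cd45 = rnorm(n, 2.5, 0.3),
      tcpp = rnorm(n, 0.8, 0.25), lineage = rnorm(n, 1.0, 0.3),
      cd206 = rnorm(n, 0.9, 0.3)),
    corner = function(n) list(
      fsc_a = ln(n, 2.2e5, 0.05), ssc_a = ln(n, 1.5e4, 0.3),
      fvs = rnorm(n, 1.5, 0.4), cd45 = rnorm(n, 1.5, 0.4),
      tcpp = rnorm(n, 1.0, 0.3), lineage = rnorm(n, 1.0, 0.3),
      cd206 = rnorm(n, 1.0, 0.3)),
    contaminant = function(n) list(
      fsc_a = ln(n, 1.6e5, 0.15), ssc_a = ln(n, 1.2e5, 0.25),
      fvs = rnorm(n, 0.9, 0.3), cd45 = rnorm(n, 2.0, 0.4),
      tcpp = rnorm(n, 1.0, 0.3), lineage = rnorm(n, 1.0, 0.3),
      cd206 = rnorm(n, 1.0, 0.3)))
}

LIVE_POPS <- c("leukocyte", "macrophage", "other", "tcpp_bright", "stressed")

# scatter pulse geometry: height and width track area along a tight ridge
# for single cells; doublets double the area but keep a single cell's
# width, dropping them below the ridge band the singlets gate fits
pulseGeometry <- function(pop, fsc_a, ssc_a) {
  n <- length(fsc_a)
  fsc_h <- fsc_a * rnorm(n, 0.95, 0.02)
  ssc_h <- ssc_a * rnorm(n, 0.93, 0.03)
  fsc_w <- fsc_a * rnorm(n, 0.88, 0.03)
  if (pop == "doublet") fsc_w <- fsc_a / 2 * rnorm(n, 0.88, 0.03)
  if (pop == "contaminant") fsc_w <- pmax(rnorm(n, 2.5e4, 1.2e4), 0)
  if (pop == "corner") ssc_h <- runif(n, 0, 400)
  cbind(fsc_a = fsc_a, fsc_h = fsc_h, fsc_w = fsc_w,
        ssc_a = ssc_a, ssc_h = ssc_h)
}

# assemble one assay tube: truth labels, raw channel matrix with spillover
# and autofluorescence applied, ascending Time channel
buildAssayTube <- function(spec, lp, roles, fluor_cols, tube = "blood") {
  n <- spec$n_events
  fr <- spec$fractions
  live_total <- 1 - fr[["debris"]] - fr[["dead"]] - fr[["doublet"]] -
    spec$corner_fraction - spec$contaminant_fraction
  f_tcpp <- live_total * spec$tcpp_r3_per10k / 1e4
  f_stress <- live_total * spec$fvs_r2_per10k / 1e4
  probs <- c(fr["debris"], fr["dead"], fr["doublet"], fr["leukocyte"],
             fr["macrophage"], f_tcpp, f_stress,
             corner = spec$corner_fraction,
             contaminant = spec$contaminant_fraction)
  probs <- c(probs, other = 1 - sum(probs))
  names(probs) <- c("debris", "dead", "doublet", "leukocyte", "macrophage",
                    "tcpp_bright", "stressed", "corner", "contaminant",
                    "other")
  pop <- sample(names(probs), n, replace = TRUE, prob = probs)
  models <- popChannelModels()
  scatter <- matrix(0, n, 5L)
  fluor_logicle <- matrix(0, n, 5L)
  for (p in unique(pop)) {
    i <- which(pop == p)
    if (p == "doublet") {
      a <- models$other(length(i)); b <- models$other(length(i))
      d <- list(fsc_a = a$fsc_a + b$fsc_a, ssc_a = a$ssc_a + b$ssc_a,
                fvs = a$fvs, cd45 = a$cd45, tcpp = a$tcpp,
                lineage = a$lineage, cd206 = a$cd206)
    } else d <- models[[p]](length(i))
    scatter[i, ] <- pulseGeometry(p, d$fsc_a, d$ssc_a)
    fluor_logicle[i, ] <- cbind(d$fvs, d$cd45, d$tcpp, d$lineage, d$cd206)
  }
  # epithelial tube reuses the lineage/cd206 draws as panck/epcam, with
  # bright epithelial signal on the 'other' (largely epithelial) cells
  if (tube == "epithelial") {
    epi <- pop %in% c("other", "tcpp_bright", "stressed")
    fluor_logicle[epi, 4L] <- rnorm(sum(epi), 2.8, 0.3)
    fluor_logicle[epi, 5L] <- rnorm(sum(epi), 2.7, 0.3)
  }
  # planted logicle values already include autofluorescence, so spillover is
  # the only distortion the pipeline must undo for assay tubes
  raw_fluor <- apply(fluor_logicle, 2L, inverseLogicle, p = lp)
  observed <- raw_fluor %*% spec$spillover
  tm <- cumsum(rexp(n, rate = 1)) * 100
  m <- cbind(scatter, pmin(pmax(observed, 0), RAW_FULL_SCALE), Time = tm)
  m[, 1:5] <- pmin(pmax(m[, 1:5], 0), RAW_FULL_SCALE)
  colnames(m) <- c(roles[SCATTER_ROLES], fluor_cols, roles[["TIME"]])
  truth <- data.frame(
    population = pop,
    live = pop %in% LIVE_POPS,
    singlet = !pop %in% c("doublet", "corner", "contaminant", "debris",
                          "dead"))
  list(table = flowEventTable(m, roles = roles), truth = truth)
}

#' Generate one synthetic multi-tube sample with ground truth
#'
#' Emulates the full tube set of the assay: NIST bead tube, per-fluorochrome
#' single-stain compensation controls, unstained sputum, isotype control,
#' blood tube and epithelial tube, with a known spillover matrix applied and
#' per-event population truth labels retained for oracle tests.
#'
#' @param status \code{"non-cancer"} or \code{"cancer"}.
#' @param spec a [sampleSpec()]; defaults to the class defaults.
#' @param seed integer seed; the same seed reproduces the sample
#'   byte-identically.
#' @param instrument channel dialect name (see [channelDialect()]).
#' @param logicle_params logicle parameters used to invert fluorescence
#'   draws to the raw scale.
#' @return list with \code{tubes} (named list: beads, unstained, controls
#'   (list per role), isotype, blood, epithelial), \code{truth} (data.frame
#'   per assay tube: population, live, singlet), \code{spillover} and
#'   \code{spec}.
#' @export
generateSample <- function(status = c("non-cancer", "cancer"),
                           spec = NULL, seed = 1L,
                           instrument = "lsr2",
                           logicle_params = logicleParams()) {
  status <- match.arg(status)
  spec <- spec %||% sampleSpec(status)
  roles <- channelDialect(instrument)
  lp <- logicle_params
  withSeed(seed, {
    blood_roles <- roles[c(SCATTER_ROLES, BLOOD_FLUOR_ROLES, "TIME")]
    epi_roles <- roles[c(SCATTER_ROLES, EPI_FLUOR_ROLES, "TIME")]
    # bead tube: dominant 5-micron cluster plus uniform noise
    nb <- spec$n_beads
    n_noise <- round(0.1 * nb)
    bead_m <- cbind(
      fsc_a = c(rnorm(nb - n_noise, 3e4, 2e3),
                runif(n_noise, 0, RAW_FULL_SCALE)),
      fsc_h = 0, fsc_w = rnorm(nb, 6.5e4, 3e3),
      ssc_a = c(rnorm(nb - n_noise, 1.5e4, 1.5e3),
                runif(n_noise, 0, RAW_FULL_SCALE)),
      ssc_h = 0, Time = cumsum(rexp(nb)) * 100)
    bead_m[, "fsc_h"] <- bead_m[, "fsc_a"] * rnorm(nb, 0.97, 0.01)
    bead_m[, "ssc_h"] <- bead_m[, "ssc_a"] * rnorm(nb, 0.95, 0.02)
    bead_m[, 1:5] <- pmin(pmax(bead_m[, 1:5], 0), RAW_FULL_SCALE)
    colnames(bead_m) <- c(roles[c("FSC-A", "FSC-H", "FSC-W", "SSC-A",
                                  "SSC-H")], roles[["TIME"]])
    beads <- flowEventTable(bead_m, roles = roles[c(SCATTER_ROLES, "TIME")])
    # unstained + isotype: cell-like scatter, baseline fluorescence only
    baselineTube <- function(n, roles_v, fluor_roles) {
      sc <- pulseGeometry("other", rlnorm(n, log(7e4), 0.2),
                          rlnorm(n, log(2e4), 0.25))
      base <- matrix(inverseLogicle(rnorm(length(fluor_roles) * n, 0.45,
                                          0.15), lp), n)
      obs <- base %*% spec$spillover[seq_along(fluor_roles),
                                     seq_along(fluor_roles)]
      m <- cbind(sc, pmin(pmax(obs, 0), RAW_FULL_SCALE),
                 Time = cumsum(rexp(n)) * 100)
      m[, 1:5] <- pmin(pmax(m[, 1:5], 0), RAW_FULL_SCALE)
      colnames(m) <- c(roles_v[SCATTER_ROLES], roles_v[fluor_roles],
                       roles_v[["TIME"]])
      flowEventTable(m, roles = roles_v)
    }
    unstained <- baselineTube(spec$n_unstained, blood_roles,
                              BLOOD_FLUOR_ROLES)
    isotype <- baselineTube(spec$n_unstained, blood_roles,
                            BLOOD_FLUOR_ROLES)
    # single-stain compensation controls
    controls <- setNames(lapply(seq_along(BLOOD_FLUOR_ROLES), function(i) {
      nc <- spec$n_control
      n_pos <- round(nc / 2)
      primary <- c(inverseLogicle(rnorm(n_pos, 3.8, 0.15), lp),
                   rep(0, nc - n_pos))
      true <- matrix(0, nc, length(BLOOD_FLUOR_ROLES))
      true[, i] <- primary
      base <- matrix(inverseLogicle(rnorm(length(BLOOD_FLUOR_ROLES) * nc,
                                          0.45, 0.15), lp), nc)
      obs <- (true + base) %*% spec$spillover
      sc <- pulseGeometry("other", rlnorm(nc, log(7e4), 0.2),
                          rlnorm(nc, log(2e4), 0.25))
      m <- cbind(sc, pmin(pmax(obs, 0), RAW_FULL_SCALE),
                 Time = cumsum(rexp(nc)) * 100)
      m[, 1:5] <- pmin(pmax(m[, 1:5], 0), RAW_FULL_SCALE)
      colnames(m) <- c(blood_roles[SCATTER_ROLES],
                       blood_roles[BLOOD_FLUOR_ROLES],
                       blood_roles[["TIME"]])
      flowEventTable(m, roles = blood_roles)
    }), BLOOD_FLUOR_ROLES)
    blood <- buildAssayTube(spec, lp, blood_roles,
                            blood_roles[BLOOD_FLUOR_ROLES], "blood")
    epi_spill <- spec$spillover
    dimnames(epi_spill) <- list(EPI_FLUOR_ROLES, EPI_FLUOR_ROLES)
    epi_spec <- spec; epi_spec$spillover <- epi_spill
    epithelial <- buildAssayTube(epi_spec, lp, epi_roles,
                                 epi_roles[EPI_FLUOR_ROLES], "epithelial")
    list(tubes = list(beads = beads, unstained = unstained,
                      controls = controls, isotype = isotype,
                      blood = blood$table, epithelial = epithelial$table),
         truth = list(blood = blood$truth, epithelial = epithelial$truth),
         spillover = spec$spillover, spec = spec, seed = seed)
  })
}

#' Generate a synthetic cohort of feature vectors (or full tube sets)
#'
#' Fast \code{"features"} mode draws the classifier features directly from
#' class-conditional distributions (binomial per-10K counts around a
#' lognormally varying per-sample rate); its default targets are the
#' effective rates the full pipeline recovers from [generateSample()] under
#' the default specs, so the two modes agree in distribution;
#' \code{"fcs"} mode generates full tube sets per sample for end-to-end
#' runs.  Cancer labels are assigned exactly (\code{round(n_samples *
#' cancer_fraction)}).
#'
#' @param n_samples cohort size.
#' @param cancer_fraction fraction of cancer samples (default 28/150, the
#'   development-cohort ratio).
#' @param targets named list with per-class per-10K targets
#'   (\code{tcpp_r3}, \code{fvs_r2}, \code{cd206low_linmid}) and mean ages;
#'   see defaults.  Setting both classes equal yields a null cohort.
#' @param sample_cv lognormal coefficient of variation of per-sample rates.
#' @param mode \code{"features"} or \code{"fcs"}.
#' @param n_events events per assay tube in \code{"fcs"} mode.
#' @param seed integer seed.
#' @return list with \code{features} (data.frame), \code{labels} (0/1) and,
#'   in \code{"fcs"} mode, \code{samples} (list of [generateSample()]
#'   outputs).
#' @export
generateCohort <- function(n_samples = 150L, cancer_fraction = 28 / 150,
                           targets = list(
                             noncancer = c(tcpp_r3 = 55, fvs_r2 = 450,
                                           cd206low_linmid = 2850,
                                           age = 65),
                             cancer = c(tcpp_r3 = 390, fvs_r2 = 1050,
                                        cd206low_linmid = 2850,
                                        age = 72)),
                           sample_cv = 0.3, mode = c("features", "fcs"),
                           n_events = 50000L, seed = 1L) {
  mode <- match.arg(mode)
  if (cancer_fraction <= 0 || cancer_fraction >= 1)
    stop("cancer_fraction must lie in (0, 1)")
  n_cancer <- round(n_samples * cancer_fraction)
  if (n_cancer < 1L || n_cancer >= n_samples)
    stop("infeasible class counts for n_samples = ", n_samples)
  labels <- c(rep(1L, n_cancer), rep(0L, n_samples - n_cancer))
  if (mode == "fcs") {
    samples <- lapply(seq_len(n_samples), function(i)
      generateSample(if (labels[i] == 1L) "cancer" else "non-cancer",
                     spec = sampleSpec(
                       if (labels[i] == 1L) "cancer" else "non-cancer",
                       n_events = n_events),
                     seed = childSeed(seed, i)))
    ages <- withSeed(childSeed(seed, 999), round(rnorm(
      n_samples, ifelse(labels == 1L, targets$cancer[["age"]],
                        targets$noncancer[["age"]]), 6)))
    return(list(samples = samples, labels = labels,
                ages = pmax(pmin(ages, 90), 40)))
  }
  withSeed(seed, {
    cls <- ifelse(labels == 1L, "cancer", "noncancer")
    n_vs <- round(runif(n_samples, 22000, 34000))
    draw10k <- function(key) {
      tgt <- vapply(cls, function(cc) targets[[cc]][[key]], 0)
      p <- pmin(tgt / 1e4 * rlnorm(n_samples, -sample_cv^2 / 2, sample_cv),
                0.9)
      rbinom(n_samples, n_vs, p) / n_vs * 1e4
    }
    feats <- data.frame(
      age = pmax(pmin(round(rnorm(n_samples, vapply(
        cls, function(cc) targets[[cc]][["age"]], 0), 6)), 90), 40),
      tcpp_r3_per10k = draw10k("tcpp_r3"),
      fvs_r2_per10k = draw10k("fvs_r2"),
      cd206low_linmid_per10k = draw10k("cd206low_linmid"),
      macrophages = rbinom(n_samples, n_vs, 0.17),
      viable_singlets = n_vs)
    list(features = feats, labels = labels)
  })
}
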
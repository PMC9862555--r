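# Shared fixtures: generated once per test run and cached, so the seeded
# replicate suites and the per-module tests reuse the same gated samples.

.fixture_cache <- new.env(parent = emptyenv())

# generate, compensate with the generator's known spillover, logicle, gate
gatedSample <- function(status = "non-cancer", seed = 1L, n_events = 20000L,
                        ...) {
  key <- paste(status, seed, n_events, ...)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  smp <- generateSample(status, spec = sampleSpec(status,
                                                  n_events = n_events, ...),
                        seed = seed)
  tubes <- smp$tubes
  tubes$blood <- logicleTube(compensate(tubes$blood, smp$spillover))
  g <- runGating(tubes, "blood", seed = seed)
  out <- list(smp = smp, tubes = tubes, gating = g,
              truth = smp$truth$blood)
  .fixture_cache[[key]] <- out
  out
}

# minimal one-channel-plus-support event table on chosen scales
miniTube <- function(n, fvs = NULL, fsc_a = NULL, ssc_a = NULL,
                     fsc_w = NULL, tcpp = NULL, cd206 = NULL,
                     lineage = NULL, time = NULL) {
  cols <- list(
    `FSC-A` = fsc_a %||% rep(5e4, n), `SSC-A` = ssc_a %||% rep(2e4, n),
    `FSC-H` = (fsc_a %||% rep(5e4, n)) * 0.95,
    `SSC-H` = (ssc_a %||% rep(2e4, n)) * 0.93,
    `FSC-W` = fsc_w %||% (fsc_a %||% rep(5e4, n)) * 0.88,
    `BV510-A` = fvs %||% rep(1, n), `PerCP-Cy5-5-A` = tcpp %||% rep(1, n),
    `PE-A` = cd206 %||% rep(1, n), `FITC-A` = lineage %||% rep(2.7, n),
    Time = time %||% seq_len(n))
  m <- do.call(cbind, cols)
  roles <- c(`FSC-A` = "FSC-A", `SSC-A` = "SSC-A", `FSC-H` = "FSC-H",
             `SSC-H` = "SSC-H", `FSC-W` = "FSC-W", FVS510 = "BV510-A",
             TCPP = "PerCP-Cy5-5-A", CD206 = "PE-A", LINEAGE = "FITC-A",
             TIME = "Time")
  scale <- setNames(rep("raw", ncol(m)), colnames(m))
  scale[c("BV510-A", "PerCP-Cy5-5-A", "PE-A", "FITC-A")] <- "logicle"
  flowEventTable(m, roles = roles, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
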
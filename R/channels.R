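#' Built-in instrument channel dialects
#'
#' Two instrument dialects are shipped: \code{"lsr2"} (BD LSR II style
#' fluorochrome-named detectors) and \code{"navios"} (Beckman Coulter Navios
#' style numbered FL detectors).  A dialect maps each logical role used by
#' the pipeline to the instrument's channel name.  Unknown instruments
#' require a user-supplied map of the same shape.
#'
#' Roles: scatter (\code{FSC-A}, \code{FSC-H}, \code{FSC-W}, \code{SSC-A},
#' \code{SSC-H}), \code{TIME}, and fluorescence (\code{FVS510} viability
#' stain, \code{CD45}, \code{TCPP} porphyrin, \code{LINEAGE} pooled
#' CD66b/CD3/CD19, \code{CD206}, and the epithelial-tube pair \code{PANCK},
#' \code{EPCAM}).
#'
#' @param instrument \code{"lsr2"} or \code{"navios"}.
#' @return named character vector, role -> channel name.
#' @examples
#' channelDialect("lsr2")[["FVS510"]]
#' @export
channelDialect <- function(instrument = c("lsr2", "navios")) {
  instrument <- match.arg(instrument)
  common <- c(`FSC-A` = "FSC-A", `FSC-H` = "FSC-H", `FSC-W` = "FSC-W",
              `SSC-A` = "SSC-A", `SSC-H` = "SSC-H", TIME = "Time")
  fluor <- switch(instrument,
    lsr2 = c(FVS510 = "BV510-A", CD45 = "APC-Cy7-A", TCPP = "PerCP-Cy5-5-A",
             LINEAGE = "FITC-A", CD206 = "PE-A", PANCK = "AF647-A",
             EPCAM = "PE-Cy7-A"),
    navios = c(FVS510 = "FL10-A", CD45 = "FL8-A", TCPP = "FL4-A",
               LINEAGE = "FL1-A", CD206 = "FL2-A", PANCK = "FL6-A",
               EPCAM = "FL5-A"))
  map <- c(common, fluor)
  if (anyDuplicated(map)) stop("dialect maps two roles to one channel")
  map
}

# Role groups used throughout the pipeline.
SCATTER_ROLES <- c("FSC-A", "FSC-H", "FSC-W", "SSC-A", "SSC-H")
BLOOD_FLUOR_ROLES <- c("FVS510", "CD45", "TCPP", "LINEAGE", "CD206")
EPI_FLUOR_ROLES <- c("FVS510", "CD45", "TCPP", "PANCK", "EPCAM")

#' Read or write a channel-role map as a key=value config file
#'
#' @param path file path.
#' @param map named character vector role -> channel name.
#' @return \code{readChannelMap()} returns the named character vector.
#' @export
readChannelMap <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed channel map line")
  setNames(trimws(vapply(kv, `[`, "", 2L)), trimws(vapply(kv, `[`, "", 1L)))
}

#' @rdname readChannelMap
#' @export
writeChannelMap <- function(map, path) {
  writeLines(paste0(names(map), " = ", map), path)
  invisible(path)
}
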
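#' Read an FCS 3.0/3.1 file into a FlowEventTable
#'
#' A minimal list-mode FCS reader: parses the ASCII header and delimited TEXT
#' segment, then decodes the DATA segment (float \code{$DATATYPE F} or double
#' \code{D}, little- or big-endian).  The decoded event count must equal the
#' header-declared \code{$TOT}; a short or corrupt data segment is a fatal
#' QC failure, mirroring the pipeline's first decision diamond.
#'
#' @param path path to an FCS file.
#' @param map named character vector role -> instrument channel name (see
#'   [channelDialect()]).
#' @param required character vector of roles that must resolve to a present
#'   channel; defaults to scatter + TIME.  A missing role is a fatal error
#'   naming the role.
#' @return a \linkS4class{FlowEventTable} with all channels flagged raw.
#' @export
readFCS <- function(path, map = channelDialect("lsr2"),
                    required = c(SCATTER_ROLES, "TIME")) {
  if (!file.exists(path)) stop("file QC failure: no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 58) stop("file QC failure: not an FCS file: ", path)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("file QC failure: unsupported FCS version '", version, "'")
  offs <- vapply(0:5, function(k) {
    suppressWarnings(as.numeric(trimws(rawToChar(raw[(11 + 8 * k):(18 + 8 * k)]))))
  }, 0)
  if (any(is.na(offs[1:2]))) stop("file QC failure: malformed FCS header")
  txt <- rawToChar(raw[(offs[1] + 1):(offs[2] + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- c("$PAR", "$TOT", "$DATATYPE", "$BYTEORD")
  if (!all(need %in% names(kw)))
    stop("file QC failure: missing required FCS keywords")
  npar <- as.integer(kw["$PAR"]); ntot <- as.integer(kw["$TOT"])
  dtype <- toupper(trimws(kw["$DATATYPE"]))
  if (!dtype %in% c("F", "D"))
    stop("file QC failure: unsupported $DATATYPE '", dtype, "'")
  size <- if (dtype == "F") 4L else 8L
  endian <- if (startsWith(kw["$BYTEORD"], "1")) "little" else "big"
  dbeg <- offs[3]; dend <- offs[4]
  if (is.na(dbeg) || dbeg == 0) dbeg <- as.numeric(kw["$BEGINDATA"])
  if (is.na(dend) || dend == 0) dend <- as.numeric(kw["$ENDDATA"])
  expected <- as.numeric(ntot) * npar * size
  avail <- min(dend, length(raw)) - dbeg + 1
  if (!is.finite(avail) || avail < expected)
    stop("incomplete data matrix: declared ", ntot, " events (",
         expected, " bytes), found ", max(avail, 0), " bytes")
  vals <- readBin(raw[(dbeg + 1):(dbeg + expected)], "numeric",
                  n = ntot * npar, size = size, endian = endian)
  if (length(vals) != ntot * npar)
    stop("incomplete data matrix: decoded ", length(vals) %/% npar,
         " events, declared ", ntot)
  ch <- vapply(seq_len(npar), function(i) {
    v <- kw[paste0("$P", i, "N")]
    if (is.na(v)) paste0("P", i) else trimws(v)
  }, "")
  m <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE,
              dimnames = list(NULL, ch))
  present <- names(map)[map %in% ch]
  missing_req <- setdiff(required, present)
  if (length(missing_req))
    stop("file QC failure: required role(s) not present in ", basename(path),
         ": ", paste(missing_req, collapse = ", "))
  flowEventTable(m, roles = map[present])
}

#' Write a FlowEventTable (or matrix) as FCS 3.1
#'
#' Writes little-endian float32 list-mode data with the standard TEXT
#' keywords; used to materialise synthetic fixtures.  Values are stored at
#' float32 precision, so a read-write-read roundtrip is bit-stable.
#'
#' @param x a \linkS4class{FlowEventTable} or a numeric matrix with channel
#'   colnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFCS <- function(x, path) {
  m <- if (is(x, "FlowEventTable")) events(x) else x
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  npar <- ncol(m); ntot <- nrow(m)
  d <- "/"
  kv <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(npar),
          "$TOT" = as.character(ntot))
  for (i in seq_len(npar)) {
    kv[paste0("$P", i, "N")] <- colnames(m)[i]
    kv[paste0("$P", i, "B")] <- "32"
    kv[paste0("$P", i, "E")] <- "0,0"
    kv[paste0("$P", i, "R")] <- as.character(RAW_FULL_SCALE)
  }
  build <- function(kv) paste0(d, paste0(names(kv), d, kv, d, collapse = ""))
  # fixed-width data offsets so the TEXT length is stable across substitution
  kv["$BEGINDATA"] <- strrep("0", 12L); kv["$ENDDATA"] <- strrep("0", 12L)
  txt_len <- nchar(build(kv), type = "bytes")
  tbeg <- 58L
  tend <- tbeg + txt_len - 1L
  dbeg <- tend + 1L
  dend <- dbeg + ntot * npar * 4L - 1L
  kv["$BEGINDATA"] <- sprintf("%012d", dbeg)
  kv["$ENDDATA"] <- sprintf("%012d", dend)
  txt <- build(kv)
  hdr_off <- function(v) formatC(v, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", hdr_off(tbeg), hdr_off(tend),
                   if (dend <= 99999999) paste0(hdr_off(dbeg), hdr_off(dend))
                   else paste0(hdr_off(0), hdr_off(0)),
                   hdr_off(0), hdr_off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}
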
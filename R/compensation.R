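#' Derive a spillover matrix de novo from single-stain controls
#'
#' For each fluorescence channel a single-stain control tube provides a
#' positive population.  Events of each control are split into positive and
#' negative groups by a one-dimensional two-component mixture on the
#' control's primary channel; spillover entry (i, j) is the
#' background-subtracted median signal of the channel-i-positive events in
#' channel j, normalised so the diagonal is 1.
#'
#' @param controls named list of \linkS4class{FlowEventTable}s, one per
#'   fluorescence role; names are the roles they single-stain.
#' @param unstained \linkS4class{FlowEventTable} providing the per-channel
#'   background medians.
#' @param seed integer seed for the mixture split subsample.
#' @return a square numeric spillover matrix with role dimnames, diagonal 1.
#' @export
deriveSpillover <- function(controls, unstained, seed = 1L) {
  roles <- names(controls)
  if (is.null(roles) || anyDuplicated(roles))
    stop("controls must be a uniquely named list (one per fluorochrome)")
  S <- diag(length(roles))
  dimnames(S) <- list(roles, roles)
  bg <- vapply(roles, function(r) median(chan(unstained, r)), 0)
  for (i in seq_along(roles)) {
    ri <- roles[i]
    v <- chan(controls[[ri]], ri)
    idx <- fitSubsample(length(v), 5000L, childSeed(seed, i))
    fit <- withSeed(childSeed(seed, i), suppressWarnings(
      mclust::Mclust(v[idx], G = 2, modelNames = "V", verbose = FALSE)))
    if (is.null(fit)) stop("uninformative control for channel ", ri)
    hi_comp <- which.max(fit$parameters$mean)
    cutpoint <- mean(fit$parameters$mean)
    pos <- v > cutpoint
    neg_med <- median(v[!pos]); pos_med <- median(v[pos])
    sep <- (pos_med - neg_med) /
      max(mad(v[!pos]), 1e-8)
    if (!any(pos) || !any(!pos) || sep < 5)
      stop("uninformative control for channel ", ri,
           ": positive and negative medians indistinguishable")
    denom <- pos_med - bg[i]
    for (j in seq_along(roles)) {
      if (j == i) next
      vj <- chan(controls[[ri]], roles[j])
      S[i, j] <- (median(vj[pos]) - bg[j]) / denom
    }
  }
  S[!diag(length(roles))] <- pmax(S[!diag(length(roles))], 0)
  if (abs(det(S)) < 1e-12) stop("derived spillover matrix is singular")
  S
}

#' Apply (or export) spillover compensation
#'
#' Replaces the fluorescence columns of a raw tube by observed x inverse
#' (spillover); scatter and Time are untouched and negative compensated
#' values are retained for the logicle transform.
#'
#' @param t a \linkS4class{FlowEventTable} with raw fluorescence.
#' @param s square spillover matrix with fluorescence-role dimnames.
#' @return the compensated tube (scale flags updated).
#' @export
compensate <- function(t, s) {
  roles <- rownames(s)
  if (is.null(roles)) stop("spillover matrix must carry role dimnames")
  chs <- t@roles[roles]
  if (anyNA(chs)) stop("tube lacks fluorescence role(s): ",
                       paste(roles[is.na(chs)], collapse = ", "))
  if (any(t@scale[chs] != "raw"))
    stop("compensate expects raw fluorescence channels")
  inv <- tryCatch(solve(s), error = function(e)
    stop("singular spillover matrix: ", conditionMessage(e)))
  m <- t@exprs
  m[, chs] <- m[, chs, drop = FALSE] %*% inv
  sc <- t@scale
  sc[chs] <- "compensated"
  initialize(t, exprs = m, scale = sc)
}

#' Read/write a spillover matrix as CSV with a channel-name header row
#'
#' @param s spillover matrix; \code{path} file path.
#' @param path file path.
#' @return \code{readSpillover()} returns the matrix.
#' @export
writeSpillover <- function(s, path) {
  utils::write.csv(as.data.frame(s), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeSpillover
#' @export
readSpillover <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
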
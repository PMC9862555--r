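#' Logicle (biexponential) display transform
#'
#' The logicle scale maps compensated fluorescence, including the negative
#' values that arise after spillover correction, onto display decades.  It is
#' the biexponential family \deqn{S(x) = a e^{bx} - c e^{-dx} - f}{S(x) = a
#' exp(bx) - c exp(-dx) - f} (mirrored below its zero point) parameterised by
#' the top of scale \code{T}, the number of display decades \code{M}, the
#' linearisation width \code{W} and additional negative decades \code{A}.
#' \code{logicle()} returns values in decades such that a signal of \code{T}
#' maps exactly to \code{M}; \code{inverseLogicle()} is its exact inverse.
#'
#' @param T top of scale (default 262144, the 18-bit full range).
#' @param M total display decades (default 4.5).
#' @param W linearisation width in decades (default 0.5).
#' @param A additional negative display decades (default 0).
#' @return \code{logicleParams()} returns a \code{"LogicleParams"} object
#'   with the derived biexponential coefficients.
#' @references Parks, Roederer and Moore's biexponential display method for
#'   flow cytometry data.
#' @export
logicleParams <- function(T = 262144, M = 4.5, W = 0.5, A = 0) {
  stopifnot(T > 0, M > 0, W >= 0, A >= 0)
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * log(10)
  d <- if (w <= .Machine$double.eps) b else
    uniroot(function(dd) 2 * (log(dd) - log(b)) + w * (b + dd),
            c(.Machine$double.xmin^0.25, b), tol = 1e-14)$root
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a * exp(-d * x1)
  a <- T / ((exp(b) - mf_a) - c_a * exp(-d))
  structure(list(T = T, M = M, W = W, A = A,
                 a = a, b = b, c = c_a * a, d = d, f = mf_a * a, x1 = x1),
            class = "LogicleParams")
}

# biexponential scale function on the normalised display coordinate x in
# [0, 1]; values below x1 use the mirrored negative branch
logicleScaleFun <- function(x, p) {
  neg <- x < p$x1
  xx <- ifelse(neg, 2 * p$x1 - x, x)
  v <- p$a * exp(p$b * xx) - p$c * exp(-p$d * xx) - p$f
  ifelse(neg, -v, v)
}

#' @rdname logicleParams
#' @param values numeric vector of (compensated) signal values.
#' @param p a \code{"LogicleParams"} object.
#' @export
logicle <- function(values, p = logicleParams()) {
  stopifnot(inherits(p, "LogicleParams"))
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("non-finite input to logicle at indices: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...")
  if (!length(values)) return(numeric())
  # solve S(x) = |v| on the positive branch, mirror negatives
  av <- abs(values)
  hi <- 1
  vmax <- max(av)
  while (logicleScaleFun(hi, p) < vmax) hi <- hi + 0.5
  lo_b <- rep(p$x1, length(av))
  hi_b <- rep(hi, length(av))
  for (i in 1:30) {                       # bisection to ~1e-9 of the bracket
    mid <- (lo_b + hi_b) / 2
    below <- logicleScaleFun(mid, p) < av
    lo_b[below] <- mid[below]
    hi_b[!below] <- mid[!below]
  }
  x <- (lo_b + hi_b) / 2
  for (i in 1:4) {                        # Newton polish
    fx <- p$a * exp(p$b * x) - p$c * exp(-p$d * x) - p$f - av
    dfx <- p$a * p$b * exp(p$b * x) + p$c * p$d * exp(-p$d * x)
    x <- x - fx / dfx
  }
  x <- ifelse(values < 0, 2 * p$x1 - x, x)
  x * (p$M + p$A) - p$A
}

#' @rdname logicleParams
#' @param decades numeric vector of logicle display values (decades).
#' @export
inverseLogicle <- function(decades, p = logicleParams()) {
  stopifnot(inherits(p, "LogicleParams"))
  logicleScaleFun((decades + p$A) / (p$M + p$A), p)
}

#' Apply the logicle transform to the fluorescence channels of a tube
#'
#' Scatter and Time channels are left untouched (linear); each fluorescence
#' channel must be compensated (or raw, for unstained/control tubes) before
#' transformation.
#'
#' @param t a \linkS4class{FlowEventTable}.
#' @param roles fluorescence roles to transform; defaults to every mapped
#'   fluorescence role present.
#' @param p logicle parameters applied to every channel (configurable per
#'   call).
#' @return the tube with fluorescence columns on the logicle scale.
#' @export
logicleTube <- function(t, roles = NULL,
                        p = logicleParams()) {
  if (is.null(roles))
    roles <- intersect(union(BLOOD_FLUOR_ROLES, EPI_FLUOR_ROLES),
                       names(t@roles))
  m <- t@exprs
  sc <- t@scale
  for (r in roles) {
    ch <- t@roles[[r]]
    if (sc[[ch]] == "logicle") next
    m[, ch] <- logicle(m[, ch], p)
    sc[[ch]] <- "logicle"
  }
  initialize(t, exprs = m, scale = sc)
}
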
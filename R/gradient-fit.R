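#' Fit an exponential trend to an intensity profile
#'
#' Nonlinear least-squares fit of
#' \code{v(x) = background + A * exp(-(x - xMax)/lambda)} over the region
#' from the profile maximum (at \code{xMax}) toward the proximal end, with
#' log-linear initialization. Reports the gradient-steepness statistic:
#' the slope of the straight line joining Cmax (the fitted curve value at
#' xMax) to the half-maximum point, i.e.
#' \code{slope = (Cmax - Chalf)/(xHalf - xMax)} with
#' \code{Chalf = background + (Cmax - background)/2}; for zero background
#' this equals \code{Cmax/(2 * lambda * ln 2)}. Non-decaying profiles
#' (flat, or with a non-positive or unbounded decay-length estimate) are
#' returned flagged, with the slope undefined.
#'
#' @param profile an \code{\linkS4class{IntensityProfile}} with at least
#'   5 points.
#' @param fitBackground fit an additive baseline (default TRUE); when
#'   FALSE the background is fixed at 0.
#' @return a \code{\linkS4class{GradientFit}}.
#' @examples
#' x <- seq(0, 120, 1)
#' f <- fitExponential(intensityProfile(x, 100 * exp(-x / 20)),
#'                     fitBackground = FALSE)
#' slopeStat(f)  # 100 / (2 * 20 * log(2)) ~ 3.61 AU/um
#' @export
fitExponential <- function(profile, fitBackground = TRUE) {
  x <- profile@positions
  v <- profile@values
  if (length(x) < 5) stop("need at least 5 profile points")
  flaggedFit <- function() {
    new("GradientFit", cmax = max(v), xMax = x[which.max(v)],
        lambda = NA_real_, background = NA_real_, xHalf = NA_real_,
        slope = NA_real_, r2 = NA_real_, flagged = TRUE)
  }
  if (max(v) <= min(v)) return(flaggedFit())
  iMax <- which.max(v)
  xMax <- x[iMax]
  xs <- x[iMax:length(x)]
  vs <- v[iMax:length(v)]
  if (length(xs) < 5) return(flaggedFit())
  span <- max(xs) - min(xs)
  bg0 <- if (fitBackground) max(min(vs), 0) else 0
  amp0 <- max(vs) - bg0
  pos <- pmax(vs - bg0 + 0.01 * amp0, 1e-9)
  ll <- stats::lm(log(pos) ~ xs)
  lam0 <- -1 / min(stats::coef(ll)[2], -1e-6)
  lam0 <- clamp(lam0, span / 50, span * 5)
  dat <- data.frame(xs = xs, vs = vs)
  fit <- tryCatch({
    if (fitBackground) {
      minpack.lm::nlsLM(vs ~ bg + A * exp(-(xs - xMax) / lam), data = dat,
                        start = list(bg = bg0, A = amp0, lam = lam0),
                        lower = c(bg = 0, A = 0, lam = span / 1e4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(vs ~ A * exp(-(xs - xMax) / lam), data = dat,
                        start = list(A = amp0, lam = lam0),
                        lower = c(A = 0, lam = span / 1e4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(flaggedFit())
  cf <- stats::coef(fit)
  bg <- if (fitBackground) unname(cf["bg"]) else 0
  A <- unname(cf["A"])
  lam <- unname(cf["lam"])
  if (!is.finite(lam) || lam <= 0 || lam > 50 * span || A <= 0) {
    return(flaggedFit())
  }
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((vs - mean(vs))^2)
  cmax <- bg + A
  xHalf <- xMax + lam * log(2)
  slope <- (cmax - (bg + A / 2)) / (xHalf - xMax)
  new("GradientFit", cmax = cmax, xMax = xMax, lambda = lam,
      background = bg, xHalf = xHalf, slope = slope, r2 = r2,
      flagged = FALSE)
}

#' @describeIn fitExponential Fitted decay length lambda (um).
#' @param fit a \code{GradientFit}.
#' @export
decayLength <- function(fit) fit@lambda

#' @describeIn fitExponential Cmax-to-half-max slope statistic (AU/um).
#' @export
slopeStat <- function(fit) fit@slope

#' @describeIn fitExponential Fitted value at the profile maximum (AU).
#' @export
fitCmax <- function(fit) fit@cmax

#' @describeIn fitExponential TRUE for a flagged (non-decaying) fit.
#' @export
isFlagged <- function(fit) fit@flagged

#' @describeIn fitExponential One-row data.frame of the fit parameters.
#' @param x a \code{GradientFit}.
#' @param row.names,optional,... passed on (unused).
#' @export
as.data.frame.GradientFit <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  data.frame(Cmax = x@cmax, x_max = x@xMax, lambda = x@lambda,
             background = x@background, x_half = x@xHalf,
             slope = x@slope, r2 = x@r2, flagged = x@flagged)
}

#' @describeIn fitExponential Compact display.
#' @param object a \code{GradientFit}.
#' @export
setMethod("show", "GradientFit", function(object) {
  if (object@flagged) {
    cat("GradientFit: flagged (non-decaying profile); slope undefined\n")
  } else {
    cat(sprintf(
      "GradientFit: Cmax %.4g AU at %.4g um; lambda %.4g um; bg %.3g;\n",
      object@cmax, object@xMax, object@lambda, object@background))
    cat(sprintf("  x_half %.4g um; slope %.4g AU/um; r2 %.4f\n",
                object@xHalf, object@slope, object@r2))
  }
})

#' Correlate gradient slope with axis length
#'
#' Pearson correlation (two-sided) between the D-P axis length of each
#' tissue and the Cmax-to-half-max slope of its gradient, as used to show
#' that longer tissues carry shallower gradients.
#'
#' @param axisLength numeric vector of axis lengths (um), or a two-column
#'   data.frame/matrix (axis_length, slope).
#' @param slope numeric vector of slopes (AU/um); omitted when the first
#'   argument is two-column.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
correlateSlopeLength <- function(axisLength, slope = NULL) {
  if (is.null(slope)) {
    m <- as.matrix(axisLength)
    axisLength <- m[, 1]
    slope <- m[, 2]
  }
  if (length(axisLength) < 3) stop("need at least 3 pairs")
  if (stats::sd(axisLength) == 0 || stats::sd(slope) == 0) {
    stop("zero variance in axis length or slope")
  }
  ct <- stats::cor.test(axisLength, slope, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(axisLength))
}
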
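#' Clone inside/outside intensity-density ratio
#'
#' Measures the area-normalized intensity density inside a marked clone
#' ROI and in a matched control ROI at the equivalent position, and their
#' outside/inside ratio, as used to compare signal uptake in mosaic mutant
#' clones with their wild-type neighbours. The control ROI must have the
#' same area within \code{areaTolerance} (densities are per-area, but a
#' grossly mismatched control defeats the matched-position design). When
#' no control mask is supplied, one is auto-constructed by mirroring the
#' clone mask about the midline (each clone pixel is reflected through its
#' nearest midline point), which places the control at the equivalent D-P
#' position on the opposite side of the tube.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param cloneMask logical matrix, the marked clone ROI.
#' @param controlMask logical matrix, the matched control ROI, or NULL to
#'   mirror the clone about \code{midline}.
#' @param midline a \code{\linkS4class{Midline}} or polyline matrix in
#'   physical units (required when controlMask is NULL).
#' @param pixelSize physical pixel size (um).
#' @param origin physical position of pixel (1,1).
#' @param background per-pixel baseline (AU) subtracted from both
#'   densities before forming the ratio (default 0).
#' @param areaTolerance allowed relative area mismatch (default 0.1).
#' @return a \code{\linkS4class{CloneMeasurement}}; when the inside
#'   density is zero the ratio is reported as an infinite flag.
#' @export
cloneRatio <- function(image, cloneMask, controlMask = NULL,
                       midline = NULL, pixelSize = 1, origin = c(0, 0),
                       background = 0, areaTolerance = 0.1) {
  cloneMask <- as.logical(cloneMask)
  dim(cloneMask) <- dim(image)
  if (!any(cloneMask)) stop("clone mask is empty")
  if (is.null(controlMask)) {
    if (is.null(midline)) {
      stop("supply a control mask or a midline to mirror the clone about")
    }
    controlMask <- mirrorMask(cloneMask, midline, pixelSize, origin)
  }
  controlMask <- as.logical(controlMask)
  dim(controlMask) <- dim(image)
  if (!any(controlMask)) stop("control mask is empty")
  if (any(cloneMask & controlMask)) {
    stop("clone and control masks must be disjoint")
  }
  aIn <- sum(cloneMask) * pixelSize^2
  aOut <- sum(controlMask) * pixelSize^2
  if (abs(aOut - aIn) / aIn > areaTolerance) {
    stop(sprintf(
      "control ROI area (%.1f um^2) differs from clone ROI area ",
      aOut), sprintf("(%.1f um^2) by more than %d%%", aIn,
                     round(100 * areaTolerance)))
  }
  dIn <- sum(image[cloneMask]) / aIn - background / pixelSize^2
  dOut <- sum(image[controlMask]) / aOut - background / pixelSize^2
  inf <- dIn <= 0
  new("CloneMeasurement",
      insideDensity = dIn, outsideDensity = dOut,
      ratioOutIn = if (inf) Inf else dOut / dIn,
      insideArea = aIn, outsideArea = aOut, infiniteFlag = inf)
}

# reflect every mask pixel through its nearest point on the midline
mirrorMask <- function(mask, midline, pixelSize = 1, origin = c(0, 0)) {
  pts <- if (is(midline, "Midline")) midline@points else as.matrix(midline)
  idx <- which(mask, arr.ind = TRUE)
  x <- origin[1] + (idx[, 2] - 1) * pixelSize
  y <- origin[2] + (idx[, 1] - 1) * pixelSize
  pr <- polylineProject(x, y, pts)
  rx <- 2 * pr$foot_x - x
  ry <- 2 * pr$foot_y - y
  cc <- round((rx - origin[1]) / pixelSize) + 1
  rr <- round((ry - origin[2]) / pixelSize) + 1
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  out[cbind(rr[ok], cc[ok])] <- TRUE
  out
}

#' @describeIn cloneRatio Outside/inside density ratio.
#' @param measurement a \code{CloneMeasurement}.
#' @export
ratioOutIn <- function(measurement) measurement@ratioOutIn

#' @describeIn cloneRatio Compact display.
#' @param object a \code{CloneMeasurement}.
#' @export
setMethod("show", "CloneMeasurement", function(object) {
  cat(sprintf(
    "CloneMeasurement: in %.4g, out %.4g AU/um^2 (areas %.0f / %.0f um^2)",
    object@insideDensity, object@outsideDensity, object@insideArea,
    object@outsideArea))
  if (object@infiniteFlag) cat("; ratio infinite (zero inside density)\n")
  else cat(sprintf("; ratio out/in %.4g\n", object@ratioOutIn))
})
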
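#' Arc-length parameterized midline
#'
#' @slot points two-column matrix of (x, y) vertices, ordered distal to
#'   proximal.
#' @slot arc numeric, cumulative arc length (same units as points).
#' @export
setClass("Midline",
  representation(points = "matrix", arc = "numeric"))

#' @describeIn fitMidline Total arc length of a midline.
#' @export
midlineArcLength <- function(midline) {
  midline@arc[length(midline@arc)]
}

#' Fit a midline through a curved epithelium
#'
#' Fits a smoothing-spline polyline, arc-length parameterized, through
#' ordered anchor points or through a connected tube mask; this is the
#' curve along which band-limited intensity profiles are extracted (the
#' digital straightening of a curved epithelium). For a mask, candidate
#' anchors are the binned centroids of the mask pixels along their
#' principal axis (suitable for tubes turning by less than ~half a
#' circle). The spline's flexibility is increased until the maximum
#' deviation from the anchors falls below \code{tol}; a self-intersecting
#' result is an error. Orientation is fixed distal to proximal: the first
#' anchor (or, for masks, the end nearer \code{distalEnd} when given,
#' otherwise the end with the smaller x) comes first.
#'
#' @param x either an n x 2 matrix/data.frame of at least 4 ordered anchor
#'   points, or a logical/0-1 matrix mask.
#' @param tol maximum allowed deviation of the fitted curve from the
#'   anchors (same units as the input; default 0.5).
#' @param pixelSize for mask input, physical size of one pixel (default 1).
#' @param origin for mask input, physical position of pixel (1,1)
#'   (default c(0,0)).
#' @param distalEnd optional length-2 point marking the distal end.
#' @param nOut number of vertices in the resampled polyline.
#' @return a \code{\linkS4class{Midline}}.
#' @examples
#' pts <- cbind(seq(0, 100, 10), 0)
#' ml <- fitMidline(pts)
#' midlineArcLength(ml)  # 100
#' @export
fitMidline <- function(x, tol = 0.5, pixelSize = 1, origin = c(0, 0),
                       distalEnd = NULL, nOut = 400L) {
  if (is.logical(x) || (is.matrix(x) && all(x %in% c(0, 1)) &&
                        nrow(x) > 2 && ncol(x) > 2 && any(x == 0))) {
    idx <- which(x != 0, arr.ind = TRUE)
    if (nrow(idx) < 10) stop("mask too small to fit a midline")
    pts <- cbind(origin[1] + (idx[, 2] - 1) * pixelSize,
                 origin[2] + (idx[, 1] - 1) * pixelSize)
    ctr <- colMeans(pts)
    pcs <- prcomp(pts)
    t1 <- pcs$x[, 1]
    nb <- max(10L, min(40L, floor(nrow(pts) / 50)))
    binCentroids <- function(t1) {
      br <- seq(min(t1), max(t1), length.out = nb + 1L)
      bin <- pmin(findInterval(t1, br, rightmost.closed = TRUE), nb)
      a <- cbind(tapply(pts[, 1], bin, mean),
                 tapply(pts[, 2], bin, mean))
      a[stats::complete.cases(a), , drop = FALSE]
    }
    anchors <- binCentroids(t1)
    # principal-curve style refinement: smooth the anchors with a spline,
    # project the pixels onto the smoothed curve, re-bin along its arc.
    # The smoothing step keeps the iteration stable; it corrects tubes so
    # curved that a single principal axis is oblique to them.
    smoothPoly <- function(a, df = 8, nres = 200L) {
      tp <- c(0, cumsum(sqrt(rowSums(diff(a)^2))))
      df <- min(df, nrow(a) - 1)
      sx <- stats::smooth.spline(tp, a[, 1], df = df)
      sy <- stats::smooth.spline(tp, a[, 2], df = df)
      tt <- seq(0, max(tp), length.out = nres)
      cbind(stats::predict(sx, tt)$y, stats::predict(sy, tt)$y)
    }
    for (it in 1:4) {
      proj <- polylineProject(pts[, 1], pts[, 2],
                              smoothPoly(anchors))$arc
      anchors <- binCentroids(proj)
    }
    if (!is.null(distalEnd)) {
      dFirst <- sum((anchors[1, ] - distalEnd)^2)
      dLast <- sum((anchors[nrow(anchors), ] - distalEnd)^2)
      if (dLast < dFirst) anchors <- anchors[nrow(anchors):1, ]
    } else if (anchors[1, 1] > anchors[nrow(anchors), 1]) {
      anchors <- anchors[nrow(anchors):1, ]
    }
  } else {
    anchors <- as.matrix(x)
    if (nrow(anchors) < 4) stop("need at least 4 anchor points")
  }
  n <- nrow(anchors)
  tpar <- c(0, cumsum(sqrt(rowSums(diff(anchors)^2))))
  fitOne <- function(df) {
    sx <- stats::smooth.spline(tpar, anchors[, 1], df = df)
    sy <- stats::smooth.spline(tpar, anchors[, 2], df = df)
    list(sx = sx, sy = sy)
  }
  dfTry <- unique(pmin(c(4, 6, 8, 12, 16, 24, n), n))
  dfTry <- dfTry[dfTry >= 4]
  fit <- NULL
  for (df in dfTry) {
    f <- tryCatch(fitOne(df), error = function(e) NULL)
    if (is.null(f)) next
    dev <- sqrt((stats::predict(f$sx, tpar)$y - anchors[, 1])^2 +
                (stats::predict(f$sy, tpar)$y - anchors[, 2])^2)
    fit <- f
    if (max(dev) <= tol) break
  }
  if (is.null(fit)) stop("midline spline fit failed")
  tt <- seq(0, max(tpar), length.out = nOut)
  poly <- cbind(stats::predict(fit$sx, tt)$y, stats::predict(fit$sy, tt)$y)
  if (polylineSelfIntersects(poly)) {
    stop("fitted midline self-intersects")
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
  new("Midline", points = poly, arc = arc)
}

# interpolate a midline at arc positions s: returns points and unit normals
midlineAt <- function(midline, s) {
  arc <- midline@arc
  pts <- midline@points
  xi <- stats::approx(arc, pts[, 1], xout = s, rule = 2)$y
  yi <- stats::approx(arc, pts[, 2], xout = s, rule = 2)$y
  eps <- max(arc) / 1000
  xd <- stats::approx(arc, pts[, 1], xout = pmin(s + eps, max(arc)),
                      rule = 2)$y -
    stats::approx(arc, pts[, 1], xout = pmax(s - eps, 0), rule = 2)$y
  yd <- stats::approx(arc, pts[, 2], xout = pmin(s + eps, max(arc)),
                      rule = 2)$y -
    stats::approx(arc, pts[, 2], xout = pmax(s - eps, 0), rule = 2)$y
  nrm <- sqrt(xd^2 + yd^2)
  nrm[nrm == 0] <- 1
  list(x = xi, y = yi, nx = -yd / nrm, ny = xd / nrm)
}

#' Extract a band-limited intensity profile along a midline
#'
#' At each arc-length sample the image is resampled (bilinear) along the
#' perpendicular to the midline over a band of \code{bandWidthPx} pixels,
#' and the band is collapsed by the chosen projection (max by default,
#' matching maximum-intensity-projection profiling; mean available). This
#' resampling is the digital straightening of the curved epithelium. Band
#' samples falling outside the image are clipped and counted in the
#' profile's \code{clipped} metadata, with a warning.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param midline a \code{\linkS4class{Midline}} in physical units, or an
#'   n x 2 matrix of ordered polyline vertices (a straight axis works).
#' @param bandWidthPx band width in pixels (default 40).
#' @param projection "max" or "mean".
#' @param pixelSize physical size of one pixel.
#' @param origin physical position of the centre of pixel (1,1).
#' @param channel label stored in the profile metadata.
#' @return an \code{\linkS4class{IntensityProfile}}; positions are um from
#'   the distal tip (the midline start).
#' @export
extractProfile <- function(image, midline, bandWidthPx = 40,
                           projection = c("max", "mean"), pixelSize = 1,
                           origin = c(0, 0), channel = "ligand") {
  projection <- match.arg(projection)
  if (!is(midline, "Midline")) {
    pts <- as.matrix(midline)
    arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    midline <- new("Midline", points = pts, arc = arc)
  }
  L <- midlineArcLength(midline)
  s <- seq(0, L, by = pixelSize)
  mp <- midlineAt(midline, s)
  off <- (seq_len(bandWidthPx) - (bandWidthPx + 1) / 2) * pixelSize
  vals <- numeric(length(s))
  nClipped <- 0L
  for (k in seq_along(s)) {
    bx <- mp$x[k] + off * mp$nx[k]
    by <- mp$y[k] + off * mp$ny[k]
    col <- (bx - origin[1]) / pixelSize + 1
    row <- (by - origin[2]) / pixelSize + 1
    v <- bilinear(image, col, row)
    nClipped <- nClipped + sum(is.na(v))
    v <- v[!is.na(v)]
    vals[k] <- if (!length(v)) NA_real_ else
      if (projection == "max") max(v) else mean(v)
  }
  keep <- !is.na(vals)
  if (nClipped > 0) {
    warning(nClipped, " band samples fell outside the image and were ",
            "clipped")
  }
  new("IntensityProfile", positions = s[keep], values = vals[keep],
      bandWidth = as.numeric(bandWidthPx), projection = projection,
      channel = channel, clipped = as.integer(nClipped))
}

#' Band profile of a synthetic scene channel
#'
#' Convenience wrapper: extracts the band profile of one channel of a
#' rendered scene along the scene's own midline (or along the straight
#' D-P axis for a zero-curvature scene when \code{useMidline = FALSE}).
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @param channel channel name.
#' @param bandWidthPx band width in pixels.
#' @param projection "max" or "mean".
#' @param useMidline follow the curved midline (TRUE) or the straight
#'   chord from distal tip to proximal end (FALSE).
#' @return an \code{\linkS4class{IntensityProfile}}.
#' @export
sceneProfile <- function(scene, channel = "ligand", bandWidthPx = 40,
                         projection = "max", useMidline = TRUE) {
  geo <- scene@geometry
  ml <- if (useMidline) geo@midline else {
    rbind(geo@midline[1, ], geo@midline[nrow(geo@midline), ])
  }
  extractProfile(getChannel(scene, channel), ml,
                 bandWidthPx = bandWidthPx, projection = projection,
                 pixelSize = scene@pixelSize, origin = scene@origin,
                 channel = channel)
}

#' @describeIn extractProfile Positions (um) of a profile.
#' @param profile an \code{IntensityProfile}.
#' @export
profilePositions <- function(profile) profile@positions

#' @describeIn extractProfile Values (AU) of a profile.
#' @export
profileValues <- function(profile) profile@values

#' Build an intensity profile from raw vectors
#'
#' @param positions strictly increasing positions (um).
#' @param values intensities (AU).
#' @param channel metadata label.
#' @return an \code{\linkS4class{IntensityProfile}}.
#' @export
intensityProfile <- function(positions, values, channel = "manual") {
  new("IntensityProfile", positions = as.numeric(positions),
      values = as.numeric(values), bandWidth = 1, projection = "max",
      channel = channel, clipped = 0L)
}

#' @describeIn extractProfile Compact display.
#' @param object an \code{IntensityProfile}.
#' @export
setMethod("show", "IntensityProfile", function(object) {
  cat("IntensityProfile (", object@channel, "): ",
      length(object@positions), " samples over ",
      signif(max(object@positions), 4), " um; ", object@projection,
      " projection over ", object@bandWidth, " px band\n", sep = "")
})
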
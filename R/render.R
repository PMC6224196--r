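SCENE_CHANNELS <- c("ligand", "receptor", "clone", "eif", "endosome",
                    "grasp")

# physical (x, y) um -> fractional pixel (col, row), 1-based
physToPix <- function(x, y, origin, pixelSize) {
  list(col = (x - origin[1]) / pixelSize + 1,
       row = (y - origin[2]) / pixelSize + 1)
}

# additive rendering of Gaussian spots into a matrix
renderSpots <- function(img, col, row, amp, sigmaPx) {
  if (length(col) == 0L) return(img)
  w <- max(2L, ceiling(4 * sigmaPx))
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_along(col)) {
    c0 <- col[k]; r0 <- row[k]
    if (c0 + w < 1 || c0 - w > nc || r0 + w < 1 || r0 - w > nr) next
    cs <- max(1L, floor(c0 - w)):min(nc, ceiling(c0 + w))
    rs <- max(1L, floor(r0 - w)):min(nr, ceiling(r0 + w))
    gx <- exp(-((cs - c0)^2) / (2 * sigmaPx^2))
    gy <- exp(-((rs - r0)^2) / (2 * sigmaPx^2))
    img[rs, cs] <- img[rs, cs] + amp[k] * outer(gy, gx)
  }
  img
}

# arc position s and signed perpendicular distance to the midline for a
# constant-curvature tube (sign: left of the distal->proximal tangent,
# i.e. toward the centre of curvature for a curved tube)
tubeCoords <- function(x, y, config) {
  kappa <- config@curvature
  if (kappa == 0) {
    return(list(s = x, dist = y))
  }
  r0 <- 1 / kappa
  wx <- x
  wy <- y - r0
  phi <- atan2(wx, -wy)
  list(s = phi / kappa, dist = r0 - sqrt(wx^2 + wy^2))
}

# which side of the midline a point lies on: +1 left of the local tangent
# (distal -> proximal travel), -1 right
midlineSide <- function(x, y, geometry) {
  ml <- geometry@midline
  side <- numeric(length(x))
  for (k in seq_along(x)) {
    d2 <- (ml[, 1] - x[k])^2 + (ml[, 2] - y[k])^2
    i <- which.min(d2)
    j <- min(i, nrow(ml) - 1L)
    tx <- ml[j + 1L, 1] - ml[j, 1]; ty <- ml[j + 1L, 2] - ml[j, 2]
    cr <- tx * (y[k] - ml[j, 2]) - ty * (x[k] - ml[j, 1])
    side[k] <- ifelse(cr >= 0, 1, -1)
  }
  side
}

#' Render a synthetic multi-channel scene
#'
#' Generates a microscopy-like image stack with known ground truth. Ligand
#' puncta are placed per cell with expected count
#' \code{density_scale * Cmax * exp(-d_i/lambda) * uptake_factor(i)} and
#' rendered as Gaussian spots whose amplitude scales with the local expected
#' ligand level (puncta are clusters of sub-resolution molecules, so their
#' brightness tracks local concentration). Each ligand punctum carries a
#' receptor partner with probability \code{receptor_binding_prob}, a
#' surface flag with probability \code{surface_prob} (the EIF channel
#' contains only surface-flagged puncta) and, if internalized, an endosome
#' flag with probability \code{endosome_prob}. Marked clones thin punctum
#' placement by their \code{uptake_factor} inside the clone region (the
#' half of the clone cells' footprint on one side of the midline, as mosaic
#' patches are). Images are PSF-blurred, then Poisson shot noise is applied
#' to the expected counts and Gaussian read noise is added last; this order
#' is fixed. Identical config + seed gives a bit-identical stack.
#'
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @param perCellIntensity optional numeric vector of per-cell expected
#'   ligand levels (AU) overriding the configured exponential gradient;
#'   used by \code{\link{exportScene}} to render simulated steady states.
#' @param perCellCytonemes optional integer vector of per-cell cytoneme
#'   counts passed to \code{\link{placeCytonemes}}.
#' @return a \code{\linkS4class{SyntheticScene}}.
#' @examples
#' sc <- renderScene(sceneConfig(nCells = 8, seed = 1))
#' dim(sceneStack(sc))
#' @export
renderScene <- function(config, perCellIntensity = NULL,
                        perCellCytonemes = NULL) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  set.seed(config@seed)
  geo <- buildGeometry(config)
  px <- config@pixelSize
  D <- config@cellDiameter
  margin <- D / 2 + 4
  xr <- range(geo@midline[, 1]) + c(-margin, margin)
  yr <- range(geo@midline[, 2]) + c(-margin, margin)
  nc <- ceiling(diff(xr) / px)
  nr <- ceiling(diff(yr) / px)
  if (nr < 1L || nc < 1L) stop("zero-size image")
  if (nr * nc > 3e7) stop("image too large: ", nr, " x ", nc)
  origin <- c(xr[1], yr[1])

  g <- config@gradient
  pc <- config@puncta
  n <- config@nCells
  expInt <- if (is.null(perCellIntensity)) {
    g$Cmax * exp(-geo@distances / g$lambda)
  } else rep_len(perCellIntensity, n)

  uptake <- rep(1, n)
  cloneRows <- list()
  for (cl in config@clones) {
    cells <- cl$cells
    uptake[cells] <- uptake[cells] * cl$uptake_factor
    cloneRows[[length(cloneRows) + 1L]] <- data.frame(
      first_cell = min(cells), last_cell = max(cells),
      uptake_factor = cl$uptake_factor,
      expected_ratio_out_in = ifelse(cl$uptake_factor > 0,
                                     1 / cl$uptake_factor, Inf))
  }

  expCount <- pc$density_scale * expInt
  if (sum(expCount) > 1e6) {
    stop("density_scale would produce > 1e6 puncta; rejected")
  }

  # puncta: uniform in each cell's disc; clone-region thinning by uptake
  cloneCells <- integer(0)
  for (cl in config@clones) cloneCells <- union(cloneCells, cl$cells)
  punctaList <- list()
  for (i in seq_len(n)) {
    nPts <- stats::rpois(1, expCount[i])
    if (nPts == 0L) next
    rr <- (D / 2) * sqrt(runif(nPts))
    th <- runif(nPts, 0, 2 * pi)
    x <- geo@cellCenters[i, 1] + rr * cos(th)
    y <- geo@cellCenters[i, 2] + rr * sin(th)
    keep <- rep(TRUE, nPts)
    if (i %in% cloneCells && uptake[i] != 1) {
      inClone <- midlineSide(x, y, geo) > 0
      keep[inClone] <- runif(sum(inClone)) < uptake[i]
    }
    if (!any(keep)) next
    x <- x[keep]; y <- y[keep]
    m <- length(x)
    punctaList[[length(punctaList) + 1L]] <- data.frame(
      x_um = x, y_um = y, cell = i,
      intensity = pc$intensity * expInt[i] / g$Cmax,
      receptor = runif(m) < pc$receptor_binding_prob,
      surface = runif(m) < pc$surface_prob)
  }
  puncta <- if (length(punctaList)) do.call(rbind, punctaList) else
    data.frame(x_um = numeric(), y_um = numeric(), cell = integer(),
               intensity = numeric(), receptor = logical(),
               surface = logical())
  puncta$endosome <- !puncta$surface &
    runif(nrow(puncta)) < pc$endosome_prob

  cyt <- placeCytonemes(geo, config, perCellCytonemes)

  stack <- array(0, dim = c(nr, nc, length(SCENE_CHANNELS)),
                 dimnames = list(NULL, NULL, SCENE_CHANNELS))
  sigPx <- pc$spot_sigma / px
  if (nrow(puncta)) {
    p <- physToPix(puncta$x_um, puncta$y_um, origin, px)
    stack[, , "ligand"] <- renderSpots(stack[, , "ligand"], p$col, p$row,
                                       puncta$intensity, sigPx)
    sel <- puncta$surface
    stack[, , "eif"] <- renderSpots(stack[, , "eif"], p$col[sel],
                                    p$row[sel], puncta$intensity[sel],
                                    sigPx)
    sel <- puncta$endosome
    stack[, , "endosome"] <- renderSpots(stack[, , "endosome"], p$col[sel],
                                         p$row[sel],
                                         puncta$intensity[sel], sigPx)
    sel <- puncta$receptor
    if (any(sel)) {
      jx <- puncta$x_um[sel] + stats::rnorm(sum(sel), 0, pc$jitter)
      jy <- puncta$y_um[sel] + stats::rnorm(sum(sel), 0, pc$jitter)
      pj <- physToPix(jx, jy, origin, px)
      stack[, , "receptor"] <- renderSpots(stack[, , "receptor"], pj$col,
                                           pj$row,
                                           puncta$intensity[sel], sigPx)
    }
  }
  if (nrow(cyt$grasp)) {
    pg <- physToPix(cyt$grasp$x_um, cyt$grasp$y_um, origin, px)
    stack[, , "grasp"] <- renderSpots(stack[, , "grasp"], pg$col, pg$row,
                                      rep(40, nrow(cyt$grasp)), sigPx)
  }
  # continuous sub-resolution component: cell surfaces are densely
  # covered with dim nanopuncta, so the ligand channel carries a smooth
  # per-cell film proportional to the local expected ligand level
  # (thinned by uptake_factor inside clone regions), under the bright
  # discrete puncta
  if (pc$film_intensity > 0) {
    xs <- origin[1] + (seq_len(nc) - 1) * px
    ys <- origin[2] + (seq_len(nr) - 1) * px
    gx <- matrix(xs, nr, nc, byrow = TRUE)
    gy <- matrix(ys, nr, nc)
    tc <- tubeCoords(gx, gy, config)
    L <- n * D
    inTube <- abs(tc$dist) <= D / 2 & tc$s >= 0 & tc$s <= L
    # film level: the exact exponential in source distance for configured
    # gradients; per-cell interpolation when an explicit per-cell
    # intensity (e.g. a simulated steady state) is rendered
    sClamp <- pmin(pmax(tc$s, 0), L)
    if (is.null(perCellIntensity)) {
      dOfS <- if (config@curvature == 0) sClamp else
        (2 / config@curvature) * sin(config@curvature * sClamp / 2)
      dOfS <- sqrt(dOfS^2 + config@zOffset^2)
      lvl <- exp(-dOfS / g$lambda) * pc$film_intensity
    } else {
      lvl <- stats::approx(geo@cellArc, expInt, xout = sClamp,
                           rule = 2)$y * pc$film_intensity / g$Cmax
    }
    film <- matrix(0, nr, nc)
    film[inTube] <- lvl[inTube]
    # clone regions thin the film by their uptake factor
    for (cl in config@clones) {
      if (cl$uptake_factor == 1) next
      cellLo <- (min(cl$cells) - 1) * D
      cellHi <- max(cl$cells) * D
      inClone <- inTube & tc$s >= cellLo & tc$s <= cellHi & tc$dist > 0
      film[inClone] <- film[inClone] * cl$uptake_factor
    }
    stack[, , "ligand"] <- stack[, , "ligand"] + film
  }
  # clone label: filled clone region at a flat level
  for (cl in config@clones) {
    msk <- tubeSectorMask(config, cl$cells, origin, px, nr, nc)
    ch <- stack[, , "clone"]
    ch[msk] <- 50
    stack[, , "clone"] <- ch
  }
  stack[, , "ligand"] <- stack[, , "ligand"] + g$background

  psfPx <- config@noise$psf_sigma / px
  for (k in seq_along(SCENE_CHANNELS)) {
    if (psfPx > 0) {
      stack[, , k] <- EBImage::gblur(stack[, , k], sigma = psfPx)
    }
    if (isTRUE(config@noise$poisson)) {
      v <- pmax(stack[, , k], 0)
      stack[, , k] <- matrix(stats::rpois(length(v), v), nr, nc)
    }
    if (config@noise$gaussian_sd > 0) {
      stack[, , k] <- stack[, , k] +
        stats::rnorm(nr * nc, 0, config@noise$gaussian_sd)
    }
  }

  truth <- new("GroundTruth",
    cells = data.frame(
      cell = seq_len(n),
      x_um = geo@cellCenters[, 1], y_um = geo@cellCenters[, 2],
      d_um = geo@distances, uptake_factor = uptake,
      expected_count = expCount * ifelse(uptake < 1,
                                         (1 + uptake) / 2, 1),
      expected_intensity = expInt),
    trueLambda = if (is.null(perCellIntensity)) g$lambda else NA_real_,
    trueSlope = if (is.null(perCellIntensity))
      g$Cmax / (2 * g$lambda * log(2)) else NA_real_,
    puncta = puncta,
    traces = cyt$traces, traceStats = cyt$stats, grasp = cyt$grasp,
    clones = if (length(cloneRows)) do.call(rbind, cloneRows) else
      data.frame(first_cell = integer(), last_cell = integer(),
                 uptake_factor = numeric(),
                 expected_ratio_out_in = numeric()))

  new("SyntheticScene", stack = stack, channelNames = SCENE_CHANNELS,
      pixelSize = px, origin = origin, config = config, geometry = geo,
      truth = truth)
}

# logical mask (nr x nc) of a half-tube sector: arc positions
# [sLo + margin, sHi - margin], perpendicular offset on the given side
# between margin and tubeRadius - margin. margin keeps measurement ROIs
# clear of PSF bleed across region boundaries.
tubeSectorMask <- function(config, cells, origin, px, nr, nc,
                           side = 1, margin = 0) {
  xs <- origin[1] + (seq_len(nc) - 1) * px
  ys <- origin[2] + (seq_len(nr) - 1) * px
  gx <- matrix(xs, nr, nc, byrow = TRUE)
  gy <- matrix(ys, nr, nc)
  tc <- tubeCoords(gx, gy, config)
  D <- config@cellDiameter
  sLo <- (min(cells) - 1) * D
  sHi <- max(cells) * D
  off <- side * tc$dist
  tc$s >= sLo + margin & tc$s <= sHi - margin &
    off >= margin & off <= D / 2 - margin
}

#' Access the image stack and channels of a scene
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @return \code{sceneStack}: the numeric 3-d array (rows, cols, channels).
#' @export
sceneStack <- function(scene) scene@stack

#' @rdname sceneStack
#' @param channel channel name, one of
#'   \code{ligand, receptor, clone, eif, endosome, grasp}.
#' @return \code{getChannel}: one channel as a matrix.
#' @export
getChannel <- function(scene, channel) {
  channel <- match.arg(channel, scene@channelNames)
  scene@stack[, , channel]
}

#' @rdname sceneStack
#' @return \code{groundTruth}: the \code{\linkS4class{GroundTruth}}.
#' @export
groundTruth <- function(scene) scene@truth

#' @rdname sceneStack
#' @return \code{sceneGeometry}: the \code{\linkS4class{SceneGeometry}}.
#' @export
sceneGeometry <- function(scene) scene@geometry

#' @rdname sceneStack
#' @param which clone number (index into the config's clone list).
#' @param marginUm inset (um) from the region boundaries, keeping the
#'   measurement ROI clear of PSF bleed across edges (default 1).
#' @return \code{sceneCloneMask} / \code{sceneControlMask}: logical matrix
#'   masks of the clone measurement region and of its mirror-image control
#'   region at the equivalent D-P position on the other side of the
#'   midline (equal areas by construction).
#' @export
sceneCloneMask <- function(scene, which = 1L, marginUm = 1) {
  cl <- scene@config@clones[[which]]
  d <- dim(scene@stack)
  tubeSectorMask(scene@config, cl$cells, scene@origin, scene@pixelSize,
                 d[1], d[2], side = 1, margin = marginUm)
}

#' @rdname sceneStack
#' @export
sceneControlMask <- function(scene, which = 1L, marginUm = 1) {
  cl <- scene@config@clones[[which]]
  d <- dim(scene@stack)
  tubeSectorMask(scene@config, cl$cells, scene@origin, scene@pixelSize,
                 d[1], d[2], side = -1, margin = marginUm)
}

#' @describeIn sceneStack Compact display of a scene.
#' @param object a \code{SyntheticScene}.
#' @export
setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@stack)
  cat("SyntheticScene:", d[1], "x", d[2], "px x", d[3], "channels (",
      paste(object@channelNames, collapse = ", "), ")\n")
  cat("  pixel", object@pixelSize, "um;", nrow(object@truth@puncta),
      "ligand puncta;", nrow(object@truth@traceStats), "cytoneme traces\n")
})

#' Write a scene to disk
#'
#' Writes a multi-page 32-bit TIFF (one page per channel, in the order of
#' \code{channelNames}; pixel values are scaled into [0,1] by the recorded
#' \code{scale} factor), the ground truth as JSON, and the trace / GRASP
#' tables as CSV.
#'
#' @param scene a \code{SyntheticScene}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stk <- scene@stack
  sc <- max(stk, 1e-9)
  pages <- lapply(seq_along(scene@channelNames),
                  function(k) pmax(stk[, , k], 0) / sc)
  tifPath <- file.path(dir, "scene.tif")
  tiff::writeTIFF(pages, tifPath, bits.per.sample = 32L)
  tr <- scene@truth
  meta <- list(
    channels = scene@channelNames, scale = sc,
    pixel_size_um = scene@pixelSize, origin_um = scene@origin,
    true_lambda_um = tr@trueLambda, true_slope = tr@trueSlope,
    cells = tr@cells, clones = tr@clones,
    seed = scene@config@seed)
  jsonPath <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  trPath <- file.path(dir, "traces.csv")
  utils::write.csv(tr@traces, trPath, row.names = FALSE)
  gpPath <- file.path(dir, "grasp.csv")
  utils::write.csv(tr@grasp, gpPath, row.names = FALSE)
  invisible(c(tiff = tifPath, truth = jsonPath, traces = trPath,
              grasp = gpPath))
}
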
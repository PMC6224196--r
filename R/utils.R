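# Internal numerical helpers.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

hill <- function(C, theta, h) {
  # increasing Hill response; hill(theta, theta, h) == 0.5
  Ch <- pmax(C, 0)^h
  Ch / (Ch + theta^h)
}

#' Wrap angles into (-180, 180]
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped into the interval (-180, 180].
#' @export
wrapAngle <- function(deg) {
  w <- deg %% 360
  w[w > 180] <- w[w > 180] - 360
  # map -180 -> 180 so the interval is right-closed
  w[w == -180] <- 180
  w
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), mean mu (radians),
# concentration kappa. kappa == 0 degenerates to the circular uniform.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) {
    return(runif(n, -pi, pi) + mu)
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1L
    }
  }
  out
}

# bilinear interpolation of matrix img (rows = y, cols = x) at fractional
# pixel coordinates (x, y), 1-based; NA outside the image.
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmin(floor(xs), nc - 1L); y0 <- pmin(floor(ys), nr - 1L)
  dx <- xs - x0; dy <- ys - y0
  v00 <- img[cbind(y0, x0)]
  v01 <- img[cbind(y0, x0 + 1L)]
  v10 <- img[cbind(y0 + 1L, x0)]
  v11 <- img[cbind(y0 + 1L, x0 + 1L)]
  out[ok] <- v00 * (1 - dx) * (1 - dy) + v01 * dx * (1 - dy) +
    v10 * (1 - dx) * dy + v11 * dx * dy
  out
}

# minimum distance from points (px, py) to the segment (x1,y1)-(x2,y2)
pointSegDist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  if (len2 < .Machine$double.eps) {
    return(sqrt((px - x1)^2 + (py - y1)^2))
  }
  t <- clamp(((px - x1) * vx + (py - y1) * vy) / len2, 0, 1)
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

# minimum distance from each point to a polyline (matrix of vertices x,y)
pointPolylineDist <- function(px, py, poly) {
  nseg <- nrow(poly) - 1L
  d <- rep(Inf, length(px))
  for (s in seq_len(nseg)) {
    ds <- pointSegDist(px, py, poly[s, 1], poly[s, 2],
                       poly[s + 1L, 1], poly[s + 1L, 2])
    d <- pmin(d, ds)
  }
  d
}

# continuous projection of points onto a polyline: minimum distance and
# the arc-length position of the foot point
polylineProject <- function(px, py, poly) {
  nseg <- nrow(poly) - 1L
  segArc <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
  best <- rep(Inf, length(px))
  arc <- numeric(length(px))
  fx <- numeric(length(px))
  fy <- numeric(length(px))
  for (s in seq_len(nseg)) {
    x1 <- poly[s, 1]; y1 <- poly[s, 2]
    vx <- poly[s + 1L, 1] - x1; vy <- poly[s + 1L, 2] - y1
    len2 <- vx^2 + vy^2
    if (len2 < .Machine$double.eps) next
    t <- clamp(((px - x1) * vx + (py - y1) * vy) / len2, 0, 1)
    qx <- x1 + t * vx; qy <- y1 + t * vy
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    upd <- d < best
    best[upd] <- d[upd]
    arc[upd] <- segArc[s] + t[upd] * sqrt(len2)
    fx[upd] <- qx[upd]
    fy[upd] <- qy[upd]
  }
  list(dist = best, arc = arc, foot_x = fx, foot_y = fy)
}

# do segments p1-p2 and p3-p4 properly intersect?
segIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# TRUE when a polyline (n x 2 matrix) self-intersects
polylineSelfIntersects <- function(poly) {
  n <- nrow(poly) - 1L
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (segIntersect(poly[i, ], poly[i + 1L, ],
                       poly[j, ], poly[j + 1L, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# stable hash of a config list: recursively sort keys, serialize to
# canonical JSON, md5 the bytes. Stable under key reordering.
configHash <- function(x) {
  sortRec <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)) && any(nzchar(names(v)))) {
        v <- v[order(names(v))]
      }
      lapply(v, sortRec)
    } else v
  }
  js <- jsonlite::toJSON(sortRec(x), auto_unbox = TRUE, digits = 15)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

logMsg <- function(level, module, ...) {
  message(sprintf("[%s] %s: %s", level, module, paste0(...)))
}
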
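#' Detect fluorescent puncta in a channel
#'
#' Scale-space blob detection: the channel is filtered with a
#' Laplacian-of-Gaussian kernel matched to the expected punctum size, and
#' local maxima of the (sign-inverted) response above a threshold are
#' reported as puncta with sub-pixel centroid refinement over a 3x3
#' neighbourhood.
#'
#' @param channel numeric matrix (rows = y, cols = x).
#' @param logSigmaUm LoG scale in um (default 0.3, a diffraction-limited
#'   spot).
#' @param threshold absolute threshold on the LoG response; when NULL,
#'   5 robust standard deviations (MAD) above the median response.
#' @param pixelSize um per pixel.
#' @param origin physical position of pixel (1,1).
#' @return data.frame with columns \code{x_um}, \code{y_um}, \code{peak}
#'   (response peak), \code{channel}.
#' @export
detectPuncta <- function(channel, logSigmaUm = 0.3, threshold = NULL,
                         pixelSize = 1, origin = c(0, 0)) {
  sig <- logSigmaUm / pixelSize
  hw <- max(2L, ceiling(3 * sig))
  ax <- seq(-hw, hw)
  g <- exp(-ax^2 / (2 * sig^2))
  G <- outer(g, g)
  G <- G / sum(G)
  r2 <- outer(ax^2, ax^2, "+")
  LoG <- G * (r2 - 2 * sig^2) / sig^4
  LoG <- LoG - mean(LoG)
  resp <- -EBImage::filter2(channel, LoG)
  if (is.null(threshold)) {
    threshold <- stats::median(resp) + 5 * stats::mad(resp)
  }
  nr <- nrow(resp); nc <- ncol(resp)
  inner <- resp[2:(nr - 1), 2:(nc - 1)]
  isMax <- inner > threshold
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      isMax <- isMax &
        inner >= resp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    }
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      peak = numeric(), channel = character()))
  }
  rr <- idx[, 1] + 1L
  cc <- idx[, 2] + 1L
  # centroid refinement on the response in a 3x3 window
  sx <- sy <- sw <- numeric(length(rr))
  for (k in seq_along(rr)) {
    w <- resp[(rr[k] - 1):(rr[k] + 1), (cc[k] - 1):(cc[k] + 1)]
    w <- pmax(w, 0)
    tot <- sum(w)
    if (tot <= 0) { sx[k] <- cc[k]; sy[k] <- rr[k]; next }
    sx[k] <- cc[k] + sum(w %*% c(-1, 0, 1)) / tot
    sy[k] <- rr[k] + sum(c(-1, 0, 1) %*% w) / tot
  }
  data.frame(
    x_um = origin[1] + (sx - 1) * pixelSize,
    y_um = origin[2] + (sy - 1) * pixelSize,
    peak = resp[cbind(rr, cc)],
    channel = rep("detected", length(rr)))
}

#' Colocalization fraction between two punctum sets
#'
#' Fraction of puncta in A whose nearest punctum in B lies within
#' \code{maxDistUm} (nearest-centroid criterion, suitable for
#' diffraction-limited spots). The fraction is in [0,1] and is monotone
#' non-decreasing in \code{maxDistUm}.
#'
#' @param punctaA,punctaB data.frames with columns \code{x_um},
#'   \code{y_um} (as from \code{\link{detectPuncta}} or ground truth).
#' @param maxDistUm matching radius in um (default 0.5, > 0).
#' @return the fraction; \code{NA} with a warning when A is empty
#'   (undefined).
#' @export
colocalizationFraction <- function(punctaA, punctaB, maxDistUm = 0.5) {
  if (maxDistUm <= 0) stop("maxDistUm must be > 0")
  nA <- nrow(punctaA)
  if (is.null(nA) || nA == 0) {
    warning("empty punctum set A: colocalization fraction undefined")
    return(NA_real_)
  }
  if (is.null(nrow(punctaB)) || nrow(punctaB) == 0) return(0)
  hits <- 0L
  bx <- punctaB$x_um; by <- punctaB$y_um
  for (k in seq_len(nA)) {
    d2 <- (bx - punctaA$x_um[k])^2 + (by - punctaA$y_um[k])^2
    if (min(d2) <= maxDistUm^2) hits <- hits + 1L
  }
  hits / nA
}
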
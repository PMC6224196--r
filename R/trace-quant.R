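#' Measure a cytoneme trace
#'
#' Length is the polyline arc length; orientation is the angle (degrees,
#' in (-180, 180]) between the trace's net displacement (last vertex minus
#' first) and the direction from its origin toward the source, so 0 means
#' pointing straight at the source. Net displacement, rather than
#' per-segment tangents, matches visual scoring of source-oriented
#' cytonemes.
#'
#' @param polyline n x 2 matrix/data.frame of vertices (um), first vertex
#'   at the originating cell.
#' @param sourcePos length-2 source position (um).
#' @return list with \code{length_um}, \code{angle_deg} and
#'   \code{degenerate} (TRUE for a zero-length trace, whose angle is NA).
#' @examples
#' measureTrace(rbind(c(0, 0), c(20, 0)), sourcePos = c(30, 0))
#' @export
measureTrace <- function(polyline, sourcePos) {
  p <- as.matrix(polyline)
  if (nrow(p) < 2) stop("a trace needs at least 2 vertices")
  segs <- diff(p)
  len <- sum(sqrt(rowSums(segs^2)))
  disp <- p[nrow(p), ] - p[1, ]
  toSrc <- sourcePos - p[1, ]
  if (len < .Machine$double.eps) {
    return(list(length_um = 0, angle_deg = NA_real_, degenerate = TRUE))
  }
  ang <- atan2(disp[2], disp[1]) - atan2(toSrc[2], toSrc[1])
  list(length_um = len, angle_deg = wrapAngle(ang * 180 / pi),
       degenerate = FALSE)
}

#' Measure every trace in a vertex table
#'
#' @param traces data.frame with columns \code{trace_id},
#'   \code{cell_index}, \code{vertex}, \code{x_um}, \code{y_um} (schema of
#'   the generator's trace CSV).
#' @param sourcePos length-2 source position (um).
#' @return data.frame with one row per trace: trace_id, cell_index,
#'   length_um, angle_deg, length_bin.
#' @export
measureTraces <- function(traces, sourcePos) {
  ids <- unique(traces$trace_id)
  out <- lapply(ids, function(id) {
    tr <- traces[traces$trace_id == id, ]
    tr <- tr[order(tr$vertex), ]
    m <- measureTrace(cbind(tr$x_um, tr$y_um), sourcePos)
    data.frame(trace_id = id, cell_index = tr$cell_index[1],
               length_um = m$length_um, angle_deg = m$angle_deg)
  })
  res <- do.call(rbind, out)
  res$length_bin <- lengthBin(res$length_um)
  res
}

#' Classify cytoneme lengths into short/mid/long bins
#'
#' Bins are short (< 15 um), mid (15-30 um, closed on both ends) and long
#' (> 30 um); a length of exactly 15 or exactly 30 um falls in the mid
#' bin.
#'
#' @param lengths numeric vector of lengths (um, >= 0).
#' @return \code{lengthBin}: factor with levels short/mid/long;
#'   \code{classifyBins}: named counts per bin.
#' @export
lengthBin <- function(lengths) {
  if (any(lengths < 0)) stop("negative cytoneme length")
  b <- cut(lengths, breaks = c(-Inf, 15, 30, Inf), right = FALSE,
           labels = c("short", "mid", "long"))
  # right = FALSE puts exactly 30 in 'long'; the mid bin is closed at 30
  b[lengths == 30] <- "mid"
  b
}

#' @rdname lengthBin
#' @export
classifyBins <- function(lengths) {
  b <- lengthBin(lengths)
  c(short = sum(b == "short"), mid = sum(b == "mid"),
    long = sum(b == "long"))
}

#' Rose histogram of cytoneme orientations
#'
#' Bins orientation angles into \code{binDeg}-degree sectors partitioning
#' (-180, 180], with one sector centred on 0 (the direction toward the
#' source), optionally stratified by length class. The counts sum to the
#' number of traces.
#'
#' @param measured data.frame from \code{\link{measureTraces}} (columns
#'   \code{angle_deg} and, for stratification, \code{length_bin}), or a
#'   numeric vector of angles.
#' @param binDeg sector width in degrees; must divide 360 (default 20).
#' @param stratify split counts by length class (default TRUE when the
#'   input has a \code{length_bin} column).
#' @return data.frame with columns \code{bin_lo}, \code{bin_hi},
#'   \code{bin_mid} (degrees) and \code{count} (plus per-class columns
#'   when stratified).
#' @export
roseHistogram <- function(measured, binDeg = 20, stratify = NULL) {
  if (360 %% binDeg != 0) stop("binDeg must divide 360")
  if (is.numeric(measured)) {
    measured <- data.frame(angle_deg = measured)
  }
  if (is.null(stratify)) stratify <- "length_bin" %in% names(measured)
  ang <- wrapAngle(measured$angle_deg)
  # shift so that sector edges fall at +-binDeg/2: one sector contains 0
  shifted <- ang + binDeg / 2
  shifted[shifted > 180] <- shifted[shifted > 180] - 360
  edges <- seq(-180, 180, by = binDeg)
  bin <- cut(shifted, breaks = edges, include.lowest = TRUE)
  out <- data.frame(
    bin_lo = edges[-length(edges)] - binDeg / 2,
    bin_hi = edges[-1] - binDeg / 2)
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out$count <- as.integer(table(bin))
  if (stratify && "length_bin" %in% names(measured)) {
    for (cls in c("short", "mid", "long")) {
      sel <- measured$length_bin == cls
      out[[cls]] <- as.integer(table(bin[sel]))
    }
  }
  out
}

#' Assign a cell index to an ASP region
#'
#' Cells 1-3 from the distal tip form the tip zone, cells 4-7 the
#' mid-region, and cells beyond the 7th the proximal stalk.
#'
#' @param cellIndex integer vector, 1-based from the distal tip.
#' @param axisCells number of cells along the D-P axis (default 12).
#' @return character vector: "tip", "mid" or "stalk".
#' @examples
#' assignRegion(c(2, 5, 9))
#' @export
assignRegion <- function(cellIndex, axisCells = 12L) {
  if (any(cellIndex < 1L) || any(cellIndex > axisCells)) {
    stop("cell index out of range 1..", axisCells)
  }
  ifelse(cellIndex <= 3, "tip", ifelse(cellIndex <= 7, "mid", "stalk"))
}

#' Count GRASP contact puncta per trace
#'
#' Assigns each GRASP punctum to the nearest trace within
#' \code{maxDistUm} (distance from the punctum to the trace polyline);
#' puncta farther than that from every trace are unassigned. Counts are
#' non-decreasing in \code{maxDistUm}.
#'
#' @param traces vertex table (trace_id, vertex, x_um, y_um).
#' @param graspPuncta data.frame with \code{x_um}, \code{y_um}.
#' @param maxDistUm assignment radius (um, > 0; default 1).
#' @return data.frame with \code{trace_id} and \code{contact_count}.
#' @export
countContacts <- function(traces, graspPuncta, maxDistUm = 1) {
  if (maxDistUm <= 0) stop("maxDistUm must be > 0")
  ids <- unique(traces$trace_id)
  counts <- stats::setNames(integer(length(ids)), ids)
  np <- if (is.null(nrow(graspPuncta))) 0L else nrow(graspPuncta)
  if (np > 0L) {
    polys <- lapply(ids, function(id) {
      tr <- traces[traces$trace_id == id, ]
      tr <- tr[order(tr$vertex), ]
      cbind(tr$x_um, tr$y_um)
    })
    dmat <- vapply(polys, function(p) {
      pointPolylineDist(graspPuncta$x_um, graspPuncta$y_um, p)
    }, numeric(np))
    dmat <- matrix(dmat, nrow = np)
    for (k in seq_len(np)) {
      j <- which.min(dmat[k, ])
      if (dmat[k, j] <= maxDistUm) {
        counts[j] <- counts[j] + 1L
      }
    }
  }
  data.frame(trace_id = ids, contact_count = as.integer(counts))
}

#' Compare punctum loads of contacting vs non-contacting cytonemes
#'
#' Two-group comparison (two-tailed Welch t-test) of per-trace punctum
#' loads between source-contacting and non-contacting cytonemes.
#'
#' @param contact logical vector, TRUE for source-contacting traces.
#' @param punctaLoads numeric vector of per-trace punctum counts/loads.
#' @return list with group means, \code{t} and \code{p}.
#' @export
compareContacting <- function(contact, punctaLoads) {
  stopifnot(length(contact) == length(punctaLoads))
  a <- punctaLoads[contact]
  b <- punctaLoads[!contact]
  tt <- welchT(a, b)
  list(mean_contacting = mean(a), mean_noncontacting = mean(b),
       n_contacting = length(a), n_noncontacting = length(b),
       t = tt$t, p = tt$p)
}
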
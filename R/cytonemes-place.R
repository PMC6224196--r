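#' Place ground-truth cytoneme traces
#'
#' Emits cytoneme polylines rooted at cell centres. Lengths are drawn from
#' the configured short/mid/long mixture (uniform within each length class:
#' 2-15, 15-30 and 30-60 um); directions are von Mises distributed around
#' the direction from the cell centre toward the source, with angular
#' concentration \code{kappa} (kappa = 0 gives uniform orientations, as for
#' the randomly oriented short cytonemes of the proximal stalk). A trace
#' contacts the source when its reach (arc length) is at least the cell's
#' distance to the source; GRASP contact puncta are then placed along the
#' distal portion of the trace, with a mean of \code{grasp_rate} puncta per
#' contacting trace (always at least one).
#'
#' Uses the current RNG stream; \code{\link{renderScene}} seeds it from the
#' scene seed.
#'
#' @param geometry a \code{\linkS4class{SceneGeometry}}.
#' @param config a \code{\linkS4class{SceneConfig}}; the \code{cytonemes}
#'   block is used.
#' @param perCellCounts optional integer vector overriding
#'   \code{config@cytonemes$per_cell_counts} (default 4 per cell).
#' @return list with \code{traces} (vertex table: trace_id, cell_index,
#'   vertex, x_um, y_um), \code{stats} (per-trace length_um, angle_deg,
#'   length_bin, contact, contact_count) and \code{grasp} (contact punctum
#'   table: x_um, y_um, trace_id).
#' @export
placeCytonemes <- function(geometry, config, perCellCounts = NULL) {
  cy <- config@cytonemes
  n <- nrow(geometry@cellCenters)
  counts <- perCellCounts
  if (is.null(counts)) counts <- cy$per_cell_counts
  if (is.null(counts)) counts <- rep(4L, n)
  counts <- as.integer(rep_len(counts, n))
  if (any(counts < 0L)) stop("per-cell cytoneme counts must be >= 0")
  mix <- cy$length_mixture / sum(cy$length_mixture)
  binEdges <- list(short = c(2, 15), mid = c(15, 30), long = c(30, 60))
  tot <- sum(counts)
  verts <- vector("list", tot)
  stats <- vector("list", tot)
  grasp <- list()
  id <- 0L
  for (i in seq_len(n)) {
    if (counts[i] == 0L) next
    ctr <- geometry@cellCenters[i, ]
    toSrc <- geometry@sourcePos - ctr
    theta0 <- atan2(toSrc[2], toSrc[1])
    di <- geometry@distances[i]
    for (k in seq_len(counts[i])) {
      id <- id + 1L
      cls <- sample(names(mix), 1L, prob = mix)
      e <- binEdges[[cls]]
      len <- runif(1, e[1], e[2])
      dev <- rvonmises(1, 0, cy$kappa)
      ang <- theta0 + dev
      tip <- ctr + len * c(cos(ang), sin(ang))
      verts[[id]] <- data.frame(
        trace_id = id, cell_index = i, vertex = 1:2,
        x_um = c(ctr[1], tip[1]), y_um = c(ctr[2], tip[2]))
      contact <- len >= di
      nGrasp <- if (contact) 1L + stats::rpois(1, max(cy$grasp_rate - 1, 0))
                else 0L
      if (nGrasp > 0L) {
        tfrac <- runif(nGrasp, 0.8, 1)
        grasp[[length(grasp) + 1L]] <- data.frame(
          x_um = ctr[1] + tfrac * (tip[1] - ctr[1]) +
            stats::rnorm(nGrasp, 0, 0.1),
          y_um = ctr[2] + tfrac * (tip[2] - ctr[2]) +
            stats::rnorm(nGrasp, 0, 0.1),
          trace_id = id)
      }
      stats[[id]] <- data.frame(
        trace_id = id, cell_index = i, length_um = len,
        angle_deg = wrapAngle(dev * 180 / pi), length_bin = cls,
        contact = contact, contact_count = nGrasp)
    }
  }
  emptyGrasp <- data.frame(x_um = numeric(), y_um = numeric(),
                           trace_id = integer())
  list(
    traces = if (id > 0L) do.call(rbind, verts) else
      data.frame(trace_id = integer(), cell_index = integer(),
                 vertex = integer(), x_um = numeric(), y_um = numeric()),
    stats = if (id > 0L) do.call(rbind, stats) else
      data.frame(trace_id = integer(), cell_index = integer(),
                 length_um = numeric(), angle_deg = numeric(),
                 length_bin = character(), contact = logical(),
                 contact_count = integer()),
    grasp = if (length(grasp)) do.call(rbind, grasp) else emptyGrasp)
}
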
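#' Build the scene geometry
#'
#' Lays out the tubular epithelium as a midline of constant curvature,
#' places one cell centre per cell at arc-length spacing
#' \code{cellDiameter}, puts the ligand source at the distal end of the
#' midline (arc position 0), and computes each cell's straight-line (chord)
#' distance to the source. Cell 1 is the distal tip; distances are strictly
#' increasing with the cell index whenever the total turned angle
#' \code{curvature * axis length} is below pi (half circle), which is the
#' documented operating bound; a midline turning by 2*pi or more would
#' self-intersect and is rejected.
#'
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @return a \code{\linkS4class{SceneGeometry}}.
#' @examples
#' geo <- buildGeometry(sceneConfig(nCells = 12, curvature = 0))
#' diff(distancesToSource(geo))  # == cellDiameter
#' @export
buildGeometry <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  n <- config@nCells
  D <- config@cellDiameter
  kappa <- config@curvature
  L <- n * D
  if (kappa * L >= 2 * pi) {
    stop("curvature ", kappa, " /um makes the ", L,
         " um midline self-intersect (turned angle >= 2*pi)")
  }
  s <- seq(0, L, by = min(D / 20, 0.5))
  if (s[length(s)] < L) s <- c(s, L)
  if (kappa == 0) {
    midline <- cbind(x = s, y = rep(0, length(s)))
    pos <- function(sv) cbind(sv, 0)
  } else {
    pos <- function(sv) cbind(sin(kappa * sv) / kappa,
                              (1 - cos(kappa * sv)) / kappa)
    midline <- pos(s)
    colnames(midline) <- c("x", "y")
  }
  cellArc <- (seq_len(n) - 0.5) * D
  centers <- pos(cellArc)
  colnames(centers) <- c("x", "y")
  src <- midline[1, ]
  chord <- sqrt((centers[, 1] - src[1])^2 + (centers[, 2] - src[2])^2)
  d <- sqrt(chord^2 + config@zOffset^2)
  new("SceneGeometry",
      midline = midline, arcPositions = s, cellCenters = centers,
      cellArc = cellArc, sourcePos = as.numeric(src), distances = d,
      cellDiameter = D)
}

#' @rdname buildGeometry
#' @param geometry a \code{SceneGeometry}.
#' @return \code{distancesToSource}: numeric vector of per-cell
#'   straight-line distances (um), ordered distal to proximal.
#' @export
distancesToSource <- function(geometry) geometry@distances

#' @rdname buildGeometry
#' @return \code{axisLength}: total arc length of the D-P axis (um).
#' @export
axisLength <- function(geometry) {
  length(geometry@distances) * geometry@cellDiameter
}

#' @describeIn buildGeometry Compact display.
#' @param object a \code{SceneGeometry}.
#' @export
setMethod("show", "SceneGeometry", function(object) {
  cat("SceneGeometry:", nrow(object@cellCenters), "cells,",
      axisLength(object), "um axis; source at (",
      paste(signif(object@sourcePos, 4), collapse = ", "), ") um\n")
})
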
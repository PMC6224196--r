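#' Construct a scene configuration
#'
#' Builds a validated \code{\linkS4class{SceneConfig}} with defaults chosen
#' to emulate a late third-instar ASP: a 12-cell D-P axis of 10 um cells
#' (~120 um, matching the observed ~100-120 um gradient range), 0.2 um
#' pixels, and an exponential ligand gradient.
#'
#' @param nCells cells along the D-P axis.
#' @param cellDiameter cell diameter (um).
#' @param pixelSize um per pixel.
#' @param curvature midline curvature (1/um); 0 is a straight tube.
#' @param zOffset extra source distance (um) applied in quadrature, for
#'   upper-layer scenes.
#' @param gradient list(Cmax, lambda, background) in AU / um / AU.
#' @param puncta punctum statistics; see \code{\linkS4class{SceneConfig}}.
#' @param clones list of clones, each list(cells, uptake_factor,
#'   label_channel).
#' @param cytonemes cytoneme emission parameters.
#' @param noise imaging-noise model.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   scene.
#' @return a \code{SceneConfig}.
#' @examples
#' cfg <- sceneConfig(nCells = 12, seed = 1)
#' @export
sceneConfig <- function(nCells = 12L,
                        cellDiameter = 10,
                        pixelSize = 0.2,
                        curvature = 0,
                        zOffset = 0,
                        gradient = list(),
                        puncta = list(),
                        clones = list(),
                        cytonemes = list(),
                        noise = list(),
                        seed = 1L) {
  gradient <- utils::modifyList(
    list(Cmax = 100, lambda = 30, background = 2), gradient)
  puncta <- utils::modifyList(
    list(density_scale = 0.15, receptor_binding_prob = 1.0,
         endosome_prob = 0.76, surface_prob = 0.15,
         spot_sigma = 0.3, intensity = 25, film_intensity = 60,
         jitter = 0.05), puncta)
  cytonemes <- utils::modifyList(
    list(per_cell_counts = NULL,
         length_mixture = c(short = 0.5, mid = 0.3, long = 0.2),
         kappa = 4, grasp_rate = 3), cytonemes)
  noise <- utils::modifyList(
    list(gaussian_sd = 1, poisson = TRUE, psf_sigma = 0.3), noise)
  new("SceneConfig",
      nCells = as.integer(nCells), cellDiameter = cellDiameter,
      pixelSize = pixelSize, curvature = curvature, zOffset = zOffset,
      gradient = gradient, puncta = puncta, clones = clones,
      cytonemes = cytonemes, noise = noise, seed = as.integer(seed))
}

#' Read a scene configuration from YAML
#'
#' Schema-validated: unknown top-level keys are rejected with the failing
#' key path.
#'
#' @param path YAML file.
#' @return a \code{SceneConfig}.
#' @export
readSceneConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("nCells", "cellDiameter", "pixelSize", "curvature", "zOffset",
             "gradient", "puncta", "clones", "cytonemes", "noise", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown scene config key(s): ", paste(bad, collapse = ", "))
  }
  for (blk in c("gradient", "puncta", "cytonemes", "noise")) {
    if (!is.null(y[[blk]]) && !is.list(y[[blk]])) {
      stop("scene config key '", blk, "' must be a mapping")
    }
  }
  if (!is.null(y$cytonemes$length_mixture)) {
    y$cytonemes$length_mixture <- unlist(y$cytonemes$length_mixture)
  }
  do.call(sceneConfig, y)
}

#' Write a scene configuration to YAML
#'
#' @param config a \code{SceneConfig}.
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
writeSceneConfig <- function(config, path) {
  y <- list(
    nCells = config@nCells, cellDiameter = config@cellDiameter,
    pixelSize = config@pixelSize, curvature = config@curvature,
    zOffset = config@zOffset, gradient = config@gradient,
    puncta = config@puncta, clones = config@clones,
    cytonemes = list(
      per_cell_counts = config@cytonemes$per_cell_counts,
      length_mixture = as.list(config@cytonemes$length_mixture),
      kappa = config@cytonemes$kappa,
      grasp_rate = config@cytonemes$grasp_rate),
    noise = config@noise, seed = config@seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @describeIn sceneConfig Compact display of a scene configuration.
#' @param object a \code{SceneConfig}.
#' @export
setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@nCells, "cells x", object@cellDiameter,
      "um, pixel", object@pixelSize, "um\n")
  cat("  gradient: Cmax", object@gradient$Cmax, "AU, lambda",
      object@gradient$lambda, "um, background",
      object@gradient$background, "AU\n")
  cat("  curvature:", object@curvature, "/um;", length(object@clones),
      "clone(s); seed", object@seed, "\n")
})
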
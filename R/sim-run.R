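#' Run the feedback simulator to steady state
#'
#' Iterates \code{\link{simStep}} synchronously from the all-off initial
#' state (no ligand, transcription factors at zero, cytoneme and receptor
#' baselines) until the maximum per-field change over one step falls
#' below \code{tol}, a period-2 cycle is detected, or \code{maxSteps} is
#' exhausted. In deterministic mode all stochastic elements are replaced
#' by their expectations; in stochastic mode contacts are
#' Poisson-sampled (seed the RNG via \code{seed}) and a step budget of
#' \code{maxSteps} is run without a convergence criterion (the last
#' state is reported).
#'
#' @param params a \code{\linkS4class{SimParams}}.
#' @param seed optional integer seed for stochastic mode.
#' @param keepTrajectory record the per-step C profile (list of numeric
#'   vectors); off by default.
#' @param stochSteps step budget for stochastic mode (default 2000).
#' @return a \code{\linkS4class{SimResult}}; \code{states} has one row
#'   per cell with the steady values of C, sty, P, K, Y, B, n and the
#'   per-class expected cytoneme counts n_short, n_mid, n_long.
#' @examples
#' \donttest{
#' res <- runToSteadyState(referenceParams())
#' steadyStates(res)[, c("cell", "C", "P", "K")]
#' }
#' @export
runToSteadyState <- function(params, seed = NULL, keepTrajectory = FALSE,
                             stochSteps = 2000L) {
  validObject(params)
  checkCloneConflicts(params)
  stoch <- params@mode == "stochastic"
  if (stoch && !is.null(seed)) set.seed(seed)
  state <- applyPins(initState(params), params)
  for (cl in params@clones) {
    if (cl$type == "btl_LOF") state$B[cl$cells] <- 0
  }
  pool <- if (params@finitePool) 0 else Inf
  fields <- c("C", "sty", "P", "K", "Y", "B", "n")
  prev1 <- prev2 <- NULL
  ledger <- list(produced = 0, delivered = 0, decayed = 0,
                 undelivered = 0)
  traj <- list()
  converged <- FALSE
  oscillating <- FALSE
  nSteps <- if (stoch) as.integer(stochSteps) else params@maxSteps
  step <- 0L
  while (step < nSteps) {
    step <- step + 1L
    out <- simStep(state, params, pool)
    pool <- out$pool
    ledger$produced <- ledger$produced + out$produced
    ledger$delivered <- ledger$delivered + out$delivered
    ledger$decayed <- ledger$decayed + out$decayed
    newState <- out$state
    if (keepTrajectory) traj[[length(traj) + 1L]] <- newState$C
    if (!stoch) {
      delta <- max(abs(as.matrix(newState[, fields]) -
                         as.matrix(state[, fields])))
      if (delta < params@tol) {
        converged <- TRUE
        state <- newState
        break
      }
      if (!is.null(prev2)) {
        d2 <- max(abs(as.matrix(newState[, fields]) -
                        as.matrix(prev2[, fields])))
        if (d2 < params@tol && delta >= params@tol) {
          oscillating <- TRUE
          state <- newState
          warning("period-2 oscillation detected; stopping")
          break
        }
      }
      prev2 <- prev1
      prev1 <- state
    }
    state <- newState
  }
  if (stoch) converged <- TRUE  # budgeted run; last state reported
  ledger$undelivered <- if (params@finitePool) pool else 0
  lf <- params@longFrac
  # long source-oriented cytonemes require PntP1 above an activation
  # threshold p_min: stalk cells emit only short random cytonemes
  fLong <- clamp(lf$f0 + lf$f1 * pmax(state$P - lf$p_min, 0) /
                   (1 - lf$p_min), 0, 1)
  state$n_long <- state$n * fLong
  state$n_short <- state$n * (1 - fLong) * lf$short_share
  state$n_mid <- state$n * (1 - fLong) * (1 - lf$short_share)
  new("SimResult", states = state, converged = converged,
      oscillating = oscillating, steps = step, params = params,
      ledger = ledger, trajectory = traj)
}

checkCloneConflicts <- function(params) {
  pinField <- c(cut_GOF = "K", pnt_GOF = "P", pnt_LOF = "P",
                btl_LOF = "B", btl_GOF = "B")
  seen <- list()
  for (cl in params@clones) {
    f <- pinField[cl$type]
    if (is.na(f)) next
    key <- unname(f)
    prior <- seen[[key]]
    if (!is.null(prior) && length(intersect(prior, cl$cells))) {
      stop("conflicting clone overrides pin '", key,
           "' twice on cell(s) ",
           paste(intersect(prior, cl$cells), collapse = ","))
    }
    seen[[key]] <- union(prior, cl$cells)
  }
  invisible(TRUE)
}

#' @describeIn runToSteadyState Steady-state per-cell table.
#' @param result a \code{SimResult}.
#' @export
steadyStates <- function(result) result@states

#' @describeIn runToSteadyState Convergence flag.
#' @export
converged <- function(result) result@converged

#' @describeIn runToSteadyState The ligand profile of a run as an
#'   \code{\linkS4class{IntensityProfile}} (positions = cell distances).
#' @export
resultProfile <- function(result) {
  st <- result@states
  intensityProfile(st$d_um, st$C, channel = "simulated-C")
}

#' @describeIn runToSteadyState Compact display.
#' @param object a \code{SimResult}.
#' @export
setMethod("show", "SimResult", function(object) {
  cat("SimResult:", nrow(object@states), "cells;",
      if (object@converged) "converged" else "NOT converged", "in",
      object@steps, "steps",
      if (object@oscillating) "(period-2 cycle)" else "", "\n")
  cat(sprintf("  C range %.4g .. %.4g AU; delivered %.4g AU total\n",
              max(object@states$C), min(object@states$C),
              object@ledger$delivered))
})

#' Extract gene expression domains under the half-maximum ON rule
#'
#' A gene is ON in cell i when its steady level is at least half its
#' maximum across cells. Reports, per gene, the most distal and most
#' proximal ON cells and whether the domain is contiguous; an all-off
#' gene yields an empty (NA) domain.
#'
#' @param result a converged \code{\linkS4class{SimResult}}.
#' @return data.frame with columns \code{gene} (sty, pntP1, cut, yan),
#'   \code{first_on_cell}, \code{last_on_cell}, \code{n_on},
#'   \code{contiguous}, \code{max_level}.
#' @export
expressionDomains <- function(result) {
  if (!result@converged) stop("expressionDomains needs a converged run")
  st <- result@states
  genes <- c(sty = "sty", pntP1 = "P", cut = "K", yan = "Y")
  rows <- lapply(names(genes), function(gn) {
    lv <- st[[genes[[gn]]]]
    mx <- max(lv)
    if (mx <= 0) {
      return(data.frame(gene = gn, first_on_cell = NA_integer_,
                        last_on_cell = NA_integer_, n_on = 0L,
                        contiguous = NA, max_level = mx))
    }
    on <- which(lv >= 0.5 * mx)
    data.frame(gene = gn, first_on_cell = min(on),
               last_on_cell = max(on), n_on = length(on),
               contiguous = all(diff(on) == 1L), max_level = mx)
  })
  do.call(rbind, rows)
}

#' Apply a mosaic-clone or source perturbation
#'
#' Adds a perturbation to the parameter set, mirroring the mosaic
#' experiments: \code{cut_GOF} (Cut pinned to 1), \code{pnt_GOF} (PntP1
#' pinned to 1), \code{pnt_LOF} (PntP1 pinned to 0), \code{btl_LOF}
#' (receptor pinned to 0), \code{btl_GOF} (receptor pinned to its cap),
#' \code{ectopic_source} (a second source of the reference strength at
#' \code{position} um), and \code{source_overexpression} (all source
#' strengths scaled by \code{factor}). Pinned quantities are excluded
#' from the feedback updates for those cells. Pinning the same quantity
#' twice on one cell is an error.
#'
#' @param params a \code{\linkS4class{SimParams}}.
#' @param cells integer cell indices (ignored for the two source
#'   perturbations).
#' @param override one of the override names above.
#' @param position um, for \code{ectopic_source}.
#' @param factor multiplier, for \code{source_overexpression}.
#' @return the modified \code{SimParams}.
#' @export
applyClone <- function(params, cells = integer(),
                       override = c("cut_GOF", "pnt_GOF", "pnt_LOF",
                                    "btl_LOF", "btl_GOF",
                                    "ectopic_source",
                                    "source_overexpression"),
                       position = NULL, factor = 5) {
  override <- match.arg(override)
  if (override == "ectopic_source") {
    if (is.null(position)) stop("ectopic_source needs a position (um)")
    params@sources <- rbind(params@sources,
                            data.frame(pos_um = position,
                                       strength = params@sources$strength[1]))
    return(params)
  }
  if (override == "source_overexpression") {
    params@sources$strength <- params@sources$strength * factor
    return(params)
  }
  if (!length(cells)) stop("clone overrides need target cells")
  if (any(cells < 1L) || any(cells > params@nCells)) {
    stop("clone cells outside 1..", params@nCells)
  }
  params@clones <- c(params@clones,
                     list(list(type = override,
                               cells = as.integer(cells))))
  checkCloneConflicts(params)
  params
}

#' Gradient-scaling experiment across axis lengths
#'
#' Runs the simulator to steady state for each axis length in
#' \code{nList}, fits the exponential trend to each steady ligand
#' profile (no background term: simulated profiles carry no imaging
#' baseline) and reports the Cmax-to-half-max slope, reproducing the
#' negative correlation between D-P axis length and gradient slope.
#' The different axis lengths emulate tissues at different developmental
#' stages, whose cytoneme reach grows with the tissue: by default the
#' contact length scale rho is scaled proportionally to the axis length
#' (relative to the base parameter set), which is what lets the gradient
#' stretch with the tissue; with \code{scaleReach = FALSE} reach stays
#' absolute and the profiles are length-invariant truncations.
#'
#' @param params base \code{\linkS4class{SimParams}} (the reference).
#' @param nList integer vector of axis lengths in cells (each >= 4).
#' @param scaleReach scale cytoneme reach with axis length (default
#'   TRUE).
#' @return data.frame with \code{n_cells}, \code{axis_length_um},
#'   \code{lambda_um}, \code{slope}, \code{converged}.
#' @export
scalingExperiment <- function(params,
                              nList = c(6L, 8L, 10L, 12L, 14L),
                              scaleReach = TRUE) {
  if (any(nList < 4L)) stop("each axis needs at least 4 cells")
  rows <- lapply(nList, function(N) {
    p <- params
    p@nCells <- as.integer(N)
    if (scaleReach) {
      p@contact$rho_um <- params@contact$rho_um * N / params@nCells
    }
    res <- runToSteadyState(p)
    if (!res@converged) {
      warning("run with ", N, " cells did not converge")
    }
    fit <- fitExponential(resultProfile(res), fitBackground = FALSE)
    data.frame(n_cells = N,
               axis_length_um = N * p@cellDiameter,
               lambda_um = fit@lambda, slope = fit@slope,
               converged = res@converged)
  })
  do.call(rbind, rows)
}

#' Export a simulation result as a renderable scene
#'
#' Closes the loop simulate -> render -> re-quantify: maps the steady
#' ligand profile to per-cell expected punctum intensities and the steady
#' cytoneme emission rates to per-cell trace counts, on a scene whose
#' geometry matches the simulated axis.
#'
#' @param result a converged \code{\linkS4class{SimResult}}.
#' @param sceneDefaults named list of \code{\link{sceneConfig}} arguments
#'   to override (e.g. seed, noise).
#' @return list with \code{config} (a \code{SceneConfig}),
#'   \code{perCellIntensity} and \code{perCellCytonemes}; pass to
#'   \code{\link{renderScene}} or use \code{\link{renderSimScene}}.
#' @export
exportScene <- function(result, sceneDefaults = list()) {
  if (!result@converged) stop("exportScene needs a converged run")
  st <- result@states
  p <- result@params
  cloneCfg <- lapply(p@clones, function(cl) {
    list(cells = cl$cells, uptake_factor = 1, label_channel = "clone")
  })
  args <- utils::modifyList(
    list(nCells = p@nCells, cellDiameter = p@cellDiameter,
         clones = cloneCfg), sceneDefaults)
  cfg <- do.call(sceneConfig, args)
  list(config = cfg,
       perCellIntensity = st$C / max(st$C, 1e-12) * cfg@gradient$Cmax,
       perCellCytonemes = as.integer(round(st$n)))
}

#' @rdname exportScene
#' @param ... passed to \code{exportScene}.
#' @return \code{renderSimScene}: the rendered
#'   \code{\linkS4class{SyntheticScene}}.
#' @export
renderSimScene <- function(result, ...) {
  ex <- exportScene(result, ...)
  renderScene(ex$config, perCellIntensity = ex$perCellIntensity,
              perCellCytonemes = ex$perCellCytonemes)
}
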
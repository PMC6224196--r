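#' Construct simulator parameters
#'
#' Builds a validated \code{\linkS4class{SimParams}} for the
#' cytoneme-feedback gradient simulator. The defaults are the calibrated
#' reference configuration (also shipped as
#' \code{inst/extdata/reference.yaml}): a 14-cell D-P axis (the two most
#' proximal cells representing the transverse connective), a single
#' non-depleting source at the distal end, geometric-tail contact
#' probability, and feedback gains/thresholds fixed once so that the
#' deterministic 14-cell steady state reproduces the observed expression
#' domains (sty cells 1-3, pntP1 1-7, cut 7-14, yan 11-14) and the
#' 12-cell run a 7-cell distal zone of long source-oriented cytonemes.
#'
#' @param nCells cells along the D-P axis (default 14).
#' @param cellDiameter um; cell i sits at (i - 1/2) * cellDiameter.
#' @param sources data.frame(pos_um, strength); default one source of
#'   strength 10 at 0.
#' @param contact list(p0, rho_um, deliver_prob): contact probability
#'   p0 * exp(-d/rho_um) and per-contact delivery probability.
#' @param uptake AU per delivered contact per unit receptor per unit
#'   source strength.
#' @param deltaC per-step ligand turnover.
#' @param thresholds named ligand thresholds (sty > pnt > cut > yan).
#' @param hillN named per-gene Hill steepness.
#' @param inhibition mutual-inhibition weights (w_KP, w_YP, w_PK, w_PY).
#' @param cytoneme cytoneme-number feedback (n_base, n_floor, n_cap,
#'   alpha, beta, gamma).
#' @param receptor receptor-level feedback (B_base, B_floor, B_cap,
#'   alpha, beta, gamma).
#' @param longFrac list(f0, f1, p_min, short_share): long-class fraction
#'   clamp01(f0 + f1 * max(P - p_min, 0)/(1 - p_min)); the non-long
#'   remainder splits short_share:1-short_share between short and mid.
#' @param relax gene-level relaxation rate per step.
#' @param tol convergence tolerance (max-norm).
#' @param maxSteps step budget.
#' @param mode "deterministic" or "stochastic".
#' @param finitePool deplete the source pool (default FALSE:
#'   non-depleting source).
#' @param poolProduction AU produced per step when finitePool.
#' @return a \code{SimParams}.
#' @export
simParams <- function(nCells = 14L,
                      cellDiameter = 10,
                      sources = data.frame(pos_um = 0, strength = 10),
                      contact = list(),
                      uptake = 0.05,
                      deltaC = 0.2,
                      thresholds = c(),
                      hillN = c(),
                      inhibition = c(),
                      cytoneme = list(),
                      receptor = list(),
                      longFrac = list(),
                      relax = 0.2,
                      tol = 1e-8,
                      maxSteps = 100000L,
                      mode = "deterministic",
                      finitePool = FALSE,
                      poolProduction = 50) {
  contact <- utils::modifyList(
    list(p0 = 1, rho_um = 40, deliver_prob = 0.9,
         events_per_contact = 500), contact)
  thDef <- c(sty = 5, pnt = 0.92, cut = 0.8464, yan = 0.055)
  thresholds <- c(thresholds, thDef[setdiff(names(thDef),
                                            names(thresholds))])
  hDef <- c(sty = 4, pnt = 0.5, cut = 1, yan = 3)
  hillN <- c(hillN, hDef[setdiff(names(hDef), names(hillN))])
  wDef <- c(w_KP = 0.1, w_YP = 0.15, w_PK = 0.05, w_PY = 0.3)
  inhibition <- c(inhibition, wDef[setdiff(names(wDef),
                                           names(inhibition))])
  cytoneme <- utils::modifyList(
    list(n_base = 2, n_floor = 1, n_cap = 12,
         alpha = 2.5, beta = 2.5, gamma = 2), cytoneme)
  receptor <- utils::modifyList(
    list(B_base = 0.6, B_floor = 0.1, B_cap = 2,
         alpha = 1.2, beta = 0.4, gamma = 0.3), receptor)
  longFrac <- utils::modifyList(
    list(f0 = 0.05, f1 = 0.65, p_min = 0.35, short_share = 0.7),
    longFrac)
  new("SimParams",
      nCells = as.integer(nCells), cellDiameter = cellDiameter,
      sources = sources, contact = contact, uptake = uptake,
      deltaC = deltaC,
      thresholds = thresholds[c("sty", "pnt", "cut", "yan")],
      hillN = hillN[c("sty", "pnt", "cut", "yan")],
      inhibition = inhibition[c("w_KP", "w_YP", "w_PK", "w_PY")],
      cytoneme = cytoneme, receptor = receptor, longFrac = longFrac,
      relax = relax, tol = tol, maxSteps = as.integer(maxSteps),
      mode = mode, finitePool = finitePool,
      poolProduction = poolProduction, clones = list())
}

#' Read simulator parameters from YAML
#'
#' Schema-validated; unknown keys are rejected with the failing key path.
#' The shipped reference configuration is at
#' \code{system.file("extdata", "reference.yaml", package = "cytograd")}.
#'
#' @param path YAML file.
#' @return a \code{\linkS4class{SimParams}}.
#' @export
readSimParams <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("nCells", "cellDiameter", "sources", "contact", "uptake",
             "deltaC", "thresholds", "hillN", "inhibition", "cytoneme",
             "receptor", "longFrac", "relax", "tol", "maxSteps", "mode",
             "finitePool", "poolProduction")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown simulator config key(s): ", paste(bad, collapse = ", "))
  }
  for (blk in c("thresholds", "hillN", "inhibition")) {
    if (!is.null(y[[blk]])) y[[blk]] <- unlist(y[[blk]])
  }
  if (!is.null(y$sources)) {
    y$sources <- do.call(rbind, lapply(y$sources, as.data.frame))
  }
  do.call(simParams, y)
}

#' Write simulator parameters to YAML
#'
#' @param params a \code{SimParams}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSimParams <- function(params, path) {
  y <- list(
    nCells = params@nCells, cellDiameter = params@cellDiameter,
    sources = lapply(seq_len(nrow(params@sources)), function(i) {
      as.list(params@sources[i, ])
    }),
    contact = params@contact, uptake = params@uptake,
    deltaC = params@deltaC, thresholds = as.list(params@thresholds),
    hillN = as.list(params@hillN),
    inhibition = as.list(params@inhibition),
    cytoneme = params@cytoneme, receptor = params@receptor,
    longFrac = params@longFrac, relax = params@relax, tol = params@tol,
    maxSteps = params@maxSteps, mode = params@mode,
    finitePool = params@finitePool,
    poolProduction = params@poolProduction)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The shipped reference configuration
#'
#' @param nCells optionally override the axis length (e.g. 12 for the
#'   cytoneme-zone analysis); all other parameters are the frozen
#'   reference values.
#' @param ... further overrides passed to slots by name is not supported;
#'   modify the returned object instead.
#' @return a \code{\linkS4class{SimParams}}.
#' @export
referenceParams <- function(nCells = 14L, ...) {
  p <- readSimParams(system.file("extdata", "reference.yaml",
                                 package = "cytograd"))
  if (nCells != p@nCells) {
    p@nCells <- as.integer(nCells)
  }
  validObject(p)
  p
}

#' @describeIn simParams Compact display.
#' @param object a \code{SimParams}.
#' @export
setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nCells, "cells x", object@cellDiameter,
      "um;", object@mode, "mode\n")
  cat("  thresholds:",
      paste(names(object@thresholds),
            signif(object@thresholds, 3), sep = "=", collapse = " "),
      "\n")
  cat("  contact rho", object@contact$rho_um, "um; uptake",
      object@uptake, "; deltaC", object@deltaC, ";",
      length(object@clones), "clone override(s)\n")
})
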
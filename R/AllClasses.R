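#' @import methods
NULL

#' Scene configuration for the synthetic microscopy generator
#'
#' A \code{SceneConfig} fully parameterizes one synthetic multi-channel
#' ASP-like scene: the geometry of the curved tubular epithelium, the
#' exponential ligand gradient, punctum statistics, marked clones with
#' altered uptake, cytoneme emission, and the imaging-noise model.
#'
#' @slot nCells integer, number of cells along the distal-proximal (D-P)
#'   axis (>= 2).
#' @slot cellDiameter numeric, cell diameter in micrometres.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot curvature numeric, midline curvature in 1/um (0 = straight tube).
#' @slot zOffset numeric, extra source distance in um added to every cell;
#'   used to represent an upper epithelial layer that sits further from the
#'   source than the layer containing the distal tip.
#' @slot gradient list with elements \code{Cmax} (AU), \code{lambda}
#'   (um decay length) and \code{background} (AU).
#' @slot puncta list with elements \code{density_scale} (puncta per cell per
#'   AU), \code{receptor_binding_prob}, \code{endosome_prob},
#'   \code{surface_prob}, \code{spot_sigma} (um), \code{intensity} (AU peak
#'   amplitude at Cmax) and \code{jitter} (um, channel registration jitter).
#' @slot clones list of clones, each a list with \code{cells} (integer
#'   range), \code{uptake_factor} (>= 0) and \code{label_channel}.
#' @slot cytonemes list with \code{per_cell_counts} (integer vector or NULL),
#'   \code{length_mixture} (named proportions short/mid/long), \code{kappa}
#'   (angular concentration toward the source) and \code{grasp_rate}
#'   (mean GRASP puncta per source-contacting trace).
#' @slot noise list with \code{gaussian_sd} (AU), \code{poisson} (flag) and
#'   \code{psf_sigma} (um).
#' @slot seed integer random seed.
#' @export
setClass("SceneConfig",
  representation(
    nCells = "integer",
    cellDiameter = "numeric",
    pixelSize = "numeric",
    curvature = "numeric",
    zOffset = "numeric",
    gradient = "list",
    puncta = "list",
    clones = "list",
    cytonemes = "list",
    noise = "list",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@nCells < 2L) msg <- c(msg, "nCells must be >= 2")
  if (object@cellDiameter <= 0) msg <- c(msg, "cellDiameter must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@curvature < 0) msg <- c(msg, "curvature must be >= 0")
  g <- object@gradient
  if (!all(c("Cmax", "lambda", "background") %in% names(g)))
    msg <- c(msg, "gradient must contain Cmax, lambda, background")
  else if (g$lambda <= 0) msg <- c(msg, "gradient$lambda must be > 0")
  p <- object@puncta
  for (fld in c("receptor_binding_prob", "endosome_prob", "surface_prob")) {
    v <- p[[fld]]
    if (is.null(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("puncta$%s must be a probability in [0,1]", fld))
  }
  for (cl in object@clones) {
    if (is.null(cl$uptake_factor) || cl$uptake_factor < 0)
      msg <- c(msg, "clone uptake_factor must be >= 0")
    if (is.null(cl$cells) || any(cl$cells < 1L) ||
        any(cl$cells > object@nCells))
      msg <- c(msg, "clone cells must lie within 1..nCells")
  }
  if (length(msg)) msg else TRUE
})

#' Geometry of a synthetic scene
#'
#' Midline polyline, per-cell centres, source position, and per-cell
#' straight-line (chord) distances to the source, all in micrometres.
#' Cell 1 is the distal tip (nearest the source).
#'
#' @slot midline two-column matrix (x, y) in um, arc-length parameterized.
#' @slot arcPositions numeric, arc-length position (um) of each midline vertex.
#' @slot cellCenters two-column matrix of per-cell centres (um).
#' @slot cellArc numeric, arc-length position (um) of each cell centre.
#' @slot sourcePos numeric length-2, source position (um).
#' @slot distances numeric, straight-line distance (um) of each cell centre
#'   to the source (including any zOffset, in quadrature).
#' @slot cellDiameter numeric, um.
#' @export
setClass("SceneGeometry",
  representation(
    midline = "matrix",
    arcPositions = "numeric",
    cellCenters = "matrix",
    cellArc = "numeric",
    sourcePos = "numeric",
    distances = "numeric",
    cellDiameter = "numeric"
  )
)

#' Ground truth for a rendered scene
#'
#' Records everything the quantification operations should recover: the
#' expected per-cell ligand intensity, the configured decay length and the
#' closed-form slope statistic, per-punctum channel flags, cytoneme polylines
#' with true lengths/angles/contact counts, and clone density ratios.
#'
#' @slot cells data.frame, one row per cell: \code{cell}, \code{x_um},
#'   \code{y_um}, \code{d_um}, \code{uptake_factor}, \code{expected_count},
#'   \code{expected_intensity}.
#' @slot trueLambda numeric, configured decay length (um).
#' @slot trueSlope numeric, closed-form slope Cmax / (2 lambda ln 2) (AU/um),
#'   valid for zero background.
#' @slot puncta data.frame, one row per ligand punctum with channel flags
#'   (\code{receptor}, \code{surface}, \code{endosome}).
#' @slot traces data.frame of cytoneme polyline vertices
#'   (\code{trace_id}, \code{cell_index}, \code{vertex}, \code{x_um},
#'   \code{y_um}).
#' @slot traceStats data.frame, one row per trace: true \code{length_um},
#'   \code{angle_deg}, \code{contact} flag and \code{contact_count}.
#' @slot grasp data.frame of GRASP contact puncta (\code{x_um}, \code{y_um},
#'   \code{trace_id}).
#' @slot clones data.frame, one row per clone: cell range, uptake factor and
#'   the expected outside/inside density ratio.
#' @export
setClass("GroundTruth",
  representation(
    cells = "data.frame",
    trueLambda = "numeric",
    trueSlope = "numeric",
    puncta = "data.frame",
    traces = "data.frame",
    traceStats = "data.frame",
    grasp = "data.frame",
    clones = "data.frame"
  )
)

#' A rendered synthetic scene
#'
#' Multi-channel image stack plus its generating configuration, geometry and
#' ground truth. Channels are \code{ligand}, \code{receptor}, \code{clone},
#' \code{eif} (surface-only ligand), \code{endosome} and \code{grasp}.
#' Image arrays are row-major matrices indexed [row = y, col = x]; physical
#' coordinates are in um with the origin at the image corner and the distal
#' tip near x = 0.
#'
#' @slot stack numeric 3-d array (rows, cols, channels).
#' @slot channelNames character vector naming the third dimension.
#' @slot pixelSize numeric, um per pixel.
#' @slot origin numeric length-2, physical (x, y) position in um of the
#'   centre of pixel (row 1, col 1); converts between image indices and the
#'   geometry frame.
#' @slot config the generating \code{SceneConfig}.
#' @slot geometry the \code{SceneGeometry}.
#' @slot truth the \code{GroundTruth}.
#' @export
setClass("SyntheticScene",
  representation(
    stack = "array",
    channelNames = "character",
    pixelSize = "numeric",
    origin = "numeric",
    config = "SceneConfig",
    geometry = "SceneGeometry",
    truth = "GroundTruth"
  )
)

#' Band-averaged intensity profile along the D-P axis
#'
#' @slot positions numeric, um from the distal tip, strictly increasing.
#' @slot values numeric, band-projected intensities (AU).
#' @slot bandWidth numeric, band width in pixels.
#' @slot projection character, "max" or "mean".
#' @slot channel character, source channel label.
#' @slot clipped integer, number of band samples clipped at the image border.
#' @export
setClass("IntensityProfile",
  representation(
    positions = "numeric",
    values = "numeric",
    bandWidth = "numeric",
    projection = "character",
    channel = "character",
    clipped = "integer"
  )
)

setValidity("IntensityProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@values))
    msg <- c(msg, "positions and values must have equal length")
  if (length(object@positions) < 3)
    msg <- c(msg, "a profile needs at least 3 points")
  if (any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Exponential fit of an intensity profile
#'
#' Least-squares fit of v(x) = background + Cmax * exp(-(x - xMax)/lambda)
#' together with the gradient-steepness statistic: the slope of the straight
#' line joining the profile maximum (Cmax at xMax) to its half-maximum point
#' (at xHalf). For a background-free exponential this slope equals
#' Cmax / (2 * lambda * ln 2).
#'
#' @slot cmax numeric, fitted amplitude above background at xMax (AU).
#' @slot xMax numeric, position of the profile maximum (um).
#' @slot lambda numeric, decay length (um).
#' @slot background numeric, fitted baseline (AU).
#' @slot xHalf numeric, position where the fitted curve reaches
#'   background + cmax/2 (um).
#' @slot slope numeric, (Cmax - Chalf)/(xHalf - xMax) in AU/um.
#' @slot r2 numeric, goodness of fit.
#' @slot flagged logical, TRUE when the profile is non-decaying and the fit
#'   (hence the slope) is undefined.
#' @export
setClass("GradientFit",
  representation(
    cmax = "numeric",
    xMax = "numeric",
    lambda = "numeric",
    background = "numeric",
    xHalf = "numeric",
    slope = "numeric",
    r2 = "numeric",
    flagged = "logical"
  )
)

#' Clone inside/outside intensity measurement
#'
#' Area-normalized intensity densities inside a marked clone ROI and in a
#' matched control ROI, and their outside/inside ratio.
#'
#' @slot insideDensity numeric, AU per um^2 (background-corrected).
#' @slot outsideDensity numeric, AU per um^2 (background-corrected).
#' @slot ratioOutIn numeric, outsideDensity / insideDensity; Inf-flagged when
#'   insideDensity is 0.
#' @slot insideArea numeric, um^2.
#' @slot outsideArea numeric, um^2.
#' @slot infiniteFlag logical.
#' @export
setClass("CloneMeasurement",
  representation(
    insideDensity = "numeric",
    outsideDensity = "numeric",
    ratioOutIn = "numeric",
    insideArea = "numeric",
    outsideArea = "numeric",
    infiniteFlag = "logical"
  )
)

#' Parameters of the cytoneme-feedback gradient simulator
#'
#' Parameterizes the one-dimensional chain of recipient cells in which
#' contact-dependent, receptor-bound ligand uptake through cytonemes is
#' shaped by PntP1-dependent positive and Cut/Yan-dependent negative
#' feedback with mutual inhibition. See the methods vignette for the full
#' update equations.
#'
#' @slot nCells integer, cells along the D-P axis.
#' @slot cellDiameter numeric, um; cell i sits at d_i = (i - 1/2) *
#'   cellDiameter from the primary source.
#' @slot sources data.frame with columns \code{pos_um} and \code{strength};
#'   the default single source sits at pos_um = 0 (distal tip).
#' @slot contact list \code{p0}, \code{rho_um}: p_contact(d) = p0 *
#'   exp(-d/rho_um), the probability that an emitted cytoneme reaches a
#'   source at distance d. Non-increasing in d by construction.
#' @slot uptake numeric, AU internalized per contact per unit receptor per
#'   unit source strength.
#' @slot deltaC numeric, per-step ligand decay rate in (0,1].
#' @slot thresholds named numeric (sty, pnt, cut, yan) on C; ordering
#'   sty > pnt > cut > yan enforced. sty and pnt are activated above
#'   threshold; cut and yan are derepressed below threshold.
#' @slot hillN named numeric (sty, pnt, cut, yan), per-gene Hill steepness.
#' @slot inhibition named numeric: \code{w_KP} (Cut on PntP1), \code{w_YP}
#'   (Yan on PntP1), \code{w_PK} (PntP1 on Cut), \code{w_PY} (PntP1 on Yan).
#' @slot cytoneme list \code{n_base}, \code{n_floor}, \code{n_cap},
#'   \code{alpha}, \code{beta}, \code{gamma}: n = clamp(n_base + alpha P -
#'   beta K - gamma Y, n_floor, n_cap). n_floor > 0: cells always retain
#'   short random cytonemes.
#' @slot receptor list \code{B_base}, \code{B_floor}, \code{B_cap},
#'   \code{alpha}, \code{beta}, \code{gamma}, analogous clamp for Btl level.
#' @slot longFrac list \code{f0}, \code{f1}, \code{p_min},
#'   \code{short_share}: fraction of emitted cytonemes in the long
#'   (>30 um) class, clamp01(f0 + f1 * max(P - p_min, 0)/(1 - p_min)) —
#'   long source-oriented cytonemes require PntP1 above the activation
#'   threshold p_min; the remainder splits short_share : 1 - short_share
#'   between the short and mid classes.
#' @slot relax numeric, per-step relaxation rate of gene levels toward
#'   their targets, in (0,1].
#' @slot tol numeric, max-norm convergence tolerance.
#' @slot maxSteps integer.
#' @slot mode character, "deterministic" (expected value) or "stochastic"
#'   (Poisson-sampled contacts, binomially thinned delivery).
#' @slot finitePool logical; when TRUE the source produces
#'   \code{poolProduction} AU per step into a depletable pool and
#'   availability is pool-limited. Off by default (non-depleting source).
#' @slot poolProduction numeric.
#' @slot clones list of clone overrides created by \code{\link{applyClone}}.
#' @export
setClass("SimParams",
  representation(
    nCells = "integer",
    cellDiameter = "numeric",
    sources = "data.frame",
    contact = "list",
    uptake = "numeric",
    deltaC = "numeric",
    thresholds = "numeric",
    hillN = "numeric",
    inhibition = "numeric",
    cytoneme = "list",
    receptor = "list",
    longFrac = "list",
    relax = "numeric",
    tol = "numeric",
    maxSteps = "integer",
    mode = "character",
    finitePool = "logical",
    poolProduction = "numeric",
    clones = "list"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  th <- object@thresholds
  if (!all(c("sty", "pnt", "cut", "yan") %in% names(th)))
    msg <- c(msg, "thresholds must name sty, pnt, cut, yan")
  else if (!(th["sty"] > th["pnt"] && th["pnt"] > th["cut"] &&
             th["cut"] > th["yan"]))
    msg <- c(msg, "threshold ordering sty > pnt > cut > yan violated")
  if (object@uptake < 0 || object@deltaC <= 0 || object@deltaC > 1)
    msg <- c(msg, "uptake must be >= 0 and deltaC in (0,1]")
  if (object@relax <= 0 || object@relax > 1)
    msg <- c(msg, "relax must be in (0,1]")
  cy <- object@cytoneme
  if (is.null(cy$n_floor) || cy$n_floor <= 0)
    msg <- c(msg, "cytoneme n_floor must be > 0")
  if (!object@mode %in% c("deterministic", "stochastic"))
    msg <- c(msg, "mode must be 'deterministic' or 'stochastic'")
  if (any(object@sources$strength < 0))
    msg <- c(msg, "source strengths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a feedback-simulation run
#'
#' @slot states data.frame, one row per cell with the steady-state values of
#'   C (internalized ligand), sty, P (PntP1), K (Cut), Y (Yan), B (Btl),
#'   n (cytoneme emission rate) and the per-class expected counts
#'   n_short/n_mid/n_long.
#' @slot converged logical.
#' @slot oscillating logical, TRUE when a period-2 cycle was detected.
#' @slot steps integer, steps taken.
#' @slot params the \code{SimParams} used.
#' @slot ledger list with cumulative mass bookkeeping: \code{produced},
#'   \code{delivered}, \code{undelivered}, \code{decayed}.
#' @slot trajectory list, optional per-step snapshots of C.
#' @export
setClass("SimResult",
  representation(
    states = "data.frame",
    converged = "logical",
    oscillating = "logical",
    steps = "integer",
    params = "SimParams",
    ledger = "list",
    trajectory = "list"
  )
)
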
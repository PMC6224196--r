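---
title: "Feedback-regulated cytoneme transport and gradient quantification: models and methods"
author: "cytograd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-regulated cytoneme transport and gradient quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytograd)
```

# The biological problem

FGF/Bnl produced by a restricted group of *Drosophila* wing-disc cells is
taken up by the air-sac primordium (ASP), a tracheal outgrowth whose
distal tip sits nearest the source. The ligand does not spread as a free
extracellular gradient: ASP cells extend receptor (Btl)-containing
cytonemes that touch the source and carry ligand back in a receptor-bound
state, so the exponential ligand gradient along the ASP's distal-proximal
(D-P) axis is *built by the recipient tissue*. Ligand levels read out as
nested transcriptional domains — *sprouty* in the distal-most cells,
*pntP1* over the distal half, *cut* and *yan* rising in the proximal
stalk — and the transcription factors feed back on cytoneme and receptor
production: PntP1 promotes both, Cut and Yan suppress both, and PntP1 and
Cut repress each other. The result is a self-generating gradient whose
shape tracks the tissue's own morphology.

`cytograd` provides three connected layers:

1. a **feedback simulator** of this mechanism on a 1-D chain of recipient
   cells (`runToSteadyState()` and friends);
2. a **synthetic microscopy-scene generator** with complete ground truth
   (`renderScene()`), replacing the confocal data that the quantification
   methods were designed for;
3. the **quantification pipeline**: curved-epithelium straightening and
   band profiles, exponential trend fits and the Cmax-to-half-max slope,
   mosaic-clone intensity ratios, punctum detection/colocalization, and
   cytoneme length/orientation/contact statistics.

# The feedback model

## State and update rules

Each cell `i` (1-based from the distal tip, centre at
`d_i = (i - 1/2) * cellDiameter`, default 10 um) carries internalized
ligand `C_i` (AU), transcription-factor levels `sty_i, P_i, K_i, Y_i`
(PntP1, Cut, Yan; each in [0, 1]), receptor level `B_i` and cytoneme
emission rate `n_i`. One synchronous step applies, in this fixed order:

1. **Contacts.** The probability that an emitted cytoneme reaches a
   source at distance `d` is the geometric tail
   `p(d) = p0 * exp(-d / rho)` (`rho` = 40 um); expected contacts are
   `m_i = n_i * p(d_i)`, summed over sources.
2. **Uptake.** `dC_i = u * B_i * m_i * S * q` with uptake coefficient
   `u = 0.05`, source strength `S = 10` and per-contact delivery
   probability `q = 0.9`. The source is non-depleting by default
   (availability 1); a finite-pool option rations the step's total
   demand against a produced pool and is used for the mass-balance
   checks.
3. **Turnover.** `C_i <- C_i + dC_i - deltaC * C_i` with
   `deltaC = 0.2` per step; `deltaC` sets the gradient's range and is a
   free parameter of the model, not a measured quantity.
4. **Gene readout.** With `hill(C, th, h) = C^h / (C^h + th^h)`,
   the targets are

   * `sty* = hill(C, th_sty, h_sty)`
   * `P*  = hill(C, th_pnt, h_pnt) / (1 + w_KP K + w_YP Y)`
   * `K*  = (1 - hill(C, th_cut, h_cut)) / (1 + w_PK P)`
   * `Y*  = (1 - hill(C, th_yan, h_yan)) / (1 + w_PY P)`

   (activation above threshold for sty/pntP1, derepression below
   threshold for cut/yan, with mutual inhibition as divisive weights).
   Levels relax toward their targets at rate `relax = 0.2` per step.
5. **Production feedback.** `n_i = clamp(n_base + a_n P - b_n K - g_n Y,
   n_floor, n_cap)` and analogously for `B_i`. `n_floor > 0` encodes
   that even fully suppressed stalk cells keep a few short, randomly
   oriented cytonemes.

The long-cytoneme class (the >30 um, source-oriented cytonemes that
actually reach the source) is a gated fraction of emission,
`f_long = f0 + f1 * max(P - p_min, 0) / (1 - p_min)` with
`p_min = 0.35`: long oriented cytonemes require substantial PntP1, which
is why stalk clones show none at all rather than merely fewer. The
remaining emission splits 70/30 between the short and mid classes.

Deterministic mode iterates expectations until the max-norm step change
falls below `tol = 1e-8` (period-2 cycles are detected and flagged).
Stochastic mode draws Poisson contact *events* — each reaching cytoneme
makes `events_per_contact = 500` transient contact events per step whose
packets are binomially delivered — so the deterministic limit is the
exact expectation and flux noise lives at the packet level, as in
imaging where each contact streams many sub-resolution puncta. With
order-one contacts per step instead, the Poisson noise at domain
boundary cells is rectified by the feedback nonlinearity and stochastic
means detach from the deterministic fixed point.

## Calibration of the reference configuration

The shipped `reference.yaml` (also the `simParams()` defaults) was fixed
once, by the staged search documented in `scripts/calibrate.R`, so that
the 14-cell deterministic run (12 ASP cells plus the 2-cell transverse
connective) reproduces the observed domain boundaries under the
half-maximum ON rule — sty cells 1-3, pntP1 1-7, cut 7-14, yan 11-14 —
and the 12-cell run gives a 7-cell distal zone of long source-oriented
cytonemes.

Two findings from that search shape the defaults:

* **The boundary cell must be monostable.** The pntP1/cut overlap at
  cell 7 requires the boundary cell to sit at an intermediate fixed
  point (P and K both near half-max). With strong positive-feedback
  gains or a steep PntP1 response the per-cell fixed point is bistable
  and the boundary cell snaps to one branch or the other, skipping the
  overlap entirely. Soft gains (`alpha_n = 2.5`), a shallow PntP1 Hill
  (0.5), a shallow cut derepression (Hill 1), near-equal thresholds
  (`th_cut = 0.92 * th_pnt`) and weak mutual inhibition make the
  transition graded; the qualifying region is a plateau, not a knife
  edge (theta_pnt anywhere in ~0.92-0.96 works).
* **Clamp saturation.** In the deep stalk both `n` and `B` sit at their
  floors; further negative feedback there changes nothing. Sign tests
  for the Cut/Yan gains are therefore asserted where the corresponding
  factor is active *and* production is unclamped (the boundary cells),
  with global non-increase elsewhere.

## Gradient scaling

Axis lengths of 6-14 cells in `scalingExperiment()` emulate tissues at
different developmental stages. Cytoneme reach is scaled proportionally
with axis length (`rho ~ L`), reflecting that small early tissues carry
only short cytonemes while late ones extend the >30 um class; this is
what lets the gradient stretch with the tissue, producing the strictly
decreasing Cmax-to-half-max slope with increasing axis length (Pearson
r < 0). With absolute reach the steady profile is length-invariant — a
shorter axis is literally a truncation of a longer one — and the fitted
slope cannot fall with tissue size; `scaleReach = FALSE` exposes that
behaviour. The 12- and 14-cell *reference* runs, by contrast, are the
same tissue with and without the transverse connective and share one
absolute `rho`.

Slopes in the scaling experiment are fitted without a background term:
simulated profiles carry no imaging baseline.

# The synthetic scene generator

`renderScene()` draws a multi-channel, microscopy-like image of the
tubular epithelium (channels: ligand, receptor, clone label, surface-EIF,
endosome, GRASP), with every quantity recorded in a `GroundTruth`.

* **Geometry.** A constant-curvature midline with one cell per
  `cellDiameter` of arc; the source sits at the distal end. Cell-centre
  chord distances are strictly increasing for total turning below half a
  circle; a midline turning 2*pi or more is rejected. The default
  12 x 10 um axis at 0.2 um/px matches the ~100-120 um gradient range;
  upper-layer scenes are represented by `zOffset` (extra source distance
  in quadrature), not by true 3-D rendering, since all quantification
  operates on projections.
* **Ligand.** Per-cell punctum counts are Poisson with expectation
  `density_scale * Cmax * exp(-d_i/lambda) * uptake_factor(i)`. Puncta
  render as Gaussian spots (sigma 0.3 um) whose brightness scales with
  the local expected ligand level (puncta are clusters of sub-resolution
  molecules). Underneath runs a continuous *nanopuncta film* following
  the exact gradient: cell surfaces in the real tissue are densely
  covered with dim sub-resolution signal, and this film carries ~90% of
  the band flux under the defaults (`film_intensity = 60` vs punctum
  amplitude 25 at `density_scale = 0.15`). The balance matters: if
  discrete spots dominated the band profile, its decay would follow
  amplitude x presence-probability (an apparent decay length of about
  half the true one) and no estimator could recover `lambda`.
* **Channel flags.** Each ligand punctum carries a receptor partner with
  probability `receptor_binding_prob` (default 1: all ASP ligand is
  receptor-bound), a surface flag (`surface_prob = 0.15`; only these
  appear in the EIF channel), and, if internalized, an endosome flag
  (`endosome_prob = 0.76`, the early-endosome fraction). Punctum
  intensity statistics and background levels are free parameters of the
  generator recorded in the ground truth, not claims about the fly data.
* **Clones.** A marked clone occupies the half-tube on one side of the
  midline over its cells' arc range (mosaic patches sit on one face of
  the epithelium); puncta and film inside are thinned by
  `uptake_factor`. The measurement masks (`sceneCloneMask()` /
  `sceneControlMask()`) are inset 1 um from all region boundaries so
  that PSF bleed across edges does not contaminate the densities, and
  the control is the mirror region at the same D-P position.
* **Cytonemes.** Polylines rooted at cell centres; lengths from the
  short/mid/long mixture (uniform within 2-15 / 15-30 / 30-60 um),
  orientations von Mises about the source direction (Best-Fisher
  sampler; kappa = 0 is uniform). A trace contacts the source when its
  reach is at least the cell's source distance; contacting traces
  receive >= 1 GRASP puncta (mean `grasp_rate`) along their distal
  portion.
* **Noise, fixed order.** PSF blur (Gaussian, 0.3 um) first, then
  Poisson shot noise on the expected counts, then additive Gaussian read
  noise. Identical config + seed gives a bit-identical stack.

What the generator does *not* emulate: true 3-D volumes and two-layer
epithelial topology, sub-resolution nanopunctum structure within spots,
autofluorescence textures, motion or bleaching. Recovery tests therefore
demonstrate estimator correctness on data satisfying the model's own
assumptions — not performance on real confocal stacks.

# Quantification methods

* **Straightening and band profiles.** `fitMidline()` fits an
  arc-length-parameterized smoothing spline through ordered anchors or a
  tube mask (principal-curve-style iteration: smooth, project pixels
  onto the curve, re-bin; the smoothing step is what keeps the iteration
  stable on strongly curved tubes). `extractProfile()` resamples the
  image along perpendiculars over a 40-px band — the digital
  straightening of the curved epithelium — and collapses the band by max
  (default) or mean.
* **Trend fits and the slope statistic.** `fitExponential()` fits
  `v(x) = background + A exp(-(x - xMax)/lambda)` from the profile
  maximum onward by nonlinear least squares with log-linear
  initialization (background optional, default on). The gradient
  steepness statistic is the slope of the straight line from Cmax to the
  half-maximum point, `(Cmax - Chalf)/(xHalf - xMax)`; for zero
  background this equals `Cmax/(2 lambda ln 2)`, the closed form the
  tests pin to 1e-6. Non-decaying profiles (flat, or lambda estimates
  non-positive/unbounded) are flagged with an undefined slope. Recovery
  tests fit *mean*-projected band profiles — the trend line is an
  exponential fit of averaged values — while max remains the band
  default for display profiles.
* **Clone ratios.** Area-normalized intensity densities inside the clone
  ROI and in an equal-area (within 10%) control ROI at the equivalent
  position; when no control is given it is auto-constructed by mirroring
  the clone about the midline. An optional per-pixel background is
  subtracted from both densities. Zero inside-density reports an
  infinite-flag ratio rather than an error.
* **Puncta.** Single-scale Laplacian-of-Gaussian blob detection matched
  to the 0.3 um spot, local maxima above a robust (median + 5 MAD)
  threshold, 3x3 centroid refinement. Colocalization is the fraction of
  set A whose nearest neighbour in B lies within `maxDistUm`
  (nearest-centroid, default 0.5 um — a criterion suited to
  diffraction-limited spots, not pixel-overlap coefficients). The
  fraction is monotone in the radius, and at high punctum density
  incidental neighbours inflate it above the binding probability;
  recovery tests therefore use sparse scenes and a tight radius.
* **Cytoneme statistics.** Length is polyline arc length; orientation is
  the angle between the net displacement and the source direction (net
  displacement, not per-segment tangents, matches visual scoring of
  "oriented toward the source"). Length classes are <15, 15-30 (closed
  on both ends, so exactly 15 and exactly 30 are "mid") and >30 um.
  Rose histograms use 20 degree sectors with one sector centred on the
  source direction. Regions along a 12-cell axis: cells 1-3 tip, 4-7
  mid, beyond 7 stalk. GRASP puncta are assigned to the nearest trace
  within 1 um — a stated proxy for the visual assignment used on real
  images, which can swap puncta between overlapping traces near the
  source.
* **Statistics.** Two-tailed Welch t-tests for two-group comparisons;
  one-way ANOVA with Tukey HSD for multi-region comparisons; Pearson
  correlation (two-sided) for slope-versus-length.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately compact
problem sizes, chosen as the smallest that give the estimators stable
behaviour: 12-14 cell axes (converging in a few hundred steps at
tolerance 1e-8), scenes of ~90 x 700 px, 20 scenes for neutral-clone
ratios, 50 for uptake-factor recovery, 20 x ~500 puncta for
colocalization, and 100 seeds x 800 steps for the
stochastic-deterministic comparison. Ties and degenerate inputs are
handled explicitly: zero-length traces are flagged, empty punctum sets
give an undefined (NA) fraction with a warning, all-off genes yield
empty domains, and conflicting clone pins on one cell are an error.

# Known limitations

* The model is 1-D and synchronous; tissue mechanics, growth and cell
  division are out of scope, as are explicit cytoneme pathfinding,
  source-emitted cytonemes and intracellular trafficking kinetics.
* Yan has its own gain, smaller than Cut's, but only the signs of its
  effects are claimed; whether its cytoneme suppression is independent
  of Cut is not resolvable from the biology the model encodes.
* Receptor level and cytoneme number enter uptake multiplicatively;
  their relative contributions are not separately identified.
* The half-maximum ON rule is one defensible reading of expression
  domains; boundaries shift by about a cell under other cutoffs.
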
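#!/usr/bin/env Rscript
# Calibration of the reference feedback configuration.
#
# The thresholds and gains shipped in inst/extdata/reference.yaml were
# fixed once by the staged search below. The targets are anatomical:
# on the 14-cell axis (including the 2-cell transverse connective) the
# deterministic steady state must place, under the half-maximum ON
# rule, sty in cells 1-3, pntP1 in 1-7, cut in 7-14 and yan in 11-14 -
# with cell 7 expressing both pntP1 and cut - and the 12-cell run must
# give a 7-cell distal zone of long source-oriented cytonemes.
#
# Design notes from the search:
#  * With strong positive-feedback gains (alpha_n >~ 5) or steep PntP1
#    activation the boundary cell snaps between a fully-on and a
#    fully-off branch and can never sit at the intermediate state that
#    the pntP1/cut overlap at cell 7 requires; soft gains (alpha_n 2.5)
#    plus a shallow PntP1 response (Hill 0.5) make the transition
#    graded.
#  * The overlap also needs theta_cut close to theta_pnt (ratio 0.92)
#    and a shallow cut derepression (Hill 1), so that at the boundary
#    cell's ligand level PntP1 is still above half its maximum while
#    Cut has already reached half of its own.
#  * theta_sty and theta_yan are pure readouts (sty) or weak feedbacks
#    (yan) and are placed last against the converged ligand profile.
#
# Running this script re-evaluates the final neighbourhood and rewrites
# inst/extdata/reference.yaml with the frozen values.

suppressPackageStartupMessages(library(cytograd))

candidate <- function(th_pnt, ratio, th_sty, th_yan) {
  simParams(
    thresholds = c(sty = th_sty, pnt = th_pnt, cut = th_pnt * ratio,
                   yan = th_yan),
    hillN = c(sty = 4, pnt = 0.5, cut = 1, yan = 3),
    inhibition = c(w_KP = 0.1, w_YP = 0.15, w_PK = 0.05, w_PY = 0.3),
    cytoneme = list(alpha = 2.5, beta = 2.5),
    receptor = list(alpha = 1.2, beta = 0.4),
    longFrac = list(p_min = 0.35),
    contact = list(rho_um = 40))
}

evaluate <- function(p) {
  res <- runToSteadyState(p)
  if (!converged(res)) return(NULL)
  dom <- expressionDomains(res)
  get <- function(g, f) dom[[f]][dom$gene == g]
  p12 <- p
  p12@nCells <- 12L
  st12 <- steadyStates(runToSteadyState(p12))
  above <- st12$n_long > st12$n_long[12]
  zone <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  c(sty_last = get("sty", "last_on_cell"),
    pnt_last = get("pntP1", "last_on_cell"),
    cut_first = get("cut", "first_on_cell"),
    yan_first = get("yan", "first_on_cell"),
    zone = zone)
}

target <- c(sty_last = 3, pnt_last = 7, cut_first = 7, yan_first = 11,
            zone = 7)

cat("scanning the final neighbourhood...\n")
best <- NULL
for (th_pnt in seq(0.88, 0.96, by = 0.02)) {
  for (th_yan in c(0.05, 0.055, 0.06)) {
    p <- candidate(th_pnt, ratio = 0.92, th_sty = 5, th_yan = th_yan)
    ev <- evaluate(p)
    if (is.null(ev)) next
    hit <- all(ev == target)
    cat(sprintf("  th_pnt %.2f th_yan %.3f -> %s %s\n", th_pnt, th_yan,
                paste(ev, collapse = "/"),
                if (hit) "<- satisfies all targets" else ""))
    if (hit && is.null(best)) best <- p
    # the frozen reference point takes precedence when it qualifies
    if (hit && abs(th_pnt - 0.92) < 1e-9 && abs(th_yan - 0.055) < 1e-9) {
      best <- p
    }
  }
}
stopifnot(!is.null(best))
out <- file.path("inst", "extdata", "reference.yaml")
writeSimParams(best, out)
cat("frozen reference written to", out, "\n")
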
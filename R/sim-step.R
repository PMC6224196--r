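# Cell positions and per-cell source drive.
cellPositions <- function(params) {
  (seq_len(params@nCells) - 0.5) * params@cellDiameter
}

# expected per-contact-rate source drive: sum over sources of
# strength * p_contact(|x_i - pos_s|); p_contact is non-increasing in
# distance by construction
sourceDrive <- function(params) {
  x <- cellPositions(params)
  ct <- params@contact
  drive <- numeric(params@nCells)
  for (s in seq_len(nrow(params@sources))) {
    d <- abs(x - params@sources$pos_um[s])
    drive <- drive + params@sources$strength[s] * ct$p0 *
      exp(-d / ct$rho_um)
  }
  drive
}

# fresh initial state: no ligand, genes off, cytoneme/receptor baselines
initState <- function(params) {
  n0 <- clamp(params@cytoneme$n_base, params@cytoneme$n_floor,
              params@cytoneme$n_cap)
  B0 <- clamp(params@receptor$B_base, params@receptor$B_floor,
              params@receptor$B_cap)
  data.frame(
    cell = seq_len(params@nCells),
    d_um = cellPositions(params),
    C = 0, sty = 0, P = 0, K = 0, Y = 0,
    B = B0, n = n0)
}

applyPins <- function(state, params) {
  for (cl in params@clones) {
    cells <- cl$cells
    switch(cl$type,
      cut_GOF = { state$K[cells] <- 1 },
      pnt_GOF = { state$P[cells] <- 1 },
      pnt_LOF = { state$P[cells] <- 0 },
      btl_LOF = { state$B[cells] <- 0 },
      btl_GOF = { state$B[cells] <- params@receptor$B_cap },
      NULL)
    # pinned transcription factors feed through to n and B on the next
    # update; pinned B itself must survive the clamp, re-applied by caller
  }
  state
}

#' One synchronous update of the feedback simulator
#'
#' Applies, in this fixed order: (1) expected source contacts
#' m_i = n_i * p_contact(d_i) (Poisson-sampled in stochastic mode, with
#' binomial per-contact delivery); (2) uptake
#' dC_i = uptake * B_i * m_i * strength * deliver_prob * availability;
#' (3) ligand turnover C <- C + dC - deltaC * C; (4) gene targets from the
#' updated C through per-gene Hill functions with mutual-inhibition
#' divisors, toward which levels relax at rate \code{relax}; (5) cytoneme
#' and receptor production n and B as clamped linear feedback
#' (+PntP1, -Cut, -Yan), then clone pins. Availability is 1 for the
#' default non-depleting source; with \code{finitePool} the step's total
#' demand is rationed against the pool.
#'
#' @param state data.frame as produced by \code{\link{runToSteadyState}}
#'   (columns C, sty, P, K, Y, B, n).
#' @param params a \code{\linkS4class{SimParams}}.
#' @param pool current source pool (finite-pool mode only).
#' @return list with the updated \code{state}, \code{delivered} (total AU
#'   taken up this step), \code{decayed}, \code{produced} and the updated
#'   \code{pool}.
#' @export
simStep <- function(state, params, pool = Inf) {
  drive <- sourceDrive(params)
  ct <- params@contact
  stoch <- params@mode == "stochastic"
  n <- state$n
  B <- state$B
  if (stoch) {
    # realized contact events with each source are Poisson (each reaching
    # cytoneme makes events_per_contact transient contact events, as seen
    # in GRASP imaging); each event delivers its ligand packet with
    # probability deliver_prob (binomial)
    x <- cellPositions(params)
    ev <- ct$events_per_contact
    dC <- numeric(length(n))
    for (s in seq_len(nrow(params@sources))) {
      d <- abs(x - params@sources$pos_um[s])
      pReach <- ct$p0 * exp(-d / ct$rho_um)
      k <- stats::rpois(length(n), n * pReach * ev)
      del <- stats::rbinom(length(n), k, ct$deliver_prob)
      dC <- dC + params@uptake * B * params@sources$strength[s] *
        del / ev
    }
  } else {
    dC <- params@uptake * B * n * drive * ct$deliver_prob
  }
  produced <- if (params@finitePool) params@poolProduction else sum(dC)
  avail <- 1
  if (params@finitePool) {
    pool <- pool + params@poolProduction
    tot <- sum(dC)
    if (tot > pool && tot > 0) avail <- pool / tot
    dC <- dC * avail
    pool <- pool - sum(dC)
  }
  decayed <- sum(params@deltaC * state$C)
  C <- state$C + dC - params@deltaC * state$C
  if (any(!is.finite(C))) stop("non-finite ligand level: aborting")

  th <- params@thresholds
  hh <- params@hillN
  w <- params@inhibition
  sTar <- hill(C, th["sty"], hh["sty"])
  pTar <- hill(C, th["pnt"], hh["pnt"]) /
    (1 + w["w_KP"] * state$K + w["w_YP"] * state$Y)
  kTar <- (1 - hill(C, th["cut"], hh["cut"])) /
    (1 + w["w_PK"] * state$P)
  yTar <- (1 - hill(C, th["yan"], hh["yan"])) /
    (1 + w["w_PY"] * state$P)
  r <- params@relax
  newState <- state
  newState$C <- C
  newState$sty <- state$sty + r * (sTar - state$sty)
  newState$P <- state$P + r * (pTar - state$P)
  newState$K <- state$K + r * (kTar - state$K)
  newState$Y <- state$Y + r * (yTar - state$Y)
  # pinned transcription factors are excluded from the relaxation update
  # and must feed into the n/B production rules below
  newState <- applyPins(newState, params)

  cy <- params@cytoneme
  rc <- params@receptor
  newState$n <- clamp(
    cy$n_base + cy$alpha * newState$P - cy$beta * newState$K -
      cy$gamma * newState$Y, cy$n_floor, cy$n_cap)
  newState$B <- clamp(
    rc$B_base + rc$alpha * newState$P - rc$beta * newState$K -
      rc$gamma * newState$Y, rc$B_floor, rc$B_cap)
  # receptor pins override the production rule (btl_LOF sits below the
  # clamp floor; btl_GOF at the cap)
  for (cl in params@clones) {
    if (cl$type == "btl_LOF") newState$B[cl$cells] <- 0
    if (cl$type == "btl_GOF") newState$B[cl$cells] <- rc$B_cap
  }
  if (any(!is.finite(as.matrix(
    newState[, c("C", "sty", "P", "K", "Y", "B", "n")])))) {
    stop("non-finite simulator state: aborting")
  }
  list(state = newState, delivered = sum(dC), decayed = decayed,
       produced = produced, pool = pool)
}
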
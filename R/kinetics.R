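#' Mean first passage time between state sets
#'
#' Solves the standard linear system for the expected hitting time of the
#' target set: on non-target states,
#' \eqn{(I - T_{\neg B}) m = \tau \mathbf{1}}, where \eqn{\tau} is the model
#' lag in physical time; the returned MFPT is the stationary-weighted average
#' of `m` over the source set. `MFPT(A, A) = 0` by construction.
#'
#' @param model A [estimate_reversible()] model.
#' @param source,target Disjoint, non-empty sets of state indices (positions
#'   in the model's active set).
#' @return MFPT in the physical time units of the model's `frame_interval`.
#' @export
mfpt <- function(model, source, target) {
  stopifnot(inherits(model, "markov_model"))
  k <- nrow(model$T)
  source <- as.integer(source); target <- as.integer(target)
  if (length(source) == 0 || length(target) == 0)
    abort("source and target must be non-empty")
  if (any(c(source, target) < 1) || any(c(source, target) > k))
    abort("state indices outside the active set")
  if (length(intersect(source, target)) > 0) {
    if (setequal(source, target)) return(0)
    abort("source and target sets must be disjoint")
  }
  tau <- model$lag * model$frame_interval
  nt <- setdiff(seq_len(k), target)
  A <- diag(length(nt)) - model$T[nt, nt, drop = FALSE]
  m <- tryCatch(solve(A, rep(tau, length(nt))),
                error = function(e) abort("target set is unreachable from the source (singular system)"))
  m_full <- numeric(k)
  m_full[nt] <- m
  w <- model$pi[source] / sum(model$pi[source])
  sum(w * m_full[source])
}

#' Direct (counting) estimate of a mean first passage time
#'
#' Model-free estimator used to validate MSM kinetics: for every observed
#' visit to the source state, the time until the trajectory is next observed
#' in the target state is counted, and the mean over source visits is the
#' empirical MFPT (the stationary-start convention, matching [mfpt()]).
#'
#' The label sequence is read at an observation interval of `stride` frames.
#' When validating a Markov model, set `stride` to the model's lag: the
#' model describes the dynamics observed at its lag, and sub-lag barrier
#' recrossings — which a first-touch count at full frame resolution picks
#' up — are below its time resolution.
#'
#' @param labels Per-frame state labels (vector or list of vectors; `NA`
#'   allowed for unassigned frames).
#' @param from,to State labels of the source and target.
#' @param frame_interval Physical time per frame.
#' @param stride Observation interval in frames (default 1).
#' @return List with `mfpt` (physical time) and `n_events` (number of
#'   uninterrupted target entries observed, a resolution-robust event count).
#' @export
empirical_mfpt <- function(labels, from, to, frame_interval = 1,
                           stride = 1L) {
  if (!is.list(labels)) labels <- list(labels)
  total <- 0; n_obs <- 0; n_events <- 0
  for (lab in labels) {
    l <- lab[seq(1, length(lab), by = stride)]
    n <- length(l)
    idx_b <- which(!is.na(l) & l == to)
    if (length(idx_b) == 0) next
    # first target occurrence at or after each position
    pos <- findInterval(seq_len(n) - 0.5, idx_b) + 1
    nxt <- ifelse(pos <= length(idx_b), idx_b[pos], NA_integer_)
    in_a <- which(!is.na(l) & l == from & !is.na(nxt))
    if (length(in_a) == 0) next
    total <- total + sum(nxt[in_a] - in_a)
    n_obs <- n_obs + length(in_a)
    n_events <- n_events + sum(diff(idx_b) > 1) + 1
  }
  if (n_obs == 0) abort("no source-to-target passages observed")
  list(mfpt = total / n_obs * frame_interval * stride, n_events = n_events)
}

#' Pairwise macrostate kinetics table
#'
#' All pairwise mean first passage times between the crisp macrostates of a
#' [pcca_plus()] model, with rates `k = 1/MFPT`. Off-diagonal MFPTs of an
#' irreducible chain are strictly positive; the diagonal is zero.
#'
#' @param macro A `macrostate_model`.
#' @return A tibble (class `kinetics_table`) with columns `from`, `to`,
#'   `mfpt` (physical time), `rate` (1/time).
#' @export
kinetics_table <- function(macro) {
  stopifnot(inherits(macro, "macrostate_model"))
  n <- macro$n_macro
  sets <- lapply(seq_len(n), function(a) which(macro$labels == a))
  rows <- purrr::map_dfr(seq_len(n), function(a) {
    purrr::map_dfr(seq_len(n), function(b) {
      m <- if (a == b) 0 else mfpt(macro$model, sets[[a]], sets[[b]])
      tibble(from = a, to = b, mfpt = m,
             rate = ifelse(m > 0, 1 / m, NA_real_))
    })
  })
  class(rows) <- c("kinetics_table", class(rows))
  rows
}

#' State free energies from stationary weights
#'
#' \eqn{G_A = -R T \ln \Pi_A}, shifted so the most populated state sits at
#' zero. The most populated basin therefore has the lowest free energy; for
#' a voltage-sensing domain simulated at depolarised conditions this is the
#' activated state.
#'
#' @param weights Macrostate stationary weights (or a `macrostate_model`).
#' @param temperature Temperature in K (default 300).
#' @return Tibble with `state`, `weight`, `free_energy` (kJ/mol, min 0).
#' @export
state_free_energies <- function(weights, temperature = 300) {
  if (inherits(weights, "macrostate_model")) weights <- weights$weights
  if (any(weights <= 0)) abort("all state weights must be positive")
  w <- weights / sum(weights)
  R <- physical_constants()$R
  G <- -R * temperature * log(w) / 1000
  tibble(state = seq_along(w), weight = w, free_energy = G - min(G))
}

#' Transition-state-theory barrier from a rate (and back)
#'
#' Inverts the Eyring-type relation \eqn{k = (k_B T / h)\,K^\ddagger} with
#' \eqn{K^\ddagger = \exp(-\Delta G^\ddagger / R T)} (no transmission
#' prefactor):
#' \deqn{\Delta G^\ddagger = R T \ln\!\big(k_B T / (h\,k)\big).}
#' The pair `tst_barrier()` / `tst_rate()` round-trips exactly. A rate at or
#' above the attempt frequency \eqn{k_B T / h} yields a non-positive barrier,
#' returned with a warning (barrierless regime).
#'
#' @param rate_k Rate in 1/s (e.g. `1 / MFPT` with MFPT in seconds).
#' @param temperature Temperature in K.
#' @return Barrier in kJ/mol (`tst_barrier`) or rate in 1/s (`tst_rate`).
#' @examples
#' tst_barrier(1e6)             # a 1/us rate at 300 K
#' tst_rate(tst_barrier(1e6))   # = 1e6
#' @export
tst_barrier <- function(rate_k, temperature = 300) {
  if (any(rate_k <= 0)) abort("rate_k must be > 0")
  pc <- physical_constants()
  nu <- kbt_over_h(temperature)
  dG <- pc$R * temperature * log(nu / rate_k) / 1000
  if (any(rate_k >= nu))
    warn("rate at or above kB*T/h: barrier is <= 0 (barrierless regime)")
  dG
}

#' @rdname tst_barrier
#' @param barrier Barrier in kJ/mol.
#' @export
tst_rate <- function(barrier, temperature = 300) {
  pc <- physical_constants()
  kbt_over_h(temperature) * exp(-barrier * 1000 / (pc$R * temperature))
}

#' Assemble a 1D free-energy profile along a state ordering
#'
#' The schematic one-dimensional summary of the activation landscape: state
#' levels from equilibrium weights, and forward/backward barriers between
#' adjacent states from transition-state theory applied to the inverse MFPTs,
#' each measured from the departing state's level. A thermodynamic-cycle
#' diagnostic (`cycle_residual`, kJ/mol) reports how far
#' \eqn{G_B - G_A} deviates from
#' \eqn{\Delta G^\ddagger_{fwd} - \Delta G^\ddagger_{bwd}}; TST inversion
#' of finite-sampling MFPTs need not close the cycle exactly, so this is a
#' consistency report, not an error.
#'
#' @param macro A `macrostate_model`.
#' @param kinetics A [kinetics_table()] with MFPTs in seconds.
#' @param ordering Permutation of macrostate indices from the deepest resting
#'   state to the activated state (each exactly once). Defaults to the
#'   identity order.
#' @param temperature Temperature in K.
#' @param state_names Optional character names along the ordering.
#' @return Object of class `free_energy_profile`: tibbles `states`
#'   (`state`, `name`, `free_energy`) and `barriers` (`from`, `to`,
#'   `direction`, `mfpt`, `rate`, `barrier`, `peak_level`, `cycle_residual`),
#'   plus `temperature`.
#' @export
build_profile <- function(macro, kinetics = NULL, ordering = NULL,
                          temperature = 300, state_names = NULL) {
  stopifnot(inherits(macro, "macrostate_model"))
  n <- macro$n_macro
  if (is.null(kinetics)) kinetics <- kinetics_table(macro)
  if (is.null(ordering)) ordering <- seq_len(n)
  if (!setequal(ordering, seq_len(n)) || length(ordering) != n)
    abort("ordering must cover every macrostate exactly once")
  if (is.null(state_names))
    state_names <- c(paste0("resting ", rev(seq_len(n - 1))), "activated")
  G <- state_free_energies(macro, temperature)
  levels <- G$free_energy[ordering]
  states <- tibble(state = ordering, name = state_names,
                   position = seq_len(n), free_energy = levels)
  get_mfpt <- function(a, b) {
    v <- kinetics$mfpt[kinetics$from == a & kinetics$to == b]
    if (length(v) != 1 || !is.finite(v))
      abort(sprintf("no finite MFPT between macrostates %d and %d", a, b))
    v
  }
  barriers <- purrr::map_dfr(seq_len(n - 1), function(i) {
    a <- ordering[i]; b <- ordering[i + 1]
    m_f <- get_mfpt(a, b); m_b <- get_mfpt(b, a)
    dg_f <- tst_barrier(1 / m_f, temperature)
    dg_b <- tst_barrier(1 / m_b, temperature)
    resid <- abs((levels[i + 1] - levels[i]) - (dg_f - dg_b))
    tibble(from = c(a, b), to = c(b, a),
           direction = c("forward", "backward"),
           mfpt = c(m_f, m_b), rate = 1 / c(m_f, m_b),
           barrier = c(dg_f, dg_b),
           peak_level = c(levels[i] + dg_f, levels[i + 1] + dg_b),
           cycle_residual = resid)
  })
  structure(list(states = states, barriers = barriers,
                 temperature = temperature),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("<free_energy_profile> %d states at %g K\n",
              nrow(x$states), x$temperature))
  print(x$states)
  print(x$barriers[, c("from", "to", "direction", "mfpt", "barrier")])
  invisible(x)
}

#' @export
tidy.free_energy_profile <- function(x, ...) {
  dplyr::left_join(
    x$barriers,
    dplyr::select(x$states, from = "state", from_level = "free_energy"),
    by = "from")
}

#' Order macrostates along a one-dimensional coordinate
#'
#' Ranks macrostates by the stationary-weighted mean of a microstate
#' coordinate (typically tIC-1 of the cluster centres), giving the activation
#' ordering when that coordinate tracks S4 displacement.
#'
#' @param macro A `macrostate_model`.
#' @param centers Microstate centres (rows aligned with the model's active
#'   set), or a vector of one coordinate per microstate.
#' @return Integer permutation of macrostates along increasing coordinate.
#' @export
order_macrostates <- function(macro, centers) {
  x <- if (is.matrix(centers)) centers[macro$model$active_set, 1] else
    centers[macro$model$active_set]
  pos <- vapply(seq_len(macro$n_macro), function(a) {
    i <- macro$labels == a
    sum(macro$model$pi[i] * x[i]) / sum(macro$model$pi[i])
  }, numeric(1))
  order(pos)
}
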
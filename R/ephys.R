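#' Fit the current-voltage activation relation
#'
#' Nonlinear least-squares fit of
#' \deqn{I = G_{max}(V - V_{rev}) / (1 + \exp(-(V - V_{1/2})/k))}
#' to peak-current records. Initial values are derived from the data
#' (reversal from linear extrapolation of the zero crossing on the falling
#' limb, half-activation from the half-extremum current); a small restart
#' grid over slope and half-activation guesses guards against a poor start.
#' `mode = "per_cell"` (default) fits each replicate separately and averages
#' the parameters, with their SD across cells as spread; `"pooled"` fits all
#' records jointly.
#'
#' @param data Tibble with columns `voltage` (mV), `current`, optional
#'   `replicate` (an [generate_sweeps()] result qualifies). At least 4
#'   distinct voltages spanning the rising phase are required.
#' @param init Optional named list of starting values
#'   (`Gmax`, `Vrev`, `Vhalf`, `slope_k`).
#' @param mode `"per_cell"` or `"pooled"`.
#' @return Object of class `boltzmann_fit` with `params` (tibble of `term`,
#'   `estimate`, `std.error`), `model` ("iv"), `residual_norm`, `converged`,
#'   `mode`, `n`.
#' @export
fit_iv <- function(data, init = NULL, mode = c("per_cell", "pooled")) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  check_iv_data(data)
  fit_bz(data, init, mode, model = "iv")
}

#' Conductance transform of current records
#'
#' Applies `G = (-I * 1000) / (Vrev - V)` element-wise (the factor 1000 is
#' the conventional unit conversion of the source relation and is kept
#' verbatim; the conductance is in units of `1000 * current / mV`). Records
#' at `V = Vrev` are excluded with a warning. Inward (negative) currents
#' below the reversal potential give positive conductance.
#'
#' @param data Tibble with `voltage`, `current`, optional `replicate`.
#' @param Vrev Reversal potential in mV (e.g. the fitted value from
#'   [fit_iv()]).
#' @return Tibble with `voltage`, `conductance`, `replicate`.
#' @export
conductance_transform <- function(data, Vrev) {
  data <- as_tibble(data)
  at_rev <- data$voltage == Vrev
  if (any(at_rev)) {
    warn(sprintf("%d record(s) at V = Vrev excluded from the transform",
                 sum(at_rev)))
    data <- data[!at_rev, , drop = FALSE]
  }
  tibble(voltage = data$voltage,
         conductance = (-data$current * 1000) / (Vrev - data$voltage),
         replicate = if ("replicate" %in% names(data)) data$replicate else 1L)
}

#' Fit the Boltzmann activation curve
#'
#' Three-parameter fit of `G = Gmax / (1 + exp(-(V - Vhalf)/k))` to
#' conductance-voltage records (typically the output of
#' [conductance_transform()]).
#'
#' @param gv Tibble with `voltage`, `conductance`, optional `replicate`.
#' @inheritParams fit_iv
#' @return A `boltzmann_fit` with `model = "activation"`.
#' @export
fit_activation <- function(gv, init = NULL, mode = c("per_cell", "pooled")) {
  mode <- match.arg(mode)
  gv <- as_tibble(gv)
  if (!all(c("voltage", "conductance") %in% names(gv)))
    abort("gv needs `voltage` and `conductance` columns")
  if (length(unique(gv$voltage)) < 4)
    abort("need at least 4 distinct voltages")
  fit_bz(gv, init, mode, model = "activation")
}

check_iv_data <- function(data) {
  if (!all(c("voltage", "current") %in% names(data)))
    abort("data needs `voltage` and `current` columns")
  if (!all(is.finite(data$voltage)) || !all(is.finite(data$current)))
    abort("voltages and currents must be finite")
  if (length(unique(data$voltage)) < 4)
    abort("need at least 4 distinct voltages")
  if (all(data$current == 0))
    abort("all currents are zero; the fit is degenerate")
}

# shared machinery for the two printed curve fits
fit_bz <- function(data, init, mode, model) {
  ycol <- if (model == "iv") "current" else "conductance"
  reps <- if ("replicate" %in% names(data)) data$replicate else rep(1L, nrow(data))
  if (mode == "per_cell" && length(unique(reps)) > 1) {
    fits <- lapply(split(data, reps), function(d)
      fit_bz_single(d, init, model))
    P <- do.call(rbind, lapply(fits, function(f) f$estimate))
    params <- tibble(
      term = colnames(P),
      estimate = colMeans(P),
      std.error = apply(P, 2, sd) / sqrt(nrow(P))
    )
    rn <- sqrt(sum(vapply(fits, function(f) f$residual_norm^2, numeric(1))))
    return(new_boltzmann_fit(params, model, rn, TRUE, "per_cell",
                             nrow(data)))
  }
  f <- fit_bz_single(data, init, model)
  params <- tibble(term = names(f$estimate), estimate = unname(f$estimate),
                   std.error = f$std.error)
  new_boltzmann_fit(params, model, f$residual_norm, f$converged,
                    if (mode == "per_cell") "per_cell" else "pooled",
                    nrow(data))
}

fit_bz_single <- function(data, init, model) {
  V <- data$voltage
  y <- if (model == "iv") data$current else data$conductance
  if (all(y == 0)) abort("all responses are zero; the fit is degenerate")
  start <- default_start(V, y, init, model)
  grid <- restart_grid(start, model)
  last_err <- NULL
  for (s in grid) {
    fit <- tryCatch({
      if (model == "iv") {
        minpack.lm::nlsLM(
          y ~ Gmax * (V - Vrev) / (1 + exp(-(V - Vhalf) / slope_k)),
          start = s, control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ Gmax / (1 + exp(-(V - Vhalf) / slope_k)),
          start = s, control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) {
      est <- stats::coef(fit)
      se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, length(est)))
      return(list(estimate = est, std.error = unname(se[names(est)]),
                  residual_norm = sqrt(sum(stats::resid(fit)^2)),
                  converged = TRUE))
    }
  }
  abort(sprintf("nonlinear fit failed after %d restarts: %s", length(grid),
                conditionMessage(last_err)))
}

default_start <- function(V, y, init, model) {
  peak <- V[which.max(abs(y))]
  half <- V[which.min(abs(abs(y) - max(abs(y)) / 2 ))]
  vhalf0 <- min(half, peak)
  if (model == "iv") {
    # reversal: zero crossing extrapolated from the falling limb
    falling <- V >= peak
    vrev0 <- if (sum(falling) >= 2) {
      cf <- unname(stats::coef(stats::lm(y[falling] ~ V[falling])))
      if (abs(cf[2]) > 1e-12) -cf[1] / cf[2] else max(V) + 40
    } else max(V) + 40
    gmax0 <- max(abs(y)) / max(abs(vhalf0 - vrev0), 1)
    s <- list(Gmax = gmax0, Vrev = vrev0, Vhalf = vhalf0, slope_k = 6)
  } else {
    s <- list(Gmax = max(abs(y)), Vhalf = vhalf0, slope_k = 6)
  }
  if (!is.null(init)) s[names(init)] <- init
  s
}

restart_grid <- function(start, model) {
  out <- list(start)
  for (dk in c(3, 9, 15)) for (dv in c(-20, 0, 20)) {
    s <- start
    s$slope_k <- dk
    s$Vhalf <- start$Vhalf + dv
    out <- c(out, list(s))
  }
  out
}

new_boltzmann_fit <- function(params, model, residual_norm, converged,
                              mode, n) {
  est <- setNames(params$estimate, params$term)
  if (!is.na(est["slope_k"]) && est["slope_k"] == 0)
    abort("degenerate fit: slope_k = 0")
  structure(
    list(params = params, model = model, residual_norm = residual_norm,
         converged = converged, mode = mode, n = n),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s model (%s, n = %d)\n",
              x$model, x$mode, x$n))
  print(x$params)
  invisible(x)
}

#' @export
tidy.boltzmann_fit <- function(x, ...) x$params

#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(model = x$model, mode = x$mode, n = x$n,
         residual_norm = x$residual_norm, converged = x$converged)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  setNames(object$params$estimate, object$params$term)
}

#' Time from stimulus onset to peak current
#'
#' Locates the extremum (largest absolute excursion) of the optionally
#' smoothed current after the stimulus onset. With two equal extrema the
#' earlier one is taken. A trace that is monotone after onset has no
#' interior peak: the result is `NA` with a warning.
#'
#' @param trace Tibble with `time` (ms, uniformly sampled) and `current`,
#'   or a numeric current vector with `dt` supplied.
#' @param stimulus_onset Onset time (same units as `time`).
#' @param smooth_window Moving-average window in samples (default 1 = none).
#' @param dt Sample interval when `trace` is a bare vector.
#' @return Time to peak in trace time units, or `NA` if no peak.
#' @export
time_to_peak <- function(trace, stimulus_onset = 0, smooth_window = 1,
                         dt = 1) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    trace <- tibble(time = (seq_along(trace) - 1) * dt, current = trace)
  }
  trace <- as_tibble(trace)
  if (stimulus_onset < min(trace$time) || stimulus_onset > max(trace$time))
    abort("stimulus_onset lies outside the trace")
  post <- trace[trace$time >= stimulus_onset, ]
  y <- post$current
  if (smooth_window > 1) {
    w <- rep(1 / smooth_window, smooth_window)
    y <- as.numeric(stats::filter(y, w, sides = 2))
    keep <- !is.na(y)
    post <- post[keep, ]; y <- y[keep]
  }
  i <- which.max(abs(y))
  if (i == length(y) || i == 1) {
    warn("no interior peak after onset (monotone trace)")
    return(NA_real_)
  }
  post$time[i] - stimulus_onset
}

#' Single-exponential deactivation tail fit
#'
#' Fits `I(t) = A exp(-(t - t0)/tau) + C` to the tail of a current trace
#' starting at `t_start`. The single-exponential model form is this
#' package's choice of descriptor for deactivation kinetics and is flagged
#' in the output.
#'
#' @param trace Tibble with `time` (ms) and `current`.
#' @param t_start Start of the tail.
#' @return Tibble with `tau_ms`, `amplitude`, `offset`, `residual_norm`,
#'   `model` ("single_exponential").
#' @export
fit_deactivation_tail <- function(trace, t_start = NULL) {
  trace <- as_tibble(trace)
  if (is.null(t_start)) t_start <- trace$time[which.max(abs(trace$current))]
  tail_d <- trace[trace$time >= t_start, ]
  if (nrow(tail_d) < 4) abort("too few samples after t_start")
  t <- tail_d$time - t_start
  y <- tail_d$current
  tau0 <- max(diff(range(t)) / 3, 1e-6)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C,
                           start = list(A = y[1] - y[length(y)],
                                        tau = tau0, C = y[length(y)]))
  cf <- stats::coef(fit)
  tibble(tau_ms = unname(cf["tau"]), amplitude = unname(cf["A"]),
         offset = unname(cf["C"]),
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         model = "single_exponential")
}
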
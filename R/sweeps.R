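#' Specify and generate voltage-clamp I-V sweeps
#'
#' Forward model of the current-voltage relation used throughout the
#' electrophysiology analysis:
#' \deqn{I = G_{max}\,(V - V_{rev}) \,/\, (1 + \exp(-(V - V_{1/2})/k))}
#' evaluated at each test voltage for each replicate, plus additive i.i.d.
#' Gaussian noise. With `noise_sd = 0` the exact curve is returned.
#'
#' @param voltages Test potentials in mV, strictly increasing.
#' @param true_params Named list/vector with `Gmax` (conductance),
#'   `Vrev` (reversal potential, mV), `Vhalf` (half-activation, mV),
#'   `slope_k` (slope factor, mV, non-zero).
#' @param noise_sd Gaussian noise SD in current units.
#' @param n_replicates Replicates (cells) per voltage.
#' @param seed Integer seed.
#' @return `sweep_spec()` an object of class `sweep_spec`;
#'   `generate_sweeps()` a tibble (class `iv_dataset`) with columns
#'   `voltage`, `current`, `replicate`, carrying the generating parameters
#'   in `attr(, "true_params")`.
#' @examples
#' spec <- sweep_spec(seq(-40, 60, 10),
#'                    true_params = list(Gmax = 1, Vrev = 80,
#'                                       Vhalf = 20, slope_k = 6))
#' iv <- generate_sweeps(spec)
#' @export
sweep_spec <- function(voltages, true_params, noise_sd = 0,
                       n_replicates = 1L, seed = 1L) {
  if (any(diff(voltages) <= 0)) abort("voltages must be strictly increasing")
  p <- as.list(true_params)
  need <- c("Gmax", "Vrev", "Vhalf", "slope_k")
  if (!all(need %in% names(p)))
    abort("true_params needs Gmax, Vrev, Vhalf, slope_k")
  if (p$slope_k == 0) abort("slope_k must be non-zero")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(voltages = voltages, true_params = p[need], noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "sweep_spec"
  )
}

#' Boltzmann-gated current-voltage relation
#'
#' @param V Voltage in mV.
#' @param Gmax,Vrev,Vhalf,slope_k Curve parameters (see [sweep_spec()]).
#' @return Current in the units of `Gmax * mV`.
#' @export
iv_current <- function(V, Gmax, Vrev, Vhalf, slope_k) {
  Gmax * (V - Vrev) / (1 + exp(-(V - Vhalf) / slope_k))
}

#' @rdname sweep_spec
#' @param spec A `sweep_spec`.
#' @export
generate_sweeps <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  p <- spec$true_params
  grid <- tidyr::expand_grid(replicate = seq_len(spec$n_replicates),
                             voltage = spec$voltages)
  iv <- withr::with_seed(spec$seed, {
    mu <- iv_current(grid$voltage, p$Gmax, p$Vrev, p$Vhalf, p$slope_k)
    tibble(voltage = grid$voltage,
           current = mu + rnorm(nrow(grid), sd = spec$noise_sd),
           replicate = grid$replicate)
  })
  attr(iv, "true_params") <- p
  class(iv) <- c("iv_dataset", class(iv))
  iv
}
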
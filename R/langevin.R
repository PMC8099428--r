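#' Specify and run overdamped Langevin (Brownian) dynamics
#'
#' `langevin_spec()` bundles a [potential_spec()] with thermodynamic and
#' integration parameters; `generate_langevin()` integrates the overdamped
#' Euler-Maruyama scheme
#' \deqn{x_{t+1} = x_t - (dt/\gamma)\,\nabla U(x_t) +
#'   \sqrt{2\,kT\,dt/\gamma}\;\xi_t,\qquad \xi_t \sim N(0, I)}
#' and returns the positions as a [feature_series()]. This diffusive surrogate
#' reproduces the metastable-kinetics structure (wells, barriers, Boltzmann
#' populations) that the downstream MSM stages consume, standing in for
#' all-atom trajectories of a voltage-sensing domain.
#'
#' The seed fixes the trajectory bit-for-bit: equal specs give identical
#' output.
#'
#' @param potential A [potential_spec()].
#' @param kT Thermal energy in the potential's kT units (so 1 means the
#'   well depths are read directly in units of thermal energy).
#' @param friction Friction coefficient gamma (1/time).
#' @param dt Integration time step.
#' @param n_steps Number of steps (= frames returned).
#' @param x0 Initial position (length = potential dimension).
#' @param seed Integer RNG seed.
#' @return `langevin_spec()` an object of class `langevin_spec`;
#'   `generate_langevin()` a [feature_series()] of positions with
#'   `frame_interval = dt` and the spec recorded in its provenance.
#' @examples
#' pot <- potential_spec(c(-1, 1), depth = 4, width = 0.45)
#' spec <- langevin_spec(pot, dt = 5e-3, n_steps = 1000, x0 = -1, seed = 1)
#' traj <- generate_langevin(spec)
#' @export
langevin_spec <- function(potential, kT = 1, friction = 1, dt = 1e-3,
                          n_steps = 1000L, x0 = NULL, seed = 1L) {
  if (!inherits(potential, "potential_spec"))
    abort("`potential` must be a potential_spec")
  if (dt <= 0) abort("dt must be > 0")
  if (n_steps < 1) abort("n_steps must be >= 1")
  if (friction <= 0) abort("friction must be > 0")
  if (kT < 0) abort("kT must be >= 0")
  if (is.null(x0)) x0 <- spec_center(potential)
  if (length(x0) != potential$dimension)
    abort("x0 length must equal the potential dimension")
  structure(
    list(potential = potential, kT = kT, friction = friction, dt = dt,
         n_steps = as.integer(n_steps), x0 = as.numeric(x0),
         seed = as.integer(seed)),
    class = "langevin_spec"
  )
}

spec_center <- function(potential) potential$centers[1, ]

#' @rdname langevin_spec
#' @param spec A `langevin_spec`.
#' @export
generate_langevin <- function(spec) {
  stopifnot(inherits(spec, "langevin_spec"))
  pot <- spec$potential
  form_code <- if (pot$form == "harmonic") 1L else 0L
  res <- withr::with_seed(spec$seed, {
    langevin_cpp(form_code, pot$centers, pot$depths, pot$widths,
                 pot$confine_center, pot$confine_radius, pot$confine_k,
                 spec$kT, spec$friction, spec$dt, spec$n_steps, spec$x0,
                 min(pot$widths))
  })
  if (isTRUE(res$error)) {
    abort(sprintf(
      "non-finite gradient at step %d, position (%s)",
      res$step, paste(signif(res$position, 6), collapse = ", ")))
  }
  if (isTRUE(res$step_warning)) {
    warn("integration step exceeded 10x the narrowest well width; dt is likely too large")
  }
  pos <- res$positions
  colnames(pos) <- paste0("x", seq_len(ncol(pos)))
  feature_series(pos, frame_interval = spec$dt,
                 provenance = list(generator = "langevin", spec = spec))
}
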
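#' Define a metastable model potential
#'
#' Builds the potential-energy surface on which the Langevin generator runs.
#' The default form is a sum of inverted Gaussians, which places wells and
#' barriers directly and has an analytic gradient everywhere; a single
#' `"harmonic"` well is also available for closed-form checks (equipartition
#' variance, Boltzmann weights).
#'
#' Energies are in kT units and positions in nm, matching the reduced units of
#' the diffusive surrogate dynamics. With `form = "gaussian_wells"` the energy
#' is \deqn{U(x) = -\sum_i d_i \exp(-\|x - c_i\|^2 / (2 w_i^2))}
#' so each well contributes a basin of depth `d_i` at `c_i`; with
#' `form = "harmonic"`, `U(x) = depth/2 * ||x - center||^2` and `depth` is the
#' spring constant in kT/nm^2.
#'
#' @param wells Data frame with one row per well and columns `depth` (kT),
#'   `width` (nm) and either `center` (numeric, 1D) or `center_x`/`center_y`
#'   (2D). A plain numeric vector of centers is accepted for 1D wells of
#'   common depth/width via `depth` and `width` arguments.
#' @param depth,width Recycled defaults used when `wells` is a numeric vector
#'   of centers.
#' Because inverted Gaussians flatten out at infinity, the
#' `"gaussian_wells"` form adds a flat-bottom harmonic confinement beyond
#' `confine_radius` of the well centroid (per coordinate): without it the
#' dynamics would leak into the unbound region and the well-to-well kinetics
#' would not be stationary. The confinement is symmetric, so it does not
#' perturb the relative Boltzmann weights of the wells.
#'
#' @param form `"gaussian_wells"` (default) or `"harmonic"`.
#' @param confine_radius Half-width of the flat-bottom region, measured from
#'   the centroid of the well centers; default: farthest center distance
#'   plus 3 times the largest width.
#' @param confine_k Spring constant of the confinement wall (kT/nm^2).
#' @return An object of class `potential_spec`.
#' @examples
#' pot <- potential_spec(c(-1, 1), depth = 4.5, width = 0.45)
#' potential_energy(pot, c(-1, 0, 1))
#' @export
potential_spec <- function(wells, depth = 4, width = 0.5,
                           form = c("gaussian_wells", "harmonic"),
                           confine_radius = NULL, confine_k = 50) {
  form <- match.arg(form)
  if (is.numeric(wells)) {
    wells <- tibble(center = as.numeric(wells), depth = depth, width = width)
  }
  wells <- as_tibble(wells)
  if (nrow(wells) < 1) abort("a potential needs at least one well")
  if (!"depth" %in% names(wells)) wells$depth <- depth
  if (!"width" %in% names(wells)) wells$width <- width
  if (any(wells$width <= 0)) abort("well widths must be > 0")
  if (form == "harmonic" && nrow(wells) != 1)
    abort("a harmonic potential has exactly one well")
  centers <- if ("center" %in% names(wells)) {
    matrix(wells$center, ncol = 1)
  } else if (all(c("center_x", "center_y") %in% names(wells))) {
    cbind(wells$center_x, wells$center_y)
  } else {
    abort("wells need a `center` column (1D) or `center_x`/`center_y` (2D)")
  }
  centroid <- colMeans(centers)
  if (is.null(confine_radius)) {
    confine_radius <- max(sqrt(rowSums(sweep(centers, 2, centroid)^2))) +
      3 * max(wells$width)
  }
  structure(
    list(dimension = ncol(centers), centers = centers,
         depths = wells$depth, widths = wells$width, form = form,
         confine_center = centroid, confine_radius = confine_radius,
         confine_k = if (form == "harmonic") 0 else confine_k),
    class = "potential_spec"
  )
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("<potential_spec> %s, %dD, %d well(s)\n",
              x$form, x$dimension, nrow(x$centers)))
  invisible(x)
}

#' Evaluate a model potential and its gradient
#'
#' @param spec A [potential_spec()].
#' @param x Positions: a numeric vector (1D spec) or a matrix with one row per
#'   position.
#' @return `potential_energy()` returns energies in kT; `potential_gradient()`
#'   a matrix of gradients (kT/nm).
#' @export
potential_energy <- function(spec, x) {
  x <- as_position_matrix(spec, x)
  if (spec$form == "harmonic") {
    d2 <- rowSums(sweep(x, 2, spec$centers[1, ])^2)
    return(0.5 * spec$depths[1] * d2)
  }
  u <- numeric(nrow(x))
  for (i in seq_len(nrow(spec$centers))) {
    d2 <- rowSums(sweep(x, 2, spec$centers[i, ])^2)
    u <- u - spec$depths[i] * exp(-d2 / (2 * spec$widths[i]^2))
  }
  if (spec$confine_k > 0) {
    exc <- abs(sweep(x, 2, spec$confine_center)) - spec$confine_radius
    exc[exc < 0] <- 0
    u <- u + 0.5 * spec$confine_k * rowSums(exc^2)
  }
  u
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(spec, x) {
  x <- as_position_matrix(spec, x)
  if (spec$form == "harmonic") {
    return(spec$depths[1] * sweep(x, 2, spec$centers[1, ]))
  }
  g <- matrix(0, nrow(x), spec$dimension)
  for (i in seq_len(nrow(spec$centers))) {
    dx <- sweep(x, 2, spec$centers[i, ])
    w2 <- spec$widths[i]^2
    e <- spec$depths[i] * exp(-rowSums(dx^2) / (2 * w2)) / w2
    g <- g + dx * e
  }
  if (spec$confine_k > 0) {
    dxc <- sweep(x, 2, spec$confine_center)
    exc <- abs(dxc) - spec$confine_radius
    exc[exc < 0] <- 0
    g <- g + spec$confine_k * sign(dxc) * exc
  }
  g
}

as_position_matrix <- function(spec, x) {
  if (is.null(dim(x))) {
    x <- if (spec$dimension == 1) matrix(x, ncol = 1) else matrix(x, nrow = 1)
  }
  if (ncol(x) != spec$dimension)
    abort(sprintf("positions have %d columns but the potential is %dD",
                  ncol(x), spec$dimension))
  x
}
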
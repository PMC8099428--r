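# Langevin generator and I-V sweep generator: ground-truth checks against
# closed-form stationary statistics and the printed curve equations.

test_that("zero temperature on a flat potential leaves the particle in place", {
  pot <- potential_spec(tibble::tibble(center = 1, depth = 0, width = 1))
  spec <- langevin_spec(pot, kT = 0, dt = 1e-3, n_steps = 500, x0 = 1, seed = 1)
  traj <- generate_langevin(spec)
  expect_true(all(traj$values[, 1] == 1))
})

test_that("harmonic well reproduces the equipartition variance", {
  # U = kappa x^2 / 2, stationary var = kT / kappa
  pot <- potential_spec(tibble::tibble(center = 0, depth = 2, width = 1),
                        form = "harmonic")
  spec <- langevin_spec(pot, kT = 1.5, friction = 1, dt = 0.01,
                        n_steps = 3e5, x0 = 0, seed = 42)
  x <- generate_langevin(spec)$values[, 1]
  expect_equal(var(x), 1.5 / 2, tolerance = 0.05)
})

test_that("symmetric double well splits time evenly between wells", {
  pot <- potential_spec(c(-1, 1), depth = 3, width = 0.45)
  spec <- langevin_spec(pot, kT = 1, dt = 0.005, n_steps = 1e6, x0 = -1,
                        seed = 7)
  x <- generate_langevin(spec)$values[, 1]
  frac_left <- mean(x < 0)
  # tolerance from the effective sample size: ~1 independent draw per
  # well-to-well transition
  core <- ifelse(x > 0.5, 1L, ifelse(x < -0.5, -1L, NA_integer_))
  core <- core[!is.na(core)]
  n_trans <- sum(diff(core) != 0)
  expect_gt(n_trans, 30)
  expect_lt(abs(frac_left - 0.5), 3 * 0.5 / sqrt(n_trans))
})

test_that("equal seeds give bit-identical trajectories", {
  pot <- potential_spec(c(-1, 1), depth = 4, width = 0.5)
  spec <- langevin_spec(pot, dt = 0.005, n_steps = 2000, x0 = 0, seed = 99)
  expect_identical(generate_langevin(spec)$values,
                   generate_langevin(spec)$values)
})

test_that("long-run well populations follow Boltzmann ratios across barrier heights", {
  # asymmetric wells at three depth gaps; oracle = numerical integration of
  # exp(-U/kT) over each basin
  for (gap in c(0.5, 1.0, 1.5)) {
    pot <- potential_spec(tibble::tibble(center = c(-1, 1),
                                         depth = c(3 + gap, 3),
                                         width = 0.45))
    spec <- langevin_spec(pot, kT = 1, dt = 0.005, n_steps = 2e6, x0 = -1,
                          seed = 100 + round(10 * gap))
    x <- generate_langevin(spec)$values[, 1]
    U <- function(z) potential_energy(pot, z)
    sep <- stats::optimize(U, c(-0.9, 0.9), maximum = TRUE)$maximum
    zl <- stats::integrate(function(z) exp(-U(z)), -4, sep)$value
    zr <- stats::integrate(function(z) exp(-U(z)), sep, 4)$value
    dG_true <- -log(zr / zl)
    dG_obs <- -log(mean(x > sep) / mean(x < sep))
    core <- ifelse(x > sep + 0.4, 1L, ifelse(x < sep - 0.4, -1L, NA_integer_))
    core <- core[!is.na(core)]
    n_trans <- sum(diff(core) != 0)
    expect_gt(n_trans, 30)
    # log-ratio SE ~ 2/sqrt(n_trans); allow 3 SE
    expect_lt(abs(dG_obs - dG_true), 3 * 2 / sqrt(n_trans))
  }
})

test_that("langevin and potential specs validate their inputs", {
  pot <- potential_spec(c(0, 1))
  expect_error(potential_spec(tibble::tibble(center = 0, depth = 1,
                                             width = -1)), "width")
  expect_error(langevin_spec(pot, dt = 0), "dt")
  expect_error(langevin_spec(pot, n_steps = 0), "n_steps")
  expect_error(langevin_spec(pot, x0 = c(1, 2)), "x0")
  expect_warning(
    generate_langevin(langevin_spec(pot, kT = 500, dt = 0.5, n_steps = 50,
                                    x0 = 0, seed = 1)),
    "dt is likely too large")
})

test_that("sweep generator evaluates the printed I-V equation exactly", {
  spec <- sweep_spec(seq(-40, 60, 10), iv_true)
  iv <- generate_sweeps(spec)
  # midpoint: logistic = 1/2
  expect_equal(iv$current[iv$voltage == 20], 1 * (20 - 80) / 2)
  expect_equal(iv$current[iv$voltage == 20], -30)
  # driving force vanishes at the reversal potential
  spec2 <- sweep_spec(c(0, 40, 79.9, 79.99, 79.999), iv_true)
  iv2 <- generate_sweeps(spec2)
  expect_lt(abs(iv2$current[iv2$voltage == 79.999]), 1e-2)
  # noise-free is exact for every voltage
  expect_equal(iv$current,
               iv_current(iv$voltage, 1, 80, 20, 6))
})

test_that("sweep specs validate and reproduce under a seed", {
  expect_error(sweep_spec(c(0, 0, 10), iv_true), "strictly increasing")
  expect_error(sweep_spec(c(0, 10), list(Gmax = 1, Vrev = 80, Vhalf = 0,
                                         slope_k = 0)), "slope_k")
  spec <- sweep_spec(seq(-40, 60, 20), iv_true, noise_sd = 0.5,
                     n_replicates = 3, seed = 5)
  expect_identical(generate_sweeps(spec), generate_sweeps(spec))
})
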
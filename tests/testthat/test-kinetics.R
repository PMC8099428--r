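# MFPT solver, state free energies, TST barrier inversion, profile assembly.

two_state_model <- function(p, q, lag = 1L, dt = 1) {
  T <- matrix(c(1 - p, p, q, 1 - q), 2, 2, byrow = TRUE)
  pi_v <- c(q, p) / (p + q)
  structure(list(T = T, pi = pi_v, lag = lag, frame_interval = dt,
                 active_set = 1:2, residuals = list()),
            class = "markov_model")
}

test_that("MFPT matches the geometric waiting-time closed form", {
  m <- two_state_model(0.1, 0.25)
  expect_equal(mfpt(m, 1, 2), 1 / 0.1, tolerance = 1e-12)
  expect_equal(mfpt(m, 2, 1), 1 / 0.25, tolerance = 1e-12)
  expect_equal(mfpt(m, 1, 1), 0)
  # physical units scale with lag * frame_interval
  m2 <- two_state_model(0.1, 0.25, lag = 5L, dt = 0.2)
  expect_equal(mfpt(m2, 1, 2), 5 * 0.2 / 0.1, tolerance = 1e-12)
})

test_that("MFPT respects symmetry on a 3-state ring", {
  T <- matrix(c(0.8, 0.1, 0.1,
                0.1, 0.8, 0.1,
                0.1, 0.1, 0.8), 3, 3, byrow = TRUE)
  m <- structure(list(T = T, pi = rep(1 / 3, 3), lag = 1L,
                      frame_interval = 1, active_set = 1:3,
                      residuals = list()), class = "markov_model")
  expect_equal(mfpt(m, 1, 2), mfpt(m, 2, 3), tolerance = 1e-12)
  expect_equal(mfpt(m, 1, 3), mfpt(m, 3, 1), tolerance = 1e-12)
})

test_that("MFPT guards unreachable targets and bad sets", {
  m <- two_state_model(0.1, 0.2)
  expect_error(mfpt(m, integer(0), 2), "non-empty")
  expect_error(mfpt(m, 1, 3), "outside")
  T_abs <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  m_abs <- structure(list(T = T_abs, pi = c(1, 0) + c(0, 1e-12), lag = 1L,
                          frame_interval = 1, active_set = 1:2,
                          residuals = list()), class = "markov_model")
  expect_error(mfpt(m_abs, 1, 2), "unreachable")
})

test_that("the direct counting MFPT estimator agrees with the chain solution", {
  m <- two_state_model(0.05, 0.1)
  x <- simulate_chain(m$T, 2e5, seed = 31)
  emp <- empirical_mfpt(list(x), 1, 2)
  expect_equal(emp$mfpt, 1 / 0.05, tolerance = 0.1)
  emp_b <- empirical_mfpt(list(x), 2, 1)
  expect_equal(emp_b$mfpt, 1 / 0.1, tolerance = 0.1)
})

test_that("state free energies follow -RT log(weight) with a zero minimum", {
  g_eq <- state_free_energies(rep(0.25, 4))
  expect_true(all(g_eq$free_energy == 0))
  g <- state_free_energies(c(0.9, 0.1), temperature = 300)
  expect_equal(g$free_energy[2] - g$free_energy[1], 5.48062248358486,
               tolerance = 1e-10)
  expect_equal(state_free_energies(c(1.8, 0.2))$free_energy,
               state_free_energies(c(0.9, 0.1))$free_energy,
               tolerance = 1e-12)
  expect_error(state_free_energies(c(0.5, 0)), "positive")
})

test_that("TST inversion satisfies its identities", {
  nu <- vsdkinetics:::kbt_over_h(300)
  expect_warning(b0 <- tst_barrier(nu, 300), "barrierless")
  expect_equal(b0, 0)
  # round trip to 1e-12 relative
  for (k in c(1e3, 1e6, 1e9)) {
    expect_equal(tst_rate(tst_barrier(k, 310), 310), k,
                 tolerance = 1e-12)
  }
  # pinned oracle: 1/us rate at 300 K (independent CODATA computation)
  expect_equal(tst_barrier(1e6, 300), 39.0320362188897, tolerance = 1e-10)
  # strictly decreasing in rate
  rates <- 10^seq(0, 10, length.out = 20)
  expect_true(all(diff(tst_barrier(rates, 300)) < 0))
  expect_error(tst_barrier(0), "rate_k")
})

test_that("profile assembly is symmetric for a symmetric system and orders states", {
  # symmetric 2-macrostate system built by hand
  bc <- block_chain(c(3, 3), eps = 1e-3)
  e <- eigen(t(bc$T))
  piv <- Re(e$vectors[, which.max(Re(e$values))]); piv <- piv / sum(piv)
  m <- estimate_reversible(1e6 * (piv * bc$T))
  mac <- pcca_plus(m, 2)
  kin <- kinetics_table(mac)
  expect_true(all(kin$mfpt[kin$from != kin$to] > 0))
  expect_true(all(kin$mfpt[kin$from == kin$to] == 0))
  kin_s <- kin; kin_s$mfpt <- kin$mfpt * 1e-6
  prof <- build_profile(mac, kin_s, temperature = 300)
  fwd <- prof$barriers$barrier[prof$barriers$direction == "forward"]
  bwd <- prof$barriers$barrier[prof$barriers$direction == "backward"]
  expect_equal(fwd, bwd, tolerance = 0.02)
  expect_equal(min(prof$states$free_energy), 0)
  # cycle diagnostic closes for a 2-state system up to estimator noise
  expect_lt(max(prof$barriers$cycle_residual), 0.1)
})

test_that("the most populated state sits at zero free energy in the profile", {
  # 4 planted states, the last (activated) most populated
  sizes <- c(2, 2, 2, 2)
  bc <- block_chain(sizes, eps = 5e-3)
  S <- matrix(5e-3, 8, 8)
  for (b in 1:4) S[which(bc$block == b), which(bc$block == b)] <- b  # deeper later blocks
  diag(S) <- diag(S) + 4
  T <- S / rowSums(S)
  e <- eigen(t(T)); piv <- Re(e$vectors[, which.max(Re(e$values))])
  piv <- piv / sum(piv)
  m <- estimate_reversible(1e6 * (piv * T))
  mac <- pcca_plus(m, 4)
  kin <- kinetics_table(mac); kin$mfpt <- kin$mfpt * 1e-6
  ordering <- order(mac$weights)  # activated (most populated) last
  prof <- build_profile(mac, kin, ordering = ordering, temperature = 300)
  expect_equal(prof$states$name[4], "activated")
  expect_equal(prof$states$free_energy[4], 0)
  expect_true(all(prof$states$free_energy[1:3] > 0))
})

test_that("profile validation rejects bad orderings", {
  bc <- block_chain(c(3, 3), eps = 1e-3)
  e <- eigen(t(bc$T))
  piv <- Re(e$vectors[, which.max(Re(e$values))]); piv <- piv / sum(piv)
  mac <- pcca_plus(estimate_reversible(1e6 * (piv * bc$T)), 2)
  kin <- kinetics_table(mac)
  expect_error(build_profile(mac, kin, ordering = c(1, 1)), "exactly once")
})

test_that("deepening a well lowers its free energy and slows escape", {
  # Kramers-like monotonicity through the full generator + MSM route
  escape <- function(depth_gap, seed) {
    pot <- potential_spec(tibble::tibble(center = c(-1, 1),
                                         depth = c(3 + depth_gap, 3),
                                         width = 0.45))
    spec <- langevin_spec(pot, kT = 1, dt = 0.005, n_steps = 1e6, x0 = -1,
                          seed = seed)
    x <- generate_langevin(spec)$values[, 1]
    lab <- ifelse(x < 0, 1L, 2L)
    empirical_mfpt(list(lab), 1, 2, frame_interval = 0.005,
                   stride = 50)$mfpt
  }
  t_shallow <- escape(0, 41)
  t_deep <- escape(1.2, 42)
  expect_gt(t_deep, t_shallow)
})
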
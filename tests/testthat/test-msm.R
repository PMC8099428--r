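# Microstate clustering, transition counting, connectivity, the reversible
# MLE (against brute-force oracles), implied timescales, and the CK test.

test_that("k-means microstates honour the basic contracts", {
  withr::with_seed(1, X <- matrix(rnorm(300), ncol = 1))
  a1 <- kmeans_microstates(X, k = 1, seed = 2)
  expect_true(all(a1$labels[[1]] == 1))
  expect_equal(as.numeric(a1$centers), mean(X), tolerance = 1e-12)
  # three well-separated blobs are recovered up to permutation
  withr::with_seed(3, {
    B <- rbind(matrix(rnorm(200, 0), ncol = 2),
               matrix(rnorm(200, 10), ncol = 2),
               matrix(rnorm(200, -10), ncol = 2))
  })
  truth <- rep(1:3, each = 100)
  a3 <- kmeans_microstates(B, k = 3, seed = 4)
  tab <- table(truth, a3$labels[[1]])
  expect_equal(sum(apply(tab, 1, max)), 300)  # perfect agreement
  # determinism
  b3 <- kmeans_microstates(B, k = 3, seed = 4)
  expect_identical(a3$labels, b3$labels)
})

test_that("sliding-window counting matches hand counts and is additive", {
  cm <- count_transitions(list(c(1L, 2L, 1L, 2L)), lag = 1, k = 2)
  expect_equal(cm$C, matrix(c(0, 1, 2, 0), 2, 2))  # (1,2):2, (2,1):1
  expect_equal(sum(cm$C), 3)
  cm2 <- count_transitions(list(c(1L, 2L, 1L, 2L)), lag = 3, k = 2)
  expect_equal(sum(cm2$C), 1)
  a <- c(1L, 1L, 2L); b <- c(2L, 1L, 1L, 2L)
  expect_equal(count_transitions(list(a, b), lag = 1, k = 2)$C,
               count_transitions(list(a), lag = 1, k = 2)$C +
                 count_transitions(list(b), lag = 1, k = 2)$C)
  expect_error(count_transitions(list(c(1L, 2L)), lag = 5), "lag")
})

test_that("largest strongly connected set follows the graph definition", {
  C_full <- matrix(1, 3, 3)
  expect_equal(largest_connected_set(C_full)$active_set, 1:3)
  C_block <- matrix(0, 5, 5)
  C_block[1:3, 1:3] <- 10
  C_block[4:5, 4:5] <- 1
  lcs <- largest_connected_set(C_block)
  expect_equal(lcs$active_set, 1:3)
  expect_equal(lcs$fraction_states, 3 / 5)
  expect_equal(lcs$fraction_counts, 90 / 94)
  C_chain <- matrix(0, 3, 3)
  C_chain[1, 2] <- 1; C_chain[2, 3] <- 1
  diag(C_chain) <- 1
  expect_equal(length(largest_connected_set(C_chain)$active_set), 1)
})

test_that("reversible MLE fixed point matches its oracles", {
  # symmetric counts are already reversible: T = row-normalised C
  Cs <- matrix(c(8, 2, 2, 8), 2, 2)
  m <- estimate_reversible(Cs)
  expect_equal(m$T, Cs / rowSums(Cs), tolerance = 1e-10)
  # any 2-state chain satisfies detailed balance, so the constrained MLE
  # equals the unconstrained row-normalised estimate
  C2 <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE)
  m2 <- estimate_reversible(C2)
  expect_equal(m2$T, C2 / rowSums(C2), tolerance = 1e-8)
  # 3-state brute force: maximise the likelihood over the symmetric flux
  # parametrisation with constrained optimisation
  withr::with_seed(8, C3 <- matrix(rpois(9, 20) + 1, 3, 3))
  nll <- function(theta) {
    S <- matrix(0, 3, 3)
    S[upper.tri(S, diag = TRUE)] <- exp(theta)
    S <- S + t(S) - diag(diag(S))
    T <- S / rowSums(S)
    -sum(C3 * log(T))
  }
  opt <- stats::optim(rep(0, 6), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  S <- matrix(0, 3, 3)
  S[upper.tri(S, diag = TRUE)] <- exp(opt$par)
  S <- S + t(S) - diag(diag(S))
  T_oracle <- S / rowSums(S)
  m3 <- estimate_reversible(C3)
  expect_equal(m3$T, T_oracle, tolerance = 1e-6)
})

test_that("every reversible estimate satisfies the model invariants", {
  withr::with_seed(10, {
    for (i in 1:5) {
      k <- sample(3:8, 1)
      C <- matrix(rpois(k * k, 5), k, k) + 1
      m <- estimate_reversible(C)
      expect_lt(max(abs(rowSums(m$T) - 1)), 1e-10)
      expect_lt(max(abs(m$pi * m$T - t(m$pi * m$T))), 1e-8)
      expect_lt(max(abs(crossprod(m$T, m$pi) - m$pi)), 1e-8)
      expect_true(all(m$pi > 0))
      ev <- vsdkinetics:::msm_eigenvalues(m)
      expect_true(all(abs(ev) <= 1 + 1e-10))
    }
  })
  C_disc <- matrix(0, 4, 4)
  C_disc[1:2, 1:2] <- 5; C_disc[3:4, 3:4] <- 5
  expect_error(estimate_reversible(C_disc), "largest_connected_set")
})

test_that("re-estimation from simulated chains converges ~1/sqrt(n)", {
  bc <- block_chain(c(3, 3), eps = 0.05)
  errs <- vapply(c(2e3, 2e4, 2e5), function(n) {
    x <- simulate_chain(bc$T, n, seed = 13)
    m <- estimate_msm(list(x), 1)
    max(abs(m$T - bc$T))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.01)
})

test_that("implied timescales match the 2-state closed form and stay flat for Markov data", {
  # exact model via symmetric counts: T = [[.8,.2],[.2,.8]], lambda2 = 0.6
  m <- estimate_reversible(matrix(c(8, 2, 2, 8), 2, 2))
  ev <- vsdkinetics:::msm_eigenvalues(m)
  expect_equal(ev[2], 0.6, tolerance = 1e-12)
  expect_equal(vsdkinetics:::implied_ts(ev[2], 1), -1 / log(0.6),
               tolerance = 1e-10)
  # negative eigenvalue -> undefined timescale
  expect_true(is.na(vsdkinetics:::implied_ts(-0.2, 1)))
  # flat in lag on data simulated from a Markov chain
  bc <- block_chain(c(4, 4), eps = 0.02)
  x <- simulate_chain(bc$T, 2e5, seed = 14)
  its <- implied_timescales(list(x), lags = c(1, 2, 4, 8), n_timescales = 1)
  t1 <- its$timescale[its$index == 1]
  expect_lt(max(t1) / min(t1), 1.2)
})

test_that("the CK test passes Markovian data and flags heavy-tailed dwell times", {
  bc <- block_chain(c(4, 4), eps = 0.01)
  x <- simulate_chain(bc$T, 1.2e5, seed = 15)
  trajs <- split(x, rep(1:30, each = 4000))
  m <- estimate_msm(trajs, 2)
  ck <- ck_test(trajs, m, factors = c(2, 3), n_macro_sets = 2, n_boot = 30,
                seed = 3)
  expect_true(ck$pass)
  # factor 1 reference rows agree by definition
  f1 <- ck$results[ck$results$factor == 1, ]
  expect_equal(f1$predicted, f1$estimated, tolerance = 1e-10)
  # semi-Markov process with Pareto dwell times fails at short lag
  dwell <- function(n, seed) withr::with_seed(seed, ceiling(1 / runif(n)^(1 / 1.2)))
  lab <- integer(0); s <- 1L; i <- 0
  repeat {
    i <- i + 1
    lab <- c(lab, rep(s, dwell(1, 100 + i)))
    s <- 3L - s
    if (length(lab) >= 6e4) break
  }
  lab <- lab[1:6e4]
  trajs2 <- split(lab, rep(1:20, each = 3000))
  m2 <- estimate_msm(trajs2, 1)
  ck2 <- ck_test(trajs2, m2, factors = c(3, 5), n_macro_sets = 2,
                 n_boot = 30, seed = 4)
  expect_false(ck2$pass)
})
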
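# tICA estimator: oracle equivalence, recovery of planted slow directions,
# invariances of the projection and free-energy surface.

test_that("i.i.d. noise has no slow components", {
  withr::with_seed(1, {
    X <- matrix(rnorm(20000 * 5), ncol = 5)
  })
  m <- fit_tica(X, lag = 10)
  expect_true(all(abs(m$eigenvalues) < 0.1))
})

test_that("a planted two-state jump process is recovered from a 10D embedding", {
  r <- 0.02  # symmetric flip probability per step
  n <- 50000
  withr::with_seed(5, {
    s <- 2 * (cumsum(runif(n) < r) %% 2) - 1
    u <- rnorm(10); u <- u / sqrt(sum(u^2))
    X <- outer(s, u) + matrix(rnorm(n * 10, sd = 0.3), ncol = 10)
  })
  lag <- 5L
  m <- fit_tica(X, lag = lag)
  v1 <- m$eigenvectors[, 1]
  cosang <- abs(sum(v1 * u)) / sqrt(sum(v1^2))
  expect_gt(cosang, 0.95)
  # oracle: lambda_1 = (1 - 2r)^lag for the symmetric 2-state chain
  expect_equal(m$eigenvalues[1], (1 - 2 * r)^lag, tolerance = 0.1)
  # projection separates the two states almost completely
  y <- project_tica(m, X, n_components = 1)$values[, 1]
  overlap <- min(mean(y[s == 1] < 0), mean(y[s == 1] > 0)) +
    min(mean(y[s == -1] < 0), mean(y[s == -1] > 0))
  expect_lt(overlap, 0.05)
})

test_that("eigenpairs agree with an independent dense generalized eigensolver", {
  withr::with_seed(7, {
    for (d in c(4, 20, 50)) {
      X <- matrix(rnorm(4000 * d), ncol = d) %*%
        (diag(d) + 0.3 * matrix(rnorm(d * d), d, d))
      m <- fit_tica(X, lag = 3)
      # independent route: unsymmetric solve of C0^{-1} Ct on the stored
      # covariance pair
      C0r <- m$C0 + diag(m$regularization, d)
      e <- eigen(solve(C0r, m$Ct))
      lam <- Re(e$values)
      ord <- order(lam, decreasing = TRUE)
      expect_lt(max(abs(m$eigenvalues - lam[ord])), 1e-8)
      V <- Re(e$vectors)[, ord, drop = FALSE]
      for (j in seq_len(min(3, d))) {
        a <- m$eigenvectors[, j]; b <- V[, j]
        expect_lt(1 - abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1e-8)
      }
    }
  })
})

test_that("projection honours the normalization and mean contracts", {
  withr::with_seed(2, X <- matrix(rnorm(5000 * 3), ncol = 3))
  m <- fit_tica(X, lag = 2)
  y <- project_tica(m, X, n_components = m$n_components)$values
  # unit C0-variance of component 1 (biased/symmetrised estimator; loose tol)
  expect_equal(var(y[, 1]), 1, tolerance = 0.01)
  y0 <- project_tica(m, matrix(m$mean, nrow = 1))$values
  expect_true(all(abs(y0) < 1e-10))
  expect_error(project_tica(m, matrix(0, 2, 5)), "dimension")
})

test_that("eigenvalues are invariant under invertible affine feature maps", {
  withr::with_seed(9, {
    X <- matrix(rnorm(8000), ncol = 2)
    X[, 2] <- X[, 2] + 0.5 * dplyr::lag(X[, 1], default = 0)
    A <- matrix(c(2, 0.5, -1, 1.5), 2, 2)
  })
  m1 <- fit_tica(X, lag = 2, regularization = 0)
  m2 <- fit_tica(sweep(X %*% A, 2, c(3, -7), "+"), lag = 2,
                 regularization = 0)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-8)
})

test_that("tICA eigenvalues decay as the lag grows past the relaxation time", {
  r <- 0.05
  withr::with_seed(12, {
    s <- 2 * (cumsum(runif(30000) < r) %% 2) - 1
    X <- cbind(s + rnorm(30000, sd = 0.2), rnorm(30000))
  })
  lams <- vapply(c(2, 8, 32), function(l)
    fit_tica(X, lag = l)$eigenvalues[1], numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("fit_tica rejects degenerate inputs with instructive errors", {
  X <- matrix(rnorm(200), ncol = 2)
  expect_error(fit_tica(X, lag = 100), "too short")
  Xc <- cbind(X, 0)  # constant feature -> singular C0 without ridge
  expect_error(fit_tica(Xc, lag = 1, regularization = 0), "rank-deficient")
})

test_that("free-energy surface is flat for uniform samples and symmetric for equal wells", {
  withr::with_seed(21, {
    U <- cbind(runif(40000), runif(40000))
  })
  fes_u <- free_energy_surface(U, kT = 1, bins = 10)
  # expected histogram fluctuation: sd(F) ~ kT/sqrt(n_per_bin)
  expect_lt(max(fes_u$F, na.rm = TRUE) - min(fes_u$F, na.rm = TRUE),
            3 * sqrt(100 / 40000) * 3)
  withr::with_seed(22, {
    G <- rbind(cbind(rnorm(20000, -2), rnorm(20000)),
               cbind(rnorm(20000, 2), rnorm(20000)))
  })
  fes_g <- free_energy_surface(G, kT = 1, bins = 21)
  left <- min(fes_g$F[fes_g$xcenters < 0, ], na.rm = TRUE)
  right <- min(fes_g$F[fes_g$xcenters > 0, ], na.rm = TRUE)
  expect_equal(left, right, tolerance = 0.1)
  expect_equal(min(fes_g$F, na.rm = TRUE), 0)
  # density normalization: duplicating every sample changes nothing
  fes_2 <- free_energy_surface(rbind(G, G), kT = 1, bins = 21)
  expect_equal(fes_g$F, fes_2$F)
  expect_warning(free_energy_surface(matrix(rnorm(20), 10, 2), bins = 50),
                 "unreliable")
})
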
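#' Time-lagged independent component analysis
#'
#' Finds the linear combinations of input features with maximal
#' autocorrelation at a given lag — the slowest linearly decorrelating
#' coordinates of the dynamics. Estimation uses the symmetrised covariance
#' pair \eqn{C_0} (instantaneous) and \eqn{C_\tau} (time-lagged,
#' \eqn{(\hat C_\tau + \hat C_\tau^T)/2}), which guarantees a real spectrum,
#' and solves the generalised eigenproblem \eqn{C_\tau v = \lambda C_0 v}
#' with a ridge-regularised \eqn{C_0}. Components are ordered by descending
#' eigenvalue; eigenvectors are \eqn{C_0}-orthonormal.
#'
#' Multiple disjoint trajectories are supported: time-lagged pairs are formed
#' within each series only and never straddle a boundary.
#'
#' @param features A [feature_series()], a numeric matrix, or a list of
#'   `feature_series` (disjoint trajectories).
#' @param lag Lag in frames (>= 1).
#' @param n_components Number of components to retain for projection.
#'   Default: smallest m whose cumulative kinetic variance
#'   (sum of squared eigenvalues) reaches 95%.
#' @param regularization Ridge added to the diagonal of `C0`. Default
#'   `1e-6 * trace(C0) / dim`.
#' @return Object of class `tica_model` with fields `lag`, `mean`, `C0`,
#'   `Ct`, `eigenvalues`, `eigenvectors` (columns, C0-orthonormal),
#'   `n_components`, `regularization`, `frame_interval`.
#' @export
fit_tica <- function(features, lag, n_components = NULL,
                     regularization = NULL) {
  series <- as_series_list(features)
  lag <- as.integer(lag)
  if (lag < 1) abort("lag must be >= 1 frame")
  lens <- vapply(series, function(s) nrow(s$values), integer(1))
  if (all(lens <= lag + 1))
    abort("every series is too short for this lag (need length > lag + 1)")
  d <- ncol(series[[1]]$values)
  sum_x <- numeric(d); n_pairs <- 0
  S0 <- matrix(0, d, d); St <- matrix(0, d, d)
  for (s in series) {
    X <- s$values
    n <- nrow(X)
    if (n <= lag) next
    X0 <- X[seq_len(n - lag), , drop = FALSE]
    Xt <- X[(lag + 1):n, , drop = FALSE]
    sum_x <- sum_x + colSums(X0) + colSums(Xt)
    n_pairs <- n_pairs + nrow(X0)
    S0 <- S0 + crossprod(X0) + crossprod(Xt)
    St <- St + crossprod(X0, Xt)
  }
  mu <- sum_x / (2 * n_pairs)
  C0 <- S0 / (2 * n_pairs) - tcrossprod(mu)
  Ct_raw <- St / n_pairs - tcrossprod(mu)
  Ct <- (Ct_raw + t(Ct_raw)) / 2
  if (is.null(regularization)) {
    regularization <- 1e-6 * sum(diag(C0)) / d
  }
  C0r <- C0 + diag(regularization, d)
  U <- tryCatch(chol(C0r), error = function(e) {
    abort("C0 is rank-deficient even after regularization; increase `regularization` or prune redundant features")
  })
  A <- t(solve(U)) %*% Ct %*% solve(U)
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  V <- backsolve(U, eig$vectors)
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  lambda <- eig$values
  if (is.null(n_components)) {
    kv <- cumsum(lambda^2) / sum(lambda^2)
    n_components <- which(kv >= 0.95)[1]
  }
  n_components <- min(as.integer(n_components), d)
  structure(
    list(lag = lag, mean = mu, C0 = C0, Ct = Ct,
         eigenvalues = lambda, eigenvectors = V,
         n_components = n_components, regularization = regularization,
         frame_interval = series[[1]]$frame_interval),
    class = "tica_model"
  )
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> lag %d frames, %d features, %d components retained\n",
              x$lag, length(x$mean), x$n_components))
  cat("  top eigenvalues:",
      paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.tica_model <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         timescale = ifelse(x$eigenvalues > 0 & x$eigenvalues < 1,
                            -x$lag * x$frame_interval / log(x$eigenvalues),
                            NA_real_))
}

#' @export
glance.tica_model <- function(x, ...) {
  tibble(lag_frames = x$lag, n_features = length(x$mean),
         n_components = x$n_components,
         kinetic_variance = sum(head(x$eigenvalues, x$n_components)^2) /
           sum(x$eigenvalues^2),
         regularization = x$regularization)
}

#' Project features onto tICA components
#'
#' Computes `y = V^T (x - mean)` for the retained components.
#'
#' @param model A `tica_model`.
#' @param features Matrix, [feature_series()], or list thereof.
#' @param n_components Override the model's retained-component count.
#' @return A [feature_series()] in tIC coordinates (or a list, matching the
#'   input structure).
#' @export
project_tica <- function(model, features, n_components = NULL) {
  m <- n_components %||% model$n_components
  if (is.list(features) && !inherits(features, "feature_series") &&
      !is.matrix(features)) {
    return(lapply(features, project_tica, model = model, n_components = m))
  }
  single_mat <- is.matrix(features) || is.numeric(features)
  s <- if (single_mat) {
    feature_series(if (is.null(dim(features))) matrix(features, nrow = 1)
                   else features,
                   frame_interval = model$frame_interval)
  } else features
  X <- s$values
  if (ncol(X) != length(model$mean))
    abort(sprintf("feature dimension %d does not match model dimension %d",
                  ncol(X), length(model$mean)))
  Y <- sweep(X, 2, model$mean) %*% model$eigenvectors[, seq_len(m), drop = FALSE]
  colnames(Y) <- paste0("tic", seq_len(m))
  feature_series(Y, frame_interval = s$frame_interval,
                 provenance = list(source = "project_tica", lag = model$lag))
}

#' Free-energy surface over two projected coordinates
#'
#' Bins samples on a 2D grid and converts the histogram density to
#' \eqn{-kT \ln \rho}, shifted so the minimum is 0. Empty bins are undefined
#' (`NA`), not zero.
#'
#' @param projected A [feature_series()] (>= 2 components) or matrix; the
#'   first two columns are used.
#' @param kT Thermal energy in the units the surface should be expressed in.
#' @param bins Number of bins per axis.
#' @return Object of class `fes`: list with `F` (bins x bins matrix, kT
#'   units), `xcenters`, `ycenters`, `xedges`, `yedges`, `kT`.
#' @export
free_energy_surface <- function(projected, kT = 1, bins = 50) {
  X <- if (inherits(projected, "feature_series")) projected$values else
    as.matrix(projected)
  if (ncol(X) < 2) abort("need at least 2 components for a surface")
  n <- nrow(X)
  if (n < bins^2 / 100)
    warn(sprintf("only %d samples for a %dx%d grid; surface is unreliable",
                 n, bins, bins))
  xe <- seq(min(X[, 1]), max(X[, 1]), length.out = bins + 1)
  ye <- seq(min(X[, 2]), max(X[, 2]), length.out = bins + 1)
  ix <- pmin(pmax(findInterval(X[, 1], xe, rightmost.closed = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(X[, 2], ye, rightmost.closed = TRUE), 1), bins)
  H <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = 1:bins), factor(iy, levels = 1:bins))
  H[] <- as.numeric(tab)
  dens <- H / sum(H)
  F <- -kT * log(dens)
  F[!is.finite(F)] <- NA
  F <- F - min(F, na.rm = TRUE)
  structure(
    list(F = F, xcenters = (head(xe, -1) + tail(xe, -1)) / 2,
         ycenters = (head(ye, -1) + tail(ye, -1)) / 2,
         xedges = xe, yedges = ye, kT = kT),
    class = "fes"
  )
}

#' @export
tidy.fes <- function(x, ...) {
  grid <- tidyr::expand_grid(ix = seq_along(x$xcenters),
                             iy = seq_along(x$ycenters))
  tibble(tic1 = x$xcenters[grid$ix], tic2 = x$ycenters[grid$iy],
         free_energy = x$F[cbind(grid$ix, grid$iy)])
}
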
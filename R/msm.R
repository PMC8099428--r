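#' Discretise projected features into microstates by k-means
#'
#' Standard k-means (squared Euclidean) with k-means++ initialisation,
#' deterministic under a fixed seed; the best of `n_init` restarts by inertia
#' is kept. If a restart converges with an empty cluster, that centre is
#' re-seeded from the point farthest from its nearest centre and the restart
#' repeated.
#'
#' For long trajectories the centres are fitted on an evenly spaced
#' subsample of at most `max_fit_frames` frames (deterministic), then every
#' frame is assigned to its nearest centre; with fewer frames than the cap
#' this is exact standard k-means.
#'
#' @param projected A [feature_series()], matrix, or list of series (disjoint
#'   trajectories) in tIC coordinates.
#' @param k Number of microstates (must not exceed the number of frames).
#' @param seed Integer seed controlling initialisation.
#' @param n_init Number of k-means++ restarts.
#' @param max_fit_frames Cap on the number of frames used to fit the centres.
#' @return Object of class `microstate_assignment`: `labels` (list of
#'   integer vectors, one per trajectory, values in 1..k), `centers`
#'   (k x d), `k`, `seed`, `inertia`, `frame_interval`.
#' @export
kmeans_microstates <- function(projected, k, seed = 1L, n_init = 5L,
                               max_fit_frames = 2e5) {
  series <- as_series_list(projected)
  X_all <- do.call(rbind, lapply(series, function(s) s$values))
  lens <- vapply(series, function(s) nrow(s$values), integer(1))
  if (k > nrow(X_all)) abort("k cannot exceed the number of frames")
  X <- if (nrow(X_all) > max_fit_frames) {
    X_all[seq(1, nrow(X_all), length.out = max_fit_frames), , drop = FALSE]
  } else X_all
  if (k == 1) {
    labels <- split(rep(1L, nrow(X_all)), rep(seq_along(lens), lens))
    names(labels) <- NULL
    return(structure(
      list(labels = labels, centers = matrix(colMeans(X_all), 1),
           k = 1L, seed = as.integer(seed),
           inertia = sum(sweep(X_all, 2, colMeans(X_all))^2),
           frame_interval = series[[1]]$frame_interval),
      class = "microstate_assignment"))
  }
  fit <- withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(n_init)) {
      centers <- kmeanspp_init(X, k)
      km <- NULL
      for (attempt in 1:5) {
        km <- tryCatch(
          suppressWarnings(kmeans(X, centers = centers, iter.max = 100)),
          error = function(e) NULL)
        if (!is.null(km) && all(km$size > 0)) break
        # re-seed the most redundant centre from the farthest point
        d2 <- nearest_center_dist2(X, centers)
        centers[which.min(rowSums(as.matrix(stats::dist(centers)))), ] <-
          X[which.max(d2), ]
      }
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  if (is.null(fit)) abort("k-means failed to converge on any restart")
  cluster_all <- if (nrow(X) < nrow(X_all)) {
    assign_nearest(X_all, fit$centers)
  } else fit$cluster
  labels <- split(cluster_all, rep(seq_along(lens), lens))
  names(labels) <- NULL
  structure(
    list(labels = lapply(labels, as.integer), centers = fit$centers,
         k = as.integer(k), seed = as.integer(seed),
         inertia = fit$tot.withinss,
         frame_interval = series[[1]]$frame_interval),
    class = "microstate_assignment"
  )
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k == 1) return(centers)
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    # weighted draw by inverse CDF (O(n); sample.int with prob is O(n log n))
    pick <- findInterval(runif(1) * sum(d2), cumsum(d2)) + 1L
    centers[j, ] <- X[min(pick, n), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

assign_nearest <- function(X, centers) {
  best <- rep(1L, nrow(X))
  bestd <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
  for (j in seq_len(nrow(centers))[-1]) {
    d <- rowSums(sweep(X, 2, centers[j, ], "-")^2)
    upd <- d < bestd
    best[upd] <- j
    bestd[upd] <- d[upd]
  }
  best
}

nearest_center_dist2 <- function(X, centers) {
  d2 <- rep(Inf, nrow(X))
  for (j in seq_len(nrow(centers)))
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  d2
}

#' @export
print.microstate_assignment <- function(x, ...) {
  cat(sprintf("<microstate_assignment> %d trajectories, %d frames, k = %d\n",
              length(x$labels), sum(lengths(x$labels)), x$k))
  invisible(x)
}

as_label_list <- function(assignments) {
  if (inherits(assignments, "microstate_assignment")) return(assignments$labels)
  if (is.numeric(assignments)) return(list(as.integer(assignments)))
  if (is.list(assignments)) return(lapply(assignments, as.integer))
  abort("expected a microstate_assignment or label vector(s)")
}

#' Count microstate transitions at a lag
#'
#' Sliding-window counting: every pair `(label_t, label_{t+lag})` within a
#' trajectory increments one entry; trajectories are never concatenated, so
#' no pair straddles a boundary.
#'
#' @param assignments A [kmeans_microstates()] result or list of integer
#'   label vectors (values 1..k).
#' @param lag Lag in frames.
#' @param k Number of states (inferred from the assignment when omitted).
#' @return Object of class `count_matrix`: `C` (k x k), `lag`, `mode`,
#'   `frame_interval`.
#' @export
count_transitions <- function(assignments, lag, k = NULL) {
  labels <- as_label_list(assignments)
  lag <- as.integer(lag)
  if (lag < 1) abort("lag must be >= 1")
  if (all(lengths(labels) <= lag))
    abort("lag is >= every trajectory length; nothing to count")
  if (is.null(k)) {
    k <- if (inherits(assignments, "microstate_assignment")) assignments$k
         else max(unlist(labels))
  }
  C <- matrix(0, k, k)
  for (lab in labels) {
    n <- length(lab)
    if (n <= lag) next
    from <- lab[seq_len(n - lag)]
    to <- lab[(lag + 1):n]
    idx <- (from - 1L) * k + to
    cnt <- tabulate(idx, nbins = k * k)
    C <- C + matrix(cnt, k, k, byrow = TRUE)
  }
  fi <- if (inherits(assignments, "microstate_assignment"))
    assignments$frame_interval else 1
  structure(list(C = C, lag = lag, mode = "sliding", frame_interval = fi),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d states, lag %d, %g counts (%s counting)\n",
              nrow(x$C), x$lag, sum(x$C), x$mode))
  invisible(x)
}

#' Largest strongly connected set of a count matrix
#'
#' The Markov model can only be estimated on a communicating set of states:
#' returns the vertices of the largest strongly connected component of the
#' directed graph with an edge wherever `C[i, j] > 0`, along with the
#' fraction of states and of observed counts that set retains.
#'
#' @param counts A [count_transitions()] result or plain count matrix.
#' @return List with `active_set` (sorted state indices), `fraction_states`,
#'   `fraction_counts`.
#' @export
largest_connected_set <- function(counts) {
  C <- if (inherits(counts, "count_matrix")) counts$C else as.matrix(counts)
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    # tie-break: the component holding the most counts
    wt <- vapply(cand, function(cc) {
      m <- which(comp$membership == cc)
      sum(C[m, m])
    }, numeric(1))
    cand <- cand[which.max(wt)]
  } else {
    cand <- cand[1]
  }
  active <- sort(which(comp$membership == cand))
  list(active_set = active,
       fraction_states = length(active) / nrow(C),
       fraction_counts = if (sum(C) > 0) sum(C[active, active]) / sum(C) else NA_real_)
}

#' Maximum-likelihood reversible Markov model
#'
#' Estimates the transition matrix maximising \eqn{\prod_{ij} T_{ij}^{C_{ij}}}
#' subject to detailed balance, by the standard self-consistent fixed-point
#' iteration on the unnormalised flux matrix \eqn{x_{ij} = \pi_i T_{ij}}:
#' \deqn{x_{ij} \leftarrow \frac{C_{ij} + C_{ji}}{c_i / x_i + c_j / x_j}}
#' with \eqn{c_i = \sum_j C_{ij}}, \eqn{x_i = \sum_j x_{ij}}. Iteration stops
#' when the maximum relative change drops below 1e-10 or after 1e6 sweeps.
#' The stationary distribution is the normalised row sum of `x`.
#'
#' Postconditions asserted on every estimate: rows of T sum to 1 within
#' 1e-10, detailed-balance residual below 1e-8, `pi T = pi` within 1e-8,
#' all stationary weights positive.
#'
#' @param counts A [count_transitions()] result or count matrix, irreducible
#'   on its states (trim with [largest_connected_set()] first).
#' @param active_set Optional indices to restrict to (recorded as the
#'   active-set mapping).
#' @return Object of class `markov_model`: `T`, `pi`, `lag`,
#'   `frame_interval`, `active_set`, `counts`, `residuals`.
#' @export
estimate_reversible <- function(counts, active_set = NULL) {
  cm <- if (inherits(counts, "count_matrix")) counts else
    structure(list(C = as.matrix(counts), lag = 1L, mode = "sliding",
                   frame_interval = 1), class = "count_matrix")
  C <- cm$C
  if (is.null(active_set)) active_set <- seq_len(nrow(C))
  C <- C[active_set, active_set, drop = FALSE]
  lcs <- largest_connected_set(C)
  if (length(lcs$active_set) != nrow(C))
    abort("count matrix is not irreducible on the given states; restrict to largest_connected_set() first")
  k <- nrow(C)
  ci <- rowSums(C)
  x <- C + t(C)
  x <- x / sum(x)
  for (sweep_i in seq_len(1e6)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    x_new <- (C + t(C)) / denom
    x_new <- x_new / sum(x_new)
    delta <- max(abs(x_new - x) / pmax(x, 1e-300))
    x <- x_new
    if (delta < 1e-10) break
  }
  pi_hat <- rowSums(x)
  T_hat <- x / pi_hat
  T_hat <- T_hat / rowSums(T_hat)
  residuals <- list(
    row_sums = max(abs(rowSums(T_hat) - 1)),
    detailed_balance = max(abs(pi_hat * T_hat - t(pi_hat * T_hat))),
    stationarity = max(abs(crossprod(T_hat, pi_hat) - pi_hat))
  )
  if (residuals$row_sums > 1e-10 || residuals$detailed_balance > 1e-8 ||
      residuals$stationarity > 1e-8 || any(pi_hat <= 0)) {
    abort("reversible estimation failed its postconditions; counts may be too sparse")
  }
  structure(
    list(T = T_hat, pi = pi_hat, lag = cm$lag,
         frame_interval = cm$frame_interval,
         active_set = active_set, counts = C, residuals = residuals,
         reversible = TRUE),
    class = "markov_model"
  )
}

#' Estimate a reversible MSM from label sequences (trim + estimate)
#'
#' Convenience wrapper: counts transitions at `lag`, trims to the largest
#' strongly connected set (mandatory before estimation; the retained
#' fractions are recorded), and runs the reversible estimator.
#'
#' @inheritParams count_transitions
#' @return A `markov_model`; the trimming fractions are stored in
#'   `$connectivity`.
#' @export
estimate_msm <- function(assignments, lag, k = NULL) {
  cm <- count_transitions(assignments, lag, k = k)
  lcs <- largest_connected_set(cm)
  model <- estimate_reversible(cm, active_set = lcs$active_set)
  model$connectivity <- lcs[c("fraction_states", "fraction_counts")]
  model
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> %d states, lag %d frames (%g time units), reversible\n",
              nrow(x$T), x$lag, x$lag * x$frame_interval))
  invisible(x)
}

#' @export
tidy.markov_model <- function(x, ...) {
  tibble(state = x$active_set, stationary_weight = x$pi,
         free_energy_kT = -log(x$pi) - min(-log(x$pi)))
}

#' @export
glance.markov_model <- function(x, ...) {
  ev <- msm_eigenvalues(x)
  tibble(n_states = nrow(x$T), lag_frames = x$lag,
         lag_time = x$lag * x$frame_interval,
         slowest_timescale = implied_ts(ev[2], x$lag * x$frame_interval),
         detailed_balance_residual = x$residuals$detailed_balance)
}

# real spectrum of a reversible T via the pi-symmetrised similar matrix
msm_eigenvalues <- function(model, vectors = FALSE) {
  s <- sqrt(model$pi)
  S <- (s * model$T) / rep(s, each = length(s))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (!vectors) return(e$values)
  # right eigenvectors of T: psi = D^{-1/2} u
  psi <- e$vectors / s
  list(values = e$values, right_vectors = psi)
}

implied_ts <- function(lambda, tau) {
  ifelse(is.na(lambda) | lambda <= 0 | lambda >= 1, NA_real_,
         -tau / log(lambda))
}

#' Implied relaxation timescales across lags
#'
#' For each lag, estimates a reversible MSM and converts its leading
#' eigenvalues (excluding the stationary one) to timescales
#' \eqn{t_i(\tau) = -\tau / \ln \lambda_i(\tau)} in physical units.
#' Non-positive eigenvalues give an undefined (`NA`) timescale. For
#' Markovian data the curves are flat in the lag.
#'
#' @param assignments Labels as in [count_transitions()].
#' @param lags Integer vector of lags in frames (>= 2 values).
#' @param n_timescales How many timescales to report per lag.
#' @param k Number of states (inferred when omitted).
#' @return A tibble with columns `lag_frames`, `lag_time`, `index`,
#'   `eigenvalue`, `timescale` (class `implied_timescales`).
#' @export
implied_timescales <- function(assignments, lags, n_timescales = 5, k = NULL) {
  if (length(lags) < 2) abort("need at least 2 lags")
  rows <- purrr::map_dfr(as.integer(lags), function(tau) {
    model <- estimate_msm(assignments, tau, k = k)
    ev <- msm_eigenvalues(model)
    m <- min(n_timescales, length(ev) - 1)
    if (m < 1) return(tibble())
    lam <- ev[2:(m + 1)]
    tibble(lag_frames = tau,
           lag_time = tau * model$frame_interval,
           index = seq_len(m),
           eigenvalue = lam,
           timescale = implied_ts(lam, tau * model$frame_interval))
  })
  class(rows) <- c("implied_timescales", class(rows))
  rows
}
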
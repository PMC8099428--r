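#' Chapman-Kolmogorov test of a Markov state model
#'
#' Checks whether the model estimated at lag \eqn{\tau} propagates correctly
#' to longer times: for each metastable set A and each factor f, the
#' predicted staying probability under \eqn{T(\tau)^f} is compared with the
#' probability under a model re-estimated directly at \eqn{f\tau}. The test
#' passes when every prediction lies inside the bootstrap confidence band of
#' the direct estimate at every factor (trajectory-resampling bootstrap;
#' a single long trajectory is split into blocks before resampling).
#'
#' Markovian data pass by construction; dynamics with non-exponential
#' (e.g. heavy-tailed) dwell times fail detectably at short lags.
#'
#' @param assignments Labels as in [count_transitions()].
#' @param model The `markov_model` estimated at the base lag.
#' @param factors Integer multipliers of the base lag to test (factor 1 is
#'   included for reference; predicted equals estimated there by definition).
#' @param n_macro_sets Number of metastable sets (PCCA+ on `model`).
#' @param n_boot Bootstrap draws for the confidence band.
#' @param conf Band coverage (default 0.95).
#' @param n_blocks Number of blocks a single trajectory is split into before
#'   resampling.
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `ck_test`: tibble `results` (`set`, `factor`,
#'   `predicted`, `estimated`, `lower`, `upper`, `within_band`), logical
#'   `pass`, and the `factors` actually tested (data too short for a factor
#'   are skipped with a warning).
#' @export
ck_test <- function(assignments, model, factors = c(2, 3, 4),
                    n_macro_sets = 2, n_boot = 50, conf = 0.95,
                    n_blocks = 20, seed = 1L) {
  labels <- as_label_list(assignments)
  macro <- pcca_plus(model, n_macro_sets)
  sets_orig <- lapply(seq_len(n_macro_sets), function(a)
    model$active_set[macro$labels == a])
  tau <- model$lag
  max_len <- max(lengths(labels))
  factors <- sort(unique(as.integer(c(1, factors))))
  usable <- factors[factors * tau < max_len]
  if (length(usable) < length(factors))
    warn(sprintf("factors {%s} skipped: insufficient data at that lag",
                 paste(setdiff(factors, usable), collapse = ", ")))
  factors <- usable
  # resampling units: trajectories, or blocks of a single trajectory
  units <- if (length(labels) >= n_blocks) labels else {
    unlist(lapply(labels, function(l) {
      nb <- max(1, min(n_blocks, floor(length(l) / (max(factors) * tau + 1))))
      split(l, cut(seq_along(l), nb, labels = FALSE))
    }), recursive = FALSE)
  }
  stay_prob <- function(Tf, pi_w, active, set_states) {
    A <- match(intersect(set_states, active), active)
    if (length(A) == 0) return(NA_real_)
    w <- pi_w[A] / sum(pi_w[A])
    sum(w * rowSums(Tf[A, A, drop = FALSE]))
  }
  estimate_at <- function(labs, lag_f) {
    cm <- count_transitions(labs, lag_f, k = max(unlist(labs)))
    lcs <- largest_connected_set(cm)
    estimate_reversible(cm, active_set = lcs$active_set)
  }
  results <- purrr::map_dfr(factors, function(f) {
    Tf <- matpow(model$T, f)
    m_est <- estimate_at(labels, f * tau)
    boot <- withr::with_seed(as.integer(seed) + f, {
      replicate(n_boot, {
        draw <- units[sample.int(length(units), replace = TRUE)]
        ok <- tryCatch({
          mb <- estimate_at(draw, f * tau)
          vapply(sets_orig, function(ss)
            stay_prob(mb$T, mb$pi, mb$active_set, ss), numeric(1))
        }, error = function(e) rep(NA_real_, length(sets_orig)))
        ok
      })
    })
    boot <- matrix(boot, nrow = length(sets_orig))
    alpha <- (1 - conf) / 2
    purrr::map_dfr(seq_along(sets_orig), function(a) {
      pred <- stay_prob(Tf, model$pi, model$active_set, sets_orig[[a]])
      est <- stay_prob(m_est$T, m_est$pi, m_est$active_set, sets_orig[[a]])
      qs <- stats::quantile(boot[a, ], c(alpha, 1 - alpha), na.rm = TRUE)
      tibble(set = a, factor = f, predicted = pred, estimated = est,
             lower = unname(qs[1]), upper = unname(qs[2]),
             within_band = pred >= qs[1] & pred <= qs[2])
    })
  })
  structure(
    list(results = results,
         pass = all(results$within_band[results$factor > 1]),
         factors = factors, n_macro_sets = n_macro_sets),
    class = "ck_test"
  )
}

matpow <- function(M, p) {
  out <- diag(nrow(M))
  base <- M
  while (p > 0) {
    if (p %% 2 == 1) out <- out %*% base
    base <- base %*% base
    p <- p %/% 2
  }
  out
}

#' @export
print.ck_test <- function(x, ...) {
  cat(sprintf("<ck_test> %s (factors %s, %d sets)\n",
              if (x$pass) "PASS" else "FAIL",
              paste(x$factors, collapse = ","), x$n_macro_sets))
  print(x$results)
  invisible(x)
}

#' @export
tidy.ck_test <- function(x, ...) x$results
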
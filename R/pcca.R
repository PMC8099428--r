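#' PCCA+ metastable coarse-graining of a Markov model
#'
#' Groups microstates into `n_macro` metastable macrostates from the
#' dominant right eigenvectors of the reversible transition matrix. Rows of
#' the eigenvector matrix are mapped to fuzzy memberships by the inner-simplex
#' construction: the `n_macro` rows spanning the largest simplex are chosen
#' as vertices (successive farthest-point selection with orthogonal
#' deflation), every microstate's membership is its barycentric coordinate
#' with respect to those vertices, and feasibility is restored by clipping
#' at zero and renormalising each row to the simplex. Crisp labels are the
#' argmax memberships.
#'
#' @param model A reversible, irreducible [estimate_reversible()] model.
#' @param n_macro Number of macrostates; must not exceed the number of
#'   positive eigenvalues of the transition matrix.
#' @return Object of class `macrostate_model`: `n_macro`, `chi`
#'   (microstates x macrostates membership matrix, rows on the simplex),
#'   `labels` (crisp), `weights` (macrostate stationary weights
#'   \eqn{\Pi_A = \sum_{i \in A} \pi_i}), `coarse_T`, and the parent `model`.
#' @export
pcca_plus <- function(model, n_macro) {
  stopifnot(inherits(model, "markov_model"))
  n_macro <- as.integer(n_macro)
  k <- nrow(model$T)
  if (n_macro < 1 || n_macro > k)
    abort("n_macro must be between 1 and the number of microstates")
  e <- msm_eigenvalues(model, vectors = TRUE)
  if (sum(e$values > 0) < n_macro)
    abort("n_macro exceeds the number of positive transition-matrix eigenvalues")
  if (n_macro < k &&
      abs(e$values[n_macro] - e$values[n_macro + 1]) < 1e-6)
    warn("no spectral gap after the requested macrostate count; the choice of n_macro is weakly determined")
  X <- e$right_vectors[, seq_len(n_macro), drop = FALSE]
  X[, 1] <- 1  # stationary eigenvector is constant
  chi <- inner_simplex_memberships(X)
  labels <- max.col(chi, ties.method = "first")
  if (length(unique(labels)) < n_macro)
    abort("a macrostate is empty under crisp assignment; reduce n_macro")
  weights <- vapply(seq_len(n_macro), function(a) sum(model$pi[labels == a]),
                    numeric(1))
  D <- model$pi
  M <- crossprod(chi, D * chi)        # chi' diag(pi) chi
  coarse_T <- solve(M, crossprod(chi, D * (model$T %*% chi)))
  structure(
    list(n_macro = n_macro, chi = chi, labels = labels, weights = weights,
         coarse_T = coarse_T, model = model),
    class = "macrostate_model"
  )
}

# inner-simplex algorithm: vertex selection + barycentric memberships
inner_simplex_memberships <- function(X) {
  k <- nrow(X); m <- ncol(X)
  ind <- integer(m)
  ortho <- X
  d <- rowSums(ortho^2)
  ind[1] <- which.max(d)
  ortho <- sweep(ortho, 2, ortho[ind[1], ])
  if (m > 1) {
    for (j in 2:m) {
      d <- rowSums(ortho^2)
      ind[j] <- which.max(d)
      v <- ortho[ind[j], ]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12)
        abort("degenerate eigenvector geometry; cannot place simplex vertices")
      v <- v / nv
      ortho <- ortho - (ortho %*% v) %*% t(v)
    }
  }
  A <- solve(X[ind, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi / rowSums(chi)
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat(sprintf("<macrostate_model> %d macrostates over %d microstates\n",
              x$n_macro, nrow(x$chi)))
  cat("  weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.macrostate_model <- function(x, ...) {
  tibble(microstate = x$model$active_set,
         macrostate = x$labels,
         membership = x$chi[cbind(seq_len(nrow(x$chi)), x$labels)])
}

#' @export
glance.macrostate_model <- function(x, ...) {
  tibble(n_macro = x$n_macro, n_micro = nrow(x$chi),
         min_weight = min(x$weights),
         crispness = mean(x$chi[cbind(seq_len(nrow(x$chi)), x$labels)]))
}

#' Map frames to macrostates
#'
#' @param macro A [pcca_plus()] result.
#' @param assignments Microstate labels as in [count_transitions()].
#' @return List of integer macrostate label vectors (NA for frames whose
#'   microstate fell outside the model's active set).
#' @export
macrostate_labels <- function(macro, assignments) {
  labels <- as_label_list(assignments)
  lut <- rep(NA_integer_, max(unlist(labels)))
  lut[macro$model$active_set] <- macro$labels
  lapply(labels, function(l) lut[l])
}
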
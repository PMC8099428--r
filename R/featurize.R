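#' Select atoms of a trajectory by metadata predicate
#'
#' The predicate is an ordinary R expression over the columns of the atom
#' table (`name`, `resname`, `resno`, `chain`, plus any extra tags), given
#' either unquoted or as a string (the form used in run-configuration files).
#'
#' @param traj A [trajectory()].
#' @param predicate Expression or string, e.g. `name == "CA" & chain == "S4"`.
#' @return Integer vector of atom indices (class `atom_selection`).
#' @examples
#' \dontrun{
#' sel <- select_atoms(traj, name == "CA")
#' }
#' @export
select_atoms <- function(traj, predicate) {
  stopifnot(inherits(traj, "trajectory"))
  q <- rlang::enquo(predicate)
  if (rlang::quo_is_call(q) || rlang::quo_is_symbol(q)) {
    keep <- rlang::eval_tidy(q, data = traj$atoms)
  } else {
    expr_chr <- rlang::eval_tidy(q)
    if (!is.character(expr_chr)) abort("predicate must be an expression or a string")
    keep <- rlang::eval_tidy(rlang::parse_expr(expr_chr), data = traj$atoms)
  }
  if (!is.logical(keep) || length(keep) != n_atoms(traj))
    abort("predicate must evaluate to one logical per atom")
  idx <- which(keep)
  if (length(idx) == 0) abort("atom selection is empty on this trajectory")
  structure(idx, class = "atom_selection")
}

resolve_selection <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(n_atoms(traj)))
  if (inherits(selection, "atom_selection") || is.numeric(selection)) {
    idx <- as.integer(selection)
    if (length(idx) == 0 || any(idx < 1) || any(idx > n_atoms(traj)))
      abort("selection indices out of range")
    return(idx)
  }
  if (is.character(selection)) {
    keep <- rlang::eval_tidy(rlang::parse_expr(selection), data = traj$atoms)
    idx <- which(keep)
    if (length(idx) == 0) abort("atom selection is empty on this trajectory")
    return(idx)
  }
  abort("selection must be indices, an atom_selection, or a predicate string")
}

#' Root-mean-square deviation between two frames
#'
#' With `superpose = TRUE` an optimal least-squares (Kabsch) superposition of
#' `b` onto `a` precedes the RMSD, which then measures internal-geometry
#' difference only; without it, the raw coordinate deviation. The measure is
#' non-negative and symmetric in its arguments.
#'
#' @param a,b Frames as `atoms x 3` matrices (same atom count).
#' @param superpose Superpose before measuring (default `TRUE`). Requires at
#'   least 3 atoms, otherwise the superposition is underdetermined.
#' @return RMSD in Angstrom.
#' @export
rmsd_frames <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    abort("frames must have the same atom count")
  if (superpose && nrow(a) < 3)
    abort("superposition needs at least 3 atoms")
  as.numeric(bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                         fit = superpose))
}

# all-pairs RMSD matrix over selected atoms
pairwise_rmsd <- function(traj, selection = NULL, superpose = TRUE,
                          max_frames = 4000) {
  idx <- resolve_selection(traj, selection)
  nf <- n_frames(traj)
  if (nf > max_frames)
    abort(sprintf(
      "pairwise RMSD over %d frames exceeds the %d-frame budget; stride the trajectory first",
      nf, max_frames))
  xyz <- traj_xyz(traj)[, as.vector(t(outer(idx, 1:3, function(i, d) 3 * (i - 1) + d))), drop = FALSE]
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    vals <- suppressWarnings(
      bio3d::rmsd(xyz[i, ], xyz[(i + 1):nf, , drop = FALSE], fit = superpose))
    D[i, (i + 1):nf] <- vals
    D[(i + 1):nf, i] <- vals
  }
  D
}

#' Average-linkage RMSD clustering of trajectory frames
#'
#' Agglomerative clustering on the pairwise (superposed) RMSD matrix,
#' merging while the inter-cluster average distance is at or below `cutoff`.
#' This is the seeding-set selection step: each cluster's representative is
#' its medoid (the member with minimal mean RMSD to the rest of the cluster;
#' ties broken toward the lowest frame index).
#'
#' @param traj A [trajectory()].
#' @param selection Atom selection (indices, [select_atoms()] result, or
#'   predicate string); `NULL` means all atoms.
#' @param cutoff Average-linkage merge cutoff in Angstrom.
#' @param superpose Superpose frames before the RMSD (default `TRUE`).
#' @return Object of class `cluster_result` with per-frame `labels`,
#'   `representatives` (medoid frame index per cluster), `linkage`, `cutoff`.
#' @export
cluster_average_linkage <- function(traj, selection = NULL, cutoff,
                                    superpose = TRUE) {
  if (n_frames(traj) < 1) abort("need at least one frame")
  D <- pairwise_rmsd(traj, selection, superpose = superpose)
  if (n_frames(traj) == 1) {
    labels <- 1L
  } else {
    hc <- hclust(stats::as.dist(D), method = "average")
    labels <- cutree(hc, h = cutoff)
  }
  reps <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    members[which.min(rowMeans(D[members, members, drop = FALSE]))]
  }, integer(1))
  structure(
    list(labels = as.integer(labels), representatives = reps,
         linkage = "average", cutoff = cutoff,
         n_clusters = length(reps)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d frames -> %d clusters (%s linkage, cutoff %g A)\n",
              length(x$labels), x$n_clusters, x$linkage, x$cutoff))
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(frame = seq_along(x$labels), cluster = x$labels,
         is_representative = seq_along(x$labels) %in% x$representatives)
}

#' Extract per-frame coordinate features from a trajectory
#'
#' Flattens the selected atoms' coordinates into a frames x (3 n_selected)
#' matrix in atom-major order (x, y, z of atom 1, then atom 2, ...) — the
#' feature set on which tICA and microstate clustering operate, e.g. the
#' C-alpha coordinates of an S4 helix.
#'
#' @inheritParams cluster_average_linkage
#' @return A [feature_series()] with the trajectory's `frame_interval`.
#' @export
extract_features <- function(traj, selection = NULL) {
  idx <- resolve_selection(traj, selection)
  nf <- n_frames(traj)
  mat <- matrix(0, nf, 3 * length(idx))
  for (j in seq_along(idx)) {
    mat[, 3 * j - 2] <- traj$coords[, idx[j], 1]
    mat[, 3 * j - 1] <- traj$coords[, idx[j], 2]
    mat[, 3 * j]     <- traj$coords[, idx[j], 3]
  }
  colnames(mat) <- as.vector(t(outer(idx, c("x", "y", "z"),
                                     function(i, d) paste0("atom", i, "_", d))))
  feature_series(mat, frame_interval = traj$frame_interval,
                 provenance = list(source = "extract_features",
                                   selection = idx))
}
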
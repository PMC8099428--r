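#' State-resolved ion-pair (salt-bridge) occupancy table
#'
#' A frame-level ion pair exists when the minimum distance between any member
#' atom of a positive charge group and any member atom of a negative group is
#' at or below the cutoff; the occupancy of a pair in a state is the fraction
#' of that state's frames with the contact. Rows are reported only at or
#' above the occupancy threshold (a "formed in this state" call). An
#' `atom_pairs` column gives the mean number of simultaneous atom-level
#' contacts of the pair in those frames, since one residue pair can
#' contribute more than one contact at a time.
#'
#' @param traj A [trajectory()].
#' @param groups Charge-group table as from [charge_groups()]: columns
#'   `residue`, `role` or `sign`, `atoms` (list of member atom names).
#'   Default: derived from the trajectory's atom annotation.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.0;
#'   recorded on the result).
#' @param labels Per-frame state labels (default: the trajectory's own).
#' @param threshold Minimum occupancy to report (default 0.5).
#' @param state_names Optional names for the states.
#' @return A tibble (class `contact_table`): `state`, `charge`, `partner`,
#'   `type`, `occupancy`, `atom_pairs`; cutoff/threshold in attributes.
#' @export
detect_ion_pairs <- function(traj, groups = NULL, cutoff = 4.0,
                             labels = NULL, threshold = 0.5,
                             state_names = NULL) {
  if (is.null(groups)) groups <- charge_groups(traj)
  groups <- as_tibble(groups)
  if (is.null(labels)) labels <- traj$state_labels
  if (is.null(labels)) abort("no state labels supplied or stored on the trajectory")
  if (length(labels) != n_frames(traj))
    abort("labels must have one entry per frame")
  pos <- groups[groups$sign > 0, ]
  neg <- groups[groups$sign < 0, ]
  if (nrow(pos) == 0 || nrow(neg) == 0)
    abort("need charge groups of both signs")
  rows <- purrr::map_dfr(seq_len(nrow(pos)), function(i) {
    purrr::map_dfr(seq_len(nrow(neg)), function(j) {
      pair_contacts(traj, pos$residue[i], pos$atoms[[i]],
                    neg$residue[j], neg$atoms[[j]], cutoff, labels,
                    type = "ion pair")
    })
  })
  finish_contact_table(rows, threshold, cutoff, state_names)
}

# per-state occupancy of one residue pair
pair_contacts <- function(traj, res_a, atoms_a, res_b, atoms_b, cutoff,
                          labels, type) {
  ia <- atom_indices(traj, res_a, atoms_a)
  ib <- atom_indices(traj, res_b, atoms_b)
  nf <- n_frames(traj)
  n_within <- matrix(0L, nf, 1)
  n_ct <- numeric(nf)
  for (a in ia) for (b in ib) {
    d <- sqrt((traj$coords[, a, 1] - traj$coords[, b, 1])^2 +
                (traj$coords[, a, 2] - traj$coords[, b, 2])^2 +
                (traj$coords[, a, 3] - traj$coords[, b, 3])^2)
    n_ct <- n_ct + (d <= cutoff)
  }
  has <- n_ct > 0
  purrr::map_dfr(sort(unique(labels)), function(s) {
    f <- labels == s
    occ <- mean(has[f])
    tibble(state = s, charge = res_a, partner = res_b, type = type,
           occupancy = occ,
           atom_pairs = if (any(has[f])) mean(n_ct[f][has[f]]) else 0)
  })
}

atom_indices <- function(traj, residue_label, atom_names) {
  at <- traj$atoms
  idx <- if ("residue" %in% names(at)) {
    which(at$residue == residue_label & at$name %in% atom_names)
  } else {
    which(paste0(at$resname, at$resno) == residue_label &
            at$name %in% atom_names)
  }
  if (length(idx) == 0)
    abort(sprintf("no member atoms of residue %s found in the trajectory",
                  residue_label))
  idx
}

finish_contact_table <- function(rows, threshold, cutoff, state_names) {
  out <- rows[rows$occupancy >= threshold, , drop = FALSE]
  if (!is.null(state_names)) out$state_name <- state_names[out$state]
  out <- dplyr::arrange(out, .data$state, .data$charge, .data$partner)
  attr(out, "cutoff") <- cutoff
  attr(out, "threshold") <- threshold
  class(out) <- c("contact_table", class(out))
  out
}

#' State-resolved hydrogen-bond occupancy table
#'
#' A hydrogen bond is called when the donor-acceptor heavy-atom distance is
#' at or below `dist_cutoff` and, when hydrogens are available, the
#' donor-hydrogen-acceptor angle is at or above `angle_cutoff`. Coarse
#' fixtures without hydrogens must set `heavy_only = TRUE` to use the
#' distance-only criterion.
#'
#' @param traj A [trajectory()].
#' @param donors Tibble: `residue`, `atom` (donor heavy atom), optional
#'   `hydrogen` (attached H atom name).
#' @param acceptors Tibble: `residue`, `atom`.
#' @param dist_cutoff Donor-acceptor distance cutoff (Angstrom, default 3.5).
#' @param angle_cutoff D-H...A angle cutoff (degrees, default 120).
#' @param heavy_only Skip the angle criterion (required when donors carry no
#'   hydrogen).
#' @inheritParams detect_ion_pairs
#' @return A `contact_table` with `type = "H-bond"`.
#' @export
detect_hbonds <- function(traj, donors, acceptors, dist_cutoff = 3.5,
                          angle_cutoff = 120, labels = NULL,
                          heavy_only = FALSE, threshold = 0.5,
                          state_names = NULL) {
  donors <- as_tibble(donors)
  acceptors <- as_tibble(acceptors)
  if (is.null(labels)) labels <- traj$state_labels
  if (is.null(labels)) abort("no state labels supplied or stored on the trajectory")
  no_h <- !("hydrogen" %in% names(donors)) || any(is.na(donors$hydrogen))
  if (no_h && !heavy_only)
    abort("donors carry no hydrogens; set heavy_only = TRUE for a distance-only criterion")
  rows <- purrr::map_dfr(seq_len(nrow(donors)), function(i) {
    purrr::map_dfr(seq_len(nrow(acceptors)), function(j) {
      di <- atom_indices(traj, donors$residue[i], donors$atom[i])[1]
      ai <- atom_indices(traj, acceptors$residue[j], acceptors$atom[j])[1]
      d <- sqrt(rowSums((matrix(traj$coords[, di, ], ncol = 3) -
                           matrix(traj$coords[, ai, ], ncol = 3))^2))
      ok <- d <= dist_cutoff
      if (!heavy_only) {
        hi <- atom_indices(traj, donors$residue[i], donors$hydrogen[i])[1]
        H <- matrix(traj$coords[, hi, ], ncol = 3)
        D <- matrix(traj$coords[, di, ], ncol = 3)
        A <- matrix(traj$coords[, ai, ], ncol = 3)
        v1 <- D - H; v2 <- A - H
        cosang <- rowSums(v1 * v2) /
          (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        ok <- ok & (ang >= angle_cutoff)
      }
      purrr::map_dfr(sort(unique(labels)), function(s) {
        f <- labels == s
        tibble(state = s, charge = donors$residue[i],
               partner = acceptors$residue[j], type = "H-bond",
               occupancy = mean(ok[f]), atom_pairs = mean(ok[f]))
      })
    })
  })
  finish_contact_table(rows, threshold, dist_cutoff, state_names)
}

#' Signed axial displacement of a selection between two frames
#'
#' Difference of the selection's geometric-centre projections onto an axis,
#' frame `b` minus frame `a`. With the default membrane convention
#' (+z extracellular) a negative value is a downward (intracellular)
#' movement — the direction the S4 helix takes on deactivation.
#'
#' @param traj A [trajectory()].
#' @param frame_a,frame_b Frame indices.
#' @param selection Atom selection (default: all atoms).
#' @param axis Unit axis vector (default `c(0, 0, 1)`).
#' @return Signed displacement in Angstrom.
#' @export
s4_displacement <- function(traj, frame_a, frame_b, selection = NULL,
                            axis = c(0, 0, 1)) {
  idx <- resolve_selection(traj, selection)
  axis <- axis / sqrt(sum(axis^2))
  ca <- colMeans(matrix(traj$coords[frame_a, idx, ], ncol = 3))
  cb <- colMeans(matrix(traj$coords[frame_b, idx, ], ncol = 3))
  sum((cb - ca) * axis)
}

#' Representative frame of a state
#'
#' The medoid frame of the state under selection RMSD (minimum mean distance
#' to the other members; ties broken toward the lowest frame index). A
#' one-frame state returns that frame.
#'
#' @param traj A [trajectory()].
#' @param labels Per-frame state labels (default: the trajectory's own).
#' @param state The state to summarise.
#' @param selection Atom selection for the RMSD (default: all atoms).
#' @param superpose Superpose before the RMSD (default `TRUE`).
#' @return Frame index (attribute `state` carries the state's label).
#' @export
representative_structure <- function(traj, labels = NULL, state,
                                     selection = NULL, superpose = TRUE) {
  if (is.null(labels)) labels <- traj$state_labels
  if (is.null(labels)) abort("no state labels supplied or stored on the trajectory")
  members <- which(labels == state)
  if (length(members) == 0) abort("state has no frames")
  if (length(members) == 1) {
    return(structure(members, state = state))
  }
  idx <- resolve_selection(traj, selection)
  sub <- trajectory(traj$coords[members, idx, , drop = FALSE],
                    atoms = traj$atoms[idx, ],
                    frame_interval = traj$frame_interval)
  D <- pairwise_rmsd(sub, superpose = superpose)
  structure(members[which.min(rowMeans(D))], state = state)
}
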
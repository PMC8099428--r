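#' Specify a sliding-helix structural fixture
#'
#' Builds the ground-truth-known coarse model of a voltage-sensing domain
#' used to validate the structural analyses: a mobile "S4" helix carrying
#' positive gating charges slides axially through a set of fixed
#' countercharges, visiting one discrete anchor position per state
#' (emulating the stepwise downward movement between the activated and three
#' resting states). Which (charge, countercharge) pairs touch in which state
#' is planted in `contact_map_truth` and validated against the geometry: at
#' `jitter_sd = 0` every planted contact must be realised and no unplanted
#' pair may fall within the cutoff, otherwise the spec is rejected naming
#' the offending pair.
#'
#' The default spec ([default_helix_spec()]) has 4 states with anchors
#' `(0, -5.1, -10.2, -15.3)` Angstrom (activated first; total axial travel
#' 15.3 Angstrom, three helical turns), five gating charges (K0, R1-R4)
#' spaced one anchor step apart, and three countercharges: an intracellular
#' charge-transfer-centre partner contacted hand-over-hand in every state, an
#' ENC partner contacted in the activated and two adjacent resting states
#' (the VSD I-like pattern), and an ENC partner contacted in the activated
#' state only (the VSD IV-like pattern).
#'
#' @param n_states Number of states.
#' @param state_anchors Axial offset of the mobile helix per state
#'   (Angstrom), strictly monotone.
#' @param gating_charges Tibble: `residue` (label), `resname`, `resno`,
#'   `atom` (side-chain tip atom name), `offset` (axial position on the
#'   helix, Angstrom).
#' @param countercharges Tibble: `residue`, `resname`, `resno`, `atom`,
#'   `x`, `y`, `z` (fixed positions, Angstrom).
#' @param contact_map_truth Tibble: `state`, `charge`, `partner` (residue
#'   labels), the planted per-state contact map.
#' @param jitter_sd Isotropic Gaussian jitter on the mobile beads, Angstrom.
#' @param frames_per_state Frames generated per state.
#' @param contact_cutoff Heavy-atom contact cutoff used to validate the
#'   planted geometry (Angstrom).
#' @param seed Integer seed.
#' @param state_names Optional state names (same order as the anchors).
#' @return Object of class `helix_fixture_spec`.
#' @export
helix_fixture_spec <- function(n_states = 4, state_anchors, gating_charges,
                               countercharges, contact_map_truth,
                               jitter_sd = 0.3, frames_per_state = 50,
                               contact_cutoff = 4.0, seed = 1L,
                               state_names = NULL) {
  if (length(state_anchors) != n_states)
    abort("state_anchors must have one entry per state")
  d <- diff(state_anchors)
  if (!(all(d > 0) || all(d < 0)))
    abort("state anchors must be strictly monotone (axial progression)")
  if (jitter_sd < 0) abort("jitter_sd must be >= 0")
  if (frames_per_state < 1) abort("frames_per_state must be >= 1")
  if (is.null(state_names)) {
    state_names <- if (n_states > 1)
      c("activated", paste0("resting ", seq(n_states - 1, 1))) else "state 1"
  }
  spec <- structure(
    list(n_states = as.integer(n_states), state_anchors = state_anchors,
         gating_charges = as_tibble(gating_charges),
         countercharges = as_tibble(countercharges),
         contact_map_truth = as_tibble(contact_map_truth),
         jitter_sd = jitter_sd, frames_per_state = as.integer(frames_per_state),
         contact_cutoff = contact_cutoff, seed = as.integer(seed),
         state_names = state_names),
    class = "helix_fixture_spec"
  )
  validate_helix_geometry(spec)
  spec
}

#' @rdname helix_fixture_spec
#' @export
default_helix_spec <- function(jitter_sd = 0.3, frames_per_state = 50,
                               seed = 1L) {
  step <- 5.1
  charges <- tibble(
    residue = c("K0", "R1", "R2", "R3", "R4"),
    resname = c("LYS", "ARG", "ARG", "ARG", "ARG"),
    resno = 1:5,
    atom = c("NZ", "CZ", "CZ", "CZ", "CZ"),
    offset = -step * (0:4)
  )
  counter <- tibble(
    residue = c("E_INC", "E_ENC1", "D_ENC2"),
    resname = c("GLU", "GLU", "ASP"),
    resno = c(100, 90, 196),
    atom = c("OE1", "OE1", "OD1"),
    x = 3, y = 0, z = c(-4 * step, -2 * step, 2.0)
  )
  truth <- dplyr::bind_rows(
    # charge-transfer centre: hand-over-hand in every state
    tibble(state = 1:4, charge = c("R4", "R3", "R2", "R1"),
           partner = "E_INC"),
    # VSD I-like ENC partner: activated + two adjacent resting states
    tibble(state = 1:3, charge = c("R2", "R1", "K0"),
           partner = "E_ENC1"),
    # VSD IV-like ENC partner: activated state only
    tibble(state = 1, charge = "K0", partner = "D_ENC2")
  )
  helix_fixture_spec(
    n_states = 4, state_anchors = c(0, -step, -2 * step, -3 * step),
    gating_charges = charges, countercharges = counter,
    contact_map_truth = truth, jitter_sd = jitter_sd,
    frames_per_state = frames_per_state, seed = seed
  )
}

# jitter-free coordinates of every atom in one state; rows follow the atom
# table built by helix_atom_table()
helix_state_coords <- function(spec, state) {
  anchor <- spec$state_anchors[state]
  gc <- spec$gating_charges
  cc <- spec$countercharges
  rbind(
    # side-chain tip + CA bead per gating charge (mobile)
    cbind(0, 0, gc$offset + anchor),
    cbind(0.8, 0, gc$offset + anchor),
    # countercharge tip + CA bead (fixed)
    cbind(cc$x, cc$y, cc$z),
    cbind(cc$x + 0.8, cc$y, cc$z)
  )
}

helix_atom_table <- function(spec) {
  gc <- spec$gating_charges
  cc <- spec$countercharges
  dplyr::bind_rows(
    tibble(name = gc$atom, resname = gc$resname, resno = gc$resno,
           chain = "S", residue = gc$residue, role = "gating_charge",
           sign = 1, mobile = TRUE),
    tibble(name = "CA", resname = gc$resname, resno = gc$resno,
           chain = "S", residue = gc$residue, role = "gating_charge",
           sign = 1, mobile = TRUE),
    tibble(name = cc$atom, resname = cc$resname, resno = cc$resno,
           chain = "C", residue = cc$residue, role = "countercharge",
           sign = -1, mobile = FALSE),
    tibble(name = "CA", resname = cc$resname, resno = cc$resno,
           chain = "C", residue = cc$residue, role = "countercharge",
           sign = -1, mobile = FALSE)
  )
}

# the contact map realised by the jitter-free geometry (side-chain tips)
realized_contact_map <- function(spec) {
  gc <- spec$gating_charges
  cc <- spec$countercharges
  purrr::map_dfr(seq_len(spec$n_states), function(s) {
    anchor <- spec$state_anchors[s]
    purrr::map_dfr(seq_len(nrow(gc)), function(i) {
      d <- sqrt((0 - cc$x)^2 + (0 - cc$y)^2 +
                  (gc$offset[i] + anchor - cc$z)^2)
      hit <- which(d <= spec$contact_cutoff)
      if (length(hit) == 0) return(tibble())
      tibble(state = s, charge = gc$residue[i], partner = cc$residue[hit])
    })
  })
}

validate_helix_geometry <- function(spec) {
  realized <- realized_contact_map(spec)
  truth <- spec$contact_map_truth
  key <- function(df) paste(df$state, df$charge, df$partner)
  missing <- setdiff(key(truth), key(realized))
  extra <- setdiff(key(realized), key(truth))
  if (length(missing) > 0)
    abort(sprintf("planted contact not realised by the geometry: %s",
                  missing[1]))
  if (length(extra) > 0)
    abort(sprintf("geometry realises an unplanted contact: %s", extra[1]))
  invisible(spec)
}

#' Generate trajectory frames from a sliding-helix fixture
#'
#' Produces `frames_per_state * n_states` frames: the mobile helix beads sit
#' at their state anchor plus isotropic Gaussian jitter; countercharges stay
#' fixed. Per-frame ground-truth state labels travel with the trajectory.
#' Equal seeds give byte-identical coordinates.
#'
#' @param spec A [helix_fixture_spec()].
#' @return A [trajectory()] whose atom table carries `residue`, `role`,
#'   `sign` and `mobile` columns and whose `state_labels` are the planted
#'   states.
#' @export
generate_helix_fixture <- function(spec) {
  stopifnot(inherits(spec, "helix_fixture_spec"))
  atoms <- helix_atom_table(spec)
  na <- nrow(atoms)
  nf <- spec$n_states * spec$frames_per_state
  coords <- array(0, c(nf, na, 3))
  labels <- rep(seq_len(spec$n_states), each = spec$frames_per_state)
  withr::with_seed(spec$seed, {
    f <- 0
    for (s in seq_len(spec$n_states)) {
      base <- helix_state_coords(spec, s)
      for (r in seq_len(spec$frames_per_state)) {
        f <- f + 1
        fr <- base
        if (spec$jitter_sd > 0) {
          jit <- matrix(rnorm(sum(atoms$mobile) * 3, sd = spec$jitter_sd),
                        ncol = 3)
          fr[atoms$mobile, ] <- fr[atoms$mobile, ] + jit
        }
        coords[f, , ] <- fr
      }
    }
  })
  trajectory(coords, atoms = atoms, frame_interval = 1,
             state_labels = labels,
             provenance = list(generator = "helix_fixture", spec = spec))
}

#' Charge-group table of a fixture trajectory
#'
#' Collects gating charges and countercharges (residue label, role, formal
#' sign, member atom names) from a trajectory whose atom table carries
#' `role`/`sign` tags, in the shape [detect_ion_pairs()] expects.
#'
#' @param traj A fixture [trajectory()].
#' @return Tibble: `residue`, `role`, `sign`, `atoms` (list of member atom
#'   names, side-chain heavy atoms only).
#' @export
charge_groups <- function(traj) {
  at <- traj$atoms
  if (!all(c("residue", "role", "sign") %in% names(at)))
    abort("trajectory atoms carry no charge-group annotation")
  at |>
    dplyr::filter(!is.na(.data$role), .data$name != "CA") |>
    dplyr::group_by(.data$residue, .data$role, .data$sign) |>
    dplyr::summarise(atoms = list(.data$name), .groups = "drop")
}
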
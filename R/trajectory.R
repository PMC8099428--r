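#' Trajectory: ordered coordinate frames with atom metadata
#'
#' The coordinate container for all structural analysis: a frames x atoms x 3
#' array in Angstrom, a per-atom metadata table, and the physical time per
#' saved frame. The z axis is taken as the membrane normal (+z extracellular),
#' the convention under which axial S4 displacements are reported.
#'
#' @param coords Numeric array `frames x atoms x 3` (Angstrom), or a single
#'   `atoms x 3` matrix for a one-frame trajectory.
#' @param atoms Data frame with one row per atom; recognised columns are
#'   `name` (atom name, e.g. "CA"), `resname`, `resno` (residue index),
#'   `chain`, and optional role tags. Defaults are generated when omitted.
#' @param frame_interval Physical time per saved frame.
#' @param state_labels Optional integer/character vector of per-frame labels
#'   (e.g. ground-truth states of a synthetic fixture).
#' @param provenance Named list recording origin.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms = NULL, frame_interval = 1,
                       state_labels = NULL, provenance = list()) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    abort("coords must be a frames x atoms x 3 array")
  if (anyNA(coords) || any(!is.finite(coords)))
    abort("all coordinates must be finite")
  n_atoms <- dim(coords)[2]
  if (is.null(atoms)) {
    atoms <- tibble(name = rep("CA", n_atoms), resname = rep("ALA", n_atoms),
                    resno = seq_len(n_atoms), chain = rep("A", n_atoms))
  }
  atoms <- as_tibble(atoms)
  if (nrow(atoms) != n_atoms)
    abort(sprintf("atom table has %d rows but coords have %d atoms",
                  nrow(atoms), n_atoms))
  if (!is.null(state_labels) && length(state_labels) != dim(coords)[1])
    abort("state_labels must have one entry per frame")
  structure(
    list(coords = coords, atoms = atoms, frame_interval = frame_interval,
         state_labels = state_labels, provenance = provenance),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g\n",
              n_frames(x), n_atoms(x), x$frame_interval))
  invisible(x)
}

#' @rdname trajectory
#' @param x A trajectory.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(x) dim(x$coords)[2]

# one frame as an atoms x 3 matrix
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

# frames x 3N matrix in bio3d xyz layout (atom-major x,y,z)
traj_xyz <- function(traj) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  out <- matrix(0, nf, 3 * na)
  out[, seq(1, 3 * na, 3)] <- traj$coords[, , 1]
  out[, seq(2, 3 * na, 3)] <- traj$coords[, , 2]
  out[, seq(3, 3 * na, 3)] <- traj$coords[, , 3]
  out
}

xyz_to_array <- function(xyz, n_atoms) {
  xyz <- matrix(xyz, ncol = 3 * n_atoms)
  arr <- array(0, c(nrow(xyz), n_atoms, 3))
  arr[, , 1] <- xyz[, seq(1, 3 * n_atoms, 3)]
  arr[, , 2] <- xyz[, seq(2, 3 * n_atoms, 3)]
  arr[, , 3] <- xyz[, seq(3, 3 * n_atoms, 3)]
  arr
}

#' Read a trajectory from disk
#'
#' Supports multi-frame PDB (`MODEL`/`ENDMDL` records) and binary CHARMM/NAMD
#' DCD. A DCD carries no atom metadata, so a PDB topology is required; its
#' atom count must match every frame.
#'
#' @param path Trajectory file (`.pdb` or `.dcd`).
#' @param topology_path PDB file supplying atom metadata (required for DCD;
#'   optional for PDB where the file is its own topology).
#' @param frame_interval Physical time per frame to record on the result.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology_path = NULL, frame_interval = 1) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    if (is.null(topology_path))
      abort("a PDB topology is required to read a DCD trajectory")
    top <- read_pdb_checked(topology_path)
    xyz <- tryCatch(
      suppressWarnings(bio3d::read.dcd(path, verbose = FALSE)),
      error = function(e) abort(sprintf("unreadable DCD '%s': %s", path,
                                        conditionMessage(e))))
    na_top <- nrow(top$atom)
    na_dcd <- ncol(xyz) / 3
    if (na_dcd != na_top)
      abort(sprintf("atom-count mismatch: topology has %d atoms, DCD frames have %d",
                    na_top, na_dcd))
    return(trajectory(xyz_to_array(xyz, na_top), atoms = pdb_atom_table(top),
                      frame_interval = frame_interval,
                      provenance = list(source = path, topology = topology_path)))
  }
  pdb <- read_pdb_checked(path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  na_pdb <- nrow(pdb$atom)
  if (!is.null(topology_path)) {
    top <- read_pdb_checked(topology_path)
    if (nrow(top$atom) != na_pdb)
      abort(sprintf("atom-count mismatch: topology has %d atoms, trajectory frames have %d",
                    nrow(top$atom), na_pdb))
    atoms <- pdb_atom_table(top)
  } else {
    atoms <- pdb_atom_table(pdb)
  }
  trajectory(xyz_to_array(xyz, na_pdb), atoms = atoms,
             frame_interval = frame_interval,
             provenance = list(source = path))
}

read_pdb_checked <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(sprintf("unreadable PDB '%s': %s", path,
                                      conditionMessage(e))))
}

pdb_atom_table <- function(pdb) {
  a <- pdb$atom
  tibble(name = a$elety, resname = a$resid, resno = a$resno,
         chain = ifelse(is.na(a$chain), "A", a$chain))
}

#' Write a trajectory to disk
#'
#' Multi-frame PDB (standard ATOM records inside MODEL/ENDMDL blocks) or
#' binary CHARMM-format DCD. PDB coordinates are fixed-point with 3 decimals,
#' so a PDB round trip is exact to 1e-3 Angstrom; DCD stores single-precision
#' floats.
#'
#' @param traj A [trajectory()].
#' @param path Output path; format chosen by extension (`.pdb` or `.dcd`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    write_dcd(traj_xyz(traj), path, delta = traj$frame_interval)
  } else {
    bio3d::write.pdb(file = path, xyz = traj_xyz(traj),
                     elety = traj$atoms$name, resid = traj$atoms$resname,
                     resno = traj$atoms$resno, chain = traj$atoms$chain)
  }
  invisible(path)
}

# Minimal CHARMM-format DCD writer (single precision, no unit cell).
# Layout: 84-byte "CORD" header with the icntrl block, one title record,
# the natom record, then per frame three float records (x, y, z).
write_dcd <- function(xyz, path, delta = 1) {
  xyz <- matrix(xyz, ncol = ncol(xyz))
  n_frames <- nrow(xyz)
  natom <- ncol(xyz) / 3
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(v) writeBin(as.integer(v), con, size = 4)
  # header record
  wint(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- n_frames       # NSET
  icntrl[2] <- 1              # ISTART
  icntrl[3] <- 1              # NSAVC
  icntrl[4] <- n_frames
  icntrl[20] <- 24            # CHARMM version flag
  wint(icntrl[1:9])
  writeBin(as.numeric(delta), con, size = 4)  # DELTA as float32
  wint(icntrl[11:20])
  wint(84)
  # title record
  title <- formatC("written by vsdkinetics", width = -80)
  wint(4 + 80)
  wint(1)
  writeChar(title, con, nchars = 80, eos = NULL)
  wint(4 + 80)
  # natom record
  wint(4); wint(natom); wint(4)
  ix <- seq(1, 3 * natom, 3)
  for (f in seq_len(n_frames)) {
    for (d in 0:2) {
      wint(4 * natom)
      writeBin(as.numeric(xyz[f, ix + d]), con, size = 4)
      wint(4 * natom)
    }
  }
  invisible(path)
}
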
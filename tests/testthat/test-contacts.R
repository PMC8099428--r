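# Ion-pair and H-bond occupancy, S4 displacement, representative frames.

test_that("planted contacts are found and distant pairs are absent", {
  spec <- default_helix_spec(jitter_sd = 0, frames_per_state = 2)
  traj <- generate_helix_fixture(spec)
  ct <- detect_ion_pairs(traj, cutoff = 4.0)
  # the CTC partner at exactly 3.0 A has occupancy 1
  expect_true(all(ct$occupancy == 1))
  # the VSD IV-like partner appears in the activated state only
  d_rows <- ct[ct$partner == "D_ENC2", ]
  expect_equal(d_rows$state, 1)
  # the VSD I-like partner appears in activated + two resting states
  e_rows <- ct[ct$partner == "E_ENC1", ]
  expect_equal(sort(e_rows$state), 1:3)
  # pairs beyond the cutoff never appear
  expect_false(any(ct$partner == "E_ENC1" & ct$state == 4))
})

test_that("ion-pair occupancy is monotonically non-decreasing in the cutoff", {
  traj <- generate_helix_fixture(default_helix_spec(jitter_sd = 0.4,
                                                    frames_per_state = 20,
                                                    seed = 6))
  occ_at <- function(cutoff) {
    ct <- detect_ion_pairs(traj, cutoff = cutoff, threshold = 0)
    sum(ct$occupancy)
  }
  occ <- vapply(c(3, 4, 5, 7), occ_at, numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("missing member atoms are reported by residue", {
  traj <- generate_helix_fixture(default_helix_spec(frames_per_state = 1))
  groups <- charge_groups(traj)
  groups$atoms[[1]] <- "XX"
  expect_error(detect_ion_pairs(traj, groups), groups$residue[1])
})

test_that("hydrogen bonds honour both distance and angle criteria", {
  # D-H...A: ideal linear geometry at 2.9 A
  atoms <- tibble::tibble(
    name = c("ND", "HD", "OA"), resname = c("ASN", "ASN", "SER"),
    resno = c(1, 1, 2), chain = "A",
    residue = c("N1", "N1", "S2"))
  linear <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2.9))
  bent <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 2.9, 1))  # 90 deg at H
  traj <- toy_trajectory(list(linear, bent), atoms = atoms)
  donors <- tibble::tibble(residue = "N1", atom = "ND", hydrogen = "HD")
  acceptors <- tibble::tibble(residue = "S2", atom = "OA")
  ct_lin <- detect_hbonds(traj, donors, acceptors, labels = c(1, 2),
                          threshold = 0.5)
  expect_equal(nrow(ct_lin), 1)
  expect_equal(ct_lin$state, 1)  # detected in the linear frame only
  expect_equal(ct_lin$type, "H-bond")
  # a bond present in exactly half the frames has occupancy 0.5
  traj2 <- toy_trajectory(list(linear, bent, linear, bent), atoms = atoms)
  ct_half <- detect_hbonds(traj2, donors, acceptors,
                           labels = rep(1, 4), threshold = 0.5)
  expect_equal(ct_half$occupancy, 0.5)
  # no hydrogens and heavy_only unset is an error; heavy-only mode works
  donors_noh <- tibble::tibble(residue = "N1", atom = "ND")
  expect_error(detect_hbonds(traj, donors_noh, acceptors,
                             labels = c(1, 2)), "heavy_only")
  ct_heavy <- detect_hbonds(traj, donors_noh, acceptors, labels = c(1, 2),
                            heavy_only = TRUE, threshold = 0.5)
  expect_equal(sort(unique(ct_heavy$state)), 1:2)  # distance-only: both pass
})

test_that("axial displacement is signed, orthogonal to lateral motion, and additive", {
  a <- square_frame()
  traj <- toy_trajectory(list(a,
                              sweep(a, 2, c(0, 0, -5.1), "+"),
                              sweep(a, 2, c(0, 0, -15.3), "+"),
                              sweep(a, 2, c(7, -3, 0), "+")))
  expect_equal(s4_displacement(traj, 1, 1), 0)
  expect_equal(s4_displacement(traj, 1, 3), -15.3, tolerance = 1e-12)
  expect_equal(s4_displacement(traj, 3, 1), 15.3, tolerance = 1e-12)
  # pure lateral shift projects to zero on z
  expect_equal(s4_displacement(traj, 1, 4), 0, tolerance = 1e-12)
  # additivity along a path of states
  d13 <- s4_displacement(traj, 1, 3)
  expect_equal(s4_displacement(traj, 1, 2) + s4_displacement(traj, 2, 3),
               d13, tolerance = 1e-12)
})

test_that("representative frames are medoids with documented tie-breaks", {
  a <- square_frame()
  same <- toy_trajectory(list(a, a, a))
  r <- representative_structure(same, labels = c(1, 1, 1), state = 1)
  expect_equal(as.integer(r), 1)  # tie -> first frame
  expect_equal(attr(r, "state"), 1)
  # frame 2 midway between 1 and 3 is the medoid
  shifted <- function(dz) {
    f <- a; f[1, 3] <- f[1, 3] + dz; f
  }
  mid <- toy_trajectory(list(shifted(0), shifted(1), shifted(2)))
  r2 <- representative_structure(mid, labels = rep(1, 3), state = 1,
                                 superpose = FALSE)
  expect_equal(as.integer(r2), 2)
  # singleton state returns its frame
  r3 <- representative_structure(mid, labels = c(1, 2, 2), state = 1)
  expect_equal(as.integer(r3), 1)
  expect_error(representative_structure(mid, labels = rep(1, 3), state = 9),
               "no frames")
})
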
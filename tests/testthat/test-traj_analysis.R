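static_traj <- function(n_res = 10, n_frames = 4, seed = 1) {
  generate_trajectory(trajectory_truth(
    n_residues = n_res, n_frames = n_frames, per_residue_sigma = 0,
    domain_a_residues = max(3, n_res %/% 3), seed = seed))
}

test_that("kabsch superposition is exact on rigid copies", {
  set.seed(21)
  P <- matrix(rnorm(18), 6, 3)
  k_id <- kabsch_superpose(P, P)
  expect_equal(k_id$rmsd, 0, tolerance = 1e-12)
  expect_equal(k_id$rotation, diag(3), tolerance = 1e-10)
  R <- random_rotation(); tr <- c(4, -2, 7)
  Q <- sweep(P %*% t(R), 2, tr, "+")
  k <- kabsch_superpose(P, Q)
  expect_lt(k$rmsd, 1e-10)
  expect_error(kabsch_superpose(P, P[1:5, ]), "mismatch")
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), ">= 3")
})

test_that("kabsch rmsd matches the quaternion oracle on random instances", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- matrix(rnorm(3 * n), n, 3)
    w <- runif(n, 0.5, 2)
    expect_equal(kabsch_superpose(P, Q)$rmsd, quaternion_rmsd(P, Q),
                 tolerance = 1e-8)
    expect_equal(kabsch_superpose(P, Q, w)$rmsd, quaternion_rmsd(P, Q, w),
                 tolerance = 1e-8)
  }
})

test_that("rmsd_series is zero on static or rigidly moved trajectories", {
  traj <- static_traj()
  ca <- select_atoms(traj, atom_names = "CA")
  expect_equal(rmsd_series(traj, ca)$values, rep(0, 4), tolerance = 1e-10)
  # frames that are rigid transforms of frame 1
  set.seed(23)
  moved <- traj
  moved$frames <- lapply(traj$frames, function(F)
    sweep(F %*% t(random_rotation()), 2, rnorm(3, sd = 5), "+"))
  expect_lt(max(rmsd_series(moved, ca)$values), 1e-10)
})

test_that("single-atom displacement gives the closed-form RMSD", {
  traj <- static_traj(n_res = 16, n_frames = 6)
  ca <- select_atoms(traj, atom_names = "CA")
  d <- 2.4
  for (f in c(2, 4, 6)) traj$frames[[f]][ca[5], ] <-
      traj$frames[[f]][ca[5], ] + c(d, 0, 0)
  fit_sel <- ca[-5]
  out <- rmsd_series(traj, fit_sel, measure_selection = ca,
                     mass_weighted = FALSE)
  expected <- d / sqrt(length(ca))
  expect_equal(out$values[c(2, 4, 6)], rep(expected, 3), tolerance = 1e-10)
  expect_equal(out$values[c(1, 3, 5)], rep(0, 3), tolerance = 1e-10)
})

test_that("rmsd with measure == fit equals the superposition rmsd", {
  traj <- generate_trajectory(trajectory_truth(
    n_residues = 12, n_frames = 5, per_residue_sigma = 0.8,
    domain_a_residues = 6, seed = 31))
  ca <- select_atoms(traj, atom_names = "CA")
  series <- rmsd_series(traj, ca)
  direct <- vapply(traj$frames, function(F)
    kabsch_superpose(F[ca, ], traj$frames[[1]][ca, ],
                     traj$topology$masses[ca])$rmsd, numeric(1))
  expect_equal(series$values, direct, tolerance = 1e-12)
})

test_that("rmsf matches the two-frame and static closed forms", {
  traj <- static_traj(n_res = 12, n_frames = 5)
  ca <- select_atoms(traj, atom_names = "CA")
  expect_equal(rmsf_profile(traj, ca)$values, rep(0, 12),
               tolerance = 1e-10)
  # two frames, one atom displaced by d after fitting -> RMSF = d/2
  t2 <- static_traj(n_res = 12, n_frames = 2)
  d <- 1.8
  t2$frames[[2]][ca[3], ] <- t2$frames[[2]][ca[3], ] + c(0, d, 0)
  prof <- rmsf_profile(t2, ca, fit_selection = ca[-3],
                       mass_weighted = FALSE)
  expect_equal(prof$values[3], d / 2, tolerance = 1e-10)
  expect_lt(max(prof$values[-3]), 1e-10)
  expect_error(rmsf_profile(static_traj(n_frames = 1), ca), ">= 2 frames")
})

test_that("isotropic jitter yields RMSF near sigma * sqrt(3)", {
  sigma <- 0.5
  traj <- generate_trajectory(trajectory_truth(
    n_residues = 40, n_frames = 800, per_residue_sigma = sigma,
    domain_a_residues = 20, seed = 41))
  ca <- select_atoms(traj, atom_names = "CA")
  prof <- rmsf_profile(traj, ca, fit_selection = NULL)
  expect_lt(abs(mean(prof$values) - sigma * sqrt(3)),
            0.05 * sigma * sqrt(3))
})

test_that("radius of gyration reproduces hand-computed cases", {
  atoms <- data.frame(serial = 1:4, atom_name = "CA",
                      residue_name = "ALA", chain_id = "A",
                      residue_number = 1:4, element = "C")
  # two unit masses at (+1, 0, 0) and (-1, 0, 0) -> Rg = 1
  s2 <- md_structure(atoms[1:2, ], rbind(c(1, 0, 0), c(-1, 0, 0)),
                     masses = c(1, 1))
  t2 <- md_trajectory(s2, list(s2$coords))
  expect_equal(radius_of_gyration(t2, 1:2)$values, 1)
  # four equal masses at unit-square corners -> sqrt(0.5)
  sq <- md_structure(atoms, rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                  c(0, 1, 0)), masses = rep(1, 4))
  tsq <- md_trajectory(sq, list(sq$coords))
  expect_equal(radius_of_gyration(tsq, 1:4)$values, sqrt(0.5),
               tolerance = 1e-12)
  # single atom -> 0
  expect_equal(radius_of_gyration(tsq, 2)$values, 0)
  # mass weighting shifts Rg toward the heavy atom
  sq_w <- md_structure(atoms, sq$coords, masses = c(10, 1, 1, 1))
  tw <- md_trajectory(sq_w, list(sq_w$coords))
  expect_lt(radius_of_gyration(tw, 1:4)$values, sqrt(0.5))
  expect_equal(radius_of_gyration(tw, 1:4,
                                  mass_weighted = FALSE)$values,
               sqrt(0.5), tolerance = 1e-12)
})

test_that("interdomain distance tracks the generator profile exactly", {
  profile <- seq(10, 20, length.out = 6)
  traj <- generate_trajectory(trajectory_truth(
    n_residues = 20, n_frames = 6, per_residue_sigma = 0,
    domain_a_residues = 10, domain_separation_profile = profile,
    seed = 51))
  da <- domain_definition("A", list(c(1, 10)))
  db <- domain_definition("B", list(c(11, 20)))
  out <- interdomain_distance(traj, da, db)
  expect_equal(out$values, profile, tolerance = 1e-10)
  # translation invariance
  shifted <- traj
  shifted$frames <- lapply(traj$frames, function(F)
    sweep(F, 2, c(100, -50, 3), "+"))
  expect_equal(interdomain_distance(shifted, da, db)$values, out$values,
               tolerance = 1e-10)
  # two single-atom domains 5 A apart
  atoms <- data.frame(serial = 1:2, atom_name = "CA",
                      residue_name = "GLY", chain_id = "A",
                      residue_number = 1:2, element = "C")
  sp <- md_structure(atoms, rbind(c(0, 0, 0), c(3, 4, 0)))
  tp <- md_trajectory(sp, list(sp$coords))
  expect_equal(interdomain_distance(
    tp, domain_definition("a", list(c(1, 1))),
    domain_definition("b", list(c(2, 2))))$values, 5)
})

test_that("hydrogen-bond occupancy counts frames under the cutoff", {
  # constructed 10-frame pair: 3 frames bound at <= 3.5, 7 beyond
  atoms <- data.frame(serial = 1:2, atom_name = c("SG", "NE2"),
                      residue_name = c("CYS", "HIS"), chain_id = "A",
                      residue_number = c(113L, 59L),
                      element = c("S", "N"))
  dists <- c(3.0, 5, 3.4, 5, 5, 3.5, 5, 5, 5, 5)
  frames <- lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  traj <- md_trajectory(md_structure(atoms, frames[[1]]), frames)
  spec <- hbond_spec(list(residue = 113, atom = "SG"),
                     list(residue = 59, atom = "NE2"))
  out <- hbond_occupancy(traj, spec)
  expect_identical(out$occupancy, 0.3)
  expect_identical(out$occupancy, mean(out$satisfied))
  expect_equal(out$distance_series$values, dists)
  # all frames bound -> 1.0
  traj_b <- md_trajectory(md_structure(atoms, frames[[1]]),
                          rep(frames[1], 4))
  expect_identical(hbond_occupancy(traj_b, spec)$occupancy, 1)
  # frame order does not matter
  traj_r <- md_trajectory(md_structure(atoms, frames[[1]]), rev(frames))
  expect_identical(hbond_occupancy(traj_r, spec)$occupancy, 0.3)
  expect_error(hbond_spec(list(residue = 1, atom = "A"),
                          list(residue = 1, atom = "A")), "differ")
})

test_that("designed occupancy is recovered within binomial error", {
  occ <- 0.3; nf <- 2000
  traj <- generate_trajectory(trajectory_truth(
    n_residues = 8, n_frames = nf, per_residue_sigma = 0,
    domain_a_residues = 4,
    hbond_pairs = list(list(res_a = 2, atom_a = "SG", elem_a = "S",
                            res_b = 6, atom_b = "NE2", elem_b = "N",
                            occupancy = occ, bound_distance = 3.0,
                            unbound_distance = 5.0)),
    seed = 61))
  out <- hbond_occupancy(traj, hbond_spec(list(residue = 2, atom = "SG"),
                                          list(residue = 6, atom = "NE2")))
  expect_lt(abs(out$occupancy - occ), 3 * sqrt(occ * (1 - occ) / nf))
})

test_that("backbone H-bond count matches the brute-force oracle", {
  s <- helical_backbone_structure(n_res = 8)
  traj <- md_trajectory(s, list(s$coords))
  mine <- backbone_hbond_count(traj, distance_cutoff = 3.5)$values
  oracle <- brute_hbond_count(s$atoms, s$coords, 3.5)
  expect_gt(oracle, 0)  # the fixture is nontrivial
  expect_identical(mine, as.numeric(oracle))
  # fully extended chain with every N-O pair beyond the cutoff -> 0
  n <- 6
  atoms <- data.frame(serial = 1:(2 * n),
                      atom_name = rep(c("N", "O"), each = n),
                      residue_name = "GLY", chain_id = "A",
                      residue_number = rep(1:n, 2),
                      element = rep(c("N", "O"), each = n))
  coords <- rbind(cbind(10 * (1:n), 0, 0), cbind(10 * (1:n) + 2, 0, 0))
  ext <- md_trajectory(md_structure(atoms, coords), list(coords))
  expect_equal(backbone_hbond_count(ext)$values, 0)
  # exactly one constructed pair at 2.9 A -> 1
  coords2 <- coords
  coords2[n + 3, ] <- coords[1, ] + c(2.9, 0, 0)   # O(res 3) near N(res 1)
  one <- md_trajectory(md_structure(atoms, coords2), list(coords2))
  expect_equal(backbone_hbond_count(one)$values, 1)
})

test_that("trajectory metrics are invariant under global rigid motion", {
  traj <- generate_trajectory(trajectory_truth(
    n_residues = 14, n_frames = 6, per_residue_sigma = 0.6,
    domain_a_residues = 7, seed = 71,
    hbond_pairs = list(list(res_a = 3, atom_a = "SG", elem_a = "S",
                            res_b = 11, atom_b = "NE2", elem_b = "N",
                            occupancy = 0.5, bound_distance = 3.0,
                            unbound_distance = 5.0))))
  set.seed(72)
  R <- random_rotation(); tr <- c(12, -7, 30)
  moved <- traj
  moved$frames <- apply_rigid_frames(traj$frames, R, tr)
  ca <- select_atoms(traj, atom_names = "CA")
  da <- domain_definition("A", list(c(1, 7)))
  db <- domain_definition("B", list(c(8, 14)))
  spec <- hbond_spec(list(residue = 3, atom = "SG"),
                     list(residue = 11, atom = "NE2"))
  expect_equal(rmsd_series(moved, ca)$values,
               rmsd_series(traj, ca)$values, tolerance = 1e-8)
  expect_equal(rmsf_profile(moved, ca)$values,
               rmsf_profile(traj, ca)$values, tolerance = 1e-8)
  expect_equal(radius_of_gyration(moved, ca)$values,
               radius_of_gyration(traj, ca)$values, tolerance = 1e-8)
  expect_equal(interdomain_distance(moved, da, db)$values,
               interdomain_distance(traj, da, db)$values,
               tolerance = 1e-8)
  expect_identical(hbond_occupancy(moved, spec)$occupancy,
                   hbond_occupancy(traj, spec)$occupancy)
  expect_equal(backbone_hbond_count(moved)$values,
               backbone_hbond_count(traj)$values)
})

test_that("Rg and RMSF are invariant to atom re-ordering in a selection", {
  traj <- generate_trajectory(trajectory_truth(
    n_residues = 10, n_frames = 5, per_residue_sigma = 0.5,
    domain_a_residues = 5, seed = 81))
  ca <- select_atoms(traj, atom_names = "CA")
  perm <- rev(ca)
  expect_equal(radius_of_gyration(traj, perm)$values,
               radius_of_gyration(traj, ca)$values, tolerance = 1e-12)
  expect_equal(sort(rmsf_profile(traj, perm)$values),
               sort(rmsf_profile(traj, ca)$values), tolerance = 1e-12)
})
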
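test_that("pocket volume matches the analytic empty sphere and refines", {
  # no receptor bead anywhere near the inclusion sphere
  beads <- data.frame(id = 1:2, residue_id = 1:2, residue_name = "X",
                      role = c("receptor", "ligand"), mass = 10, charge = 0,
                      lj_sigma = 3, lj_epsilon = 0)
  sys <- cg_system(beads, rbind(c(60, 60, 60), c(70, 60, 60)), box = 80,
                   site_residues = 1, ligand_residues = 2)
  center <- c(20, 20, 20)
  analytic <- 4 / 3 * pi * 5^3
  v05 <- pocket_volume(sys$coords, sys, center, radius = 5, spacing = 0.5)
  expect_equal(v05, analytic, tolerance = 0.05)
  # halving the spacing moves the estimate closer to the analytic value
  v025 <- pocket_volume(sys$coords, sys, center, radius = 5, spacing = 0.25)
  expect_lt(abs(v025 - analytic), abs(v05 - analytic))

  # a site fully packed with receptor beads has zero free volume
  grid_pts <- as.matrix(expand.grid(seq(17, 23, 2), seq(17, 23, 2),
                                    seq(17, 23, 2)))
  beads2 <- data.frame(id = seq_len(nrow(grid_pts) + 1),
                       residue_id = seq_len(nrow(grid_pts) + 1),
                       residue_name = "X",
                       role = c(rep("receptor", nrow(grid_pts)), "ligand"),
                       mass = 10, charge = 0, lj_sigma = 3, lj_epsilon = 0)
  sys2 <- cg_system(beads2, rbind(grid_pts, c(70, 70, 70)), box = 80,
                    site_residues = 1, ligand_residues = nrow(grid_pts) + 1)
  expect_equal(pocket_volume(sys2$coords, sys2, center, radius = 5,
                             spacing = 0.5), 0)

  expect_error(pocket_volume(sys$coords, sys, c(2, 2, 2), radius = 5),
               "outside the box")
  expect_error(pocket_volume(sys$coords, sys, center, spacing = 0), "spacing")
})

test_that("occupancy counts static and intermittent beads exactly", {
  beads <- data.frame(id = 1:5, residue_id = 1:5, residue_name = "X",
                      role = c(rep("receptor", 3), "ligand", "solvent"),
                      mass = 10, charge = 0, lj_sigma = 3, lj_epsilon = 0)
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(10, 10, 10),
                c(2.5, 2.5, 2.5))
  sys <- cg_system(beads, base, site_residues = 1, ligand_residues = 4)

  # static bead at a voxel centre across 100 frames: occupancy 1 there, 0
  # everywhere else
  tr <- traj_from_frames(rep(list(base), 100))
  g <- water_occupancy_map(tr, sys, origin = c(0, 0, 0), dims = c(5, 5, 5),
                           spacing = 1, align = FALSE)
  expect_equal(g$occupancy[3, 3, 3], 1)
  expect_equal(sum(g$occupancy), 1)

  # present 10 of 100 frames: occupancy exactly 0.10
  away <- base
  away[5, ] <- c(-50, -50, -50)
  frames <- c(rep(list(base), 10), rep(list(away), 90))
  tr2 <- traj_from_frames(frames)
  g2 <- water_occupancy_map(tr2, sys, origin = c(0, 0, 0), dims = c(5, 5, 5),
                            spacing = 1, align = FALSE)
  expect_equal(g2$occupancy[3, 3, 3], 0.10)

  # occupancy is invariant under frame reordering
  tr3 <- traj_from_frames(frames[c(51:100, 1:50)])
  g3 <- water_occupancy_map(tr3, sys, origin = c(0, 0, 0), dims = c(5, 5, 5),
                            spacing = 1, align = FALSE)
  expect_identical(g2$occupancy, g3$occupancy)

  nosol <- cg_system(beads[1:4, ], base[1:4, ], site_residues = 1,
                     ligand_residues = 4)
  expect_error(water_occupancy_map(traj_from_frames(list(base[1:4, ])),
                                   nosol), "solvent")
})

test_that("the voxel mean occupancy matches a global recount", {
  beads <- data.frame(id = 1:6, residue_id = 1:6, residue_name = "X",
                      role = c(rep("receptor", 2), "ligand",
                               rep("solvent", 3)),
                      mass = 10, charge = 0, lj_sigma = 3, lj_epsilon = 0)
  set.seed(13)
  frames <- lapply(1:40, function(f) {
    X <- rbind(c(0, 0, 0), c(5, 0, 0), c(20, 20, 20),
               matrix(runif(9, 0, 5), ncol = 3))
    X
  })
  sys <- cg_system(beads, frames[[1]], site_residues = 1,
                   ligand_residues = 3)
  g <- water_occupancy_map(traj_from_frames(frames), sys,
                           origin = c(0, 0, 0), dims = c(5, 5, 5),
                           spacing = 1, align = FALSE)
  # independent recount of frame-voxel occupations
  occ_events <- 0L
  for (X in frames) {
    ix <- unique(floor(X[4:6, , drop = FALSE])) # spacing 1, origin 0
    keep <- ix[apply(ix >= 0 & ix <= 4, 1, all), , drop = FALSE]
    occ_events <- occ_events + nrow(unique(keep))
  }
  expect_equal(mean(g$occupancy), occ_events / (40 * 125))
  expect_true(all(g$occupancy >= 0 & g$occupancy <= 1))
})

test_that("hotspot extraction applies a strict threshold with stable order", {
  g <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(4, 4, 4),
                      occupancy = array(0, c(4, 4, 4)), n_frames = 100),
                 class = "occupancy_grid")
  g$occupancy[2, 3, 1] <- 0.5
  h <- hotspots(g, 0.10)
  expect_equal(nrow(h), 1)
  expect_equal(unlist(h[1, c("i", "j", "k")], use.names = FALSE), c(2, 3, 1))
  expect_equal(h$x, 1.5)
  expect_equal(h$occupancy, 0.5)

  # a voxel at exactly the threshold is excluded
  g$occupancy[1, 1, 1] <- 0.10
  expect_equal(nrow(hotspots(g, 0.10)), 1)

  g0 <- g
  g0$occupancy[] <- 0
  expect_equal(nrow(hotspots(g0, 0)), 0)
  expect_error(hotspots(g, 1), "threshold")
})

test_that("planted high-residence sites are recovered with no false positives", {
  # 3 planted sites occupied 60% of frames; diffuse background beads
  dims <- c(8, 8, 8)
  planted <- rbind(c(2, 2, 2), c(6, 3, 5), c(4, 7, 7))
  n_back <- 4
  n_fr <- 100
  beads <- data.frame(
    id = 1:(2 + 3 + n_back),
    residue_id = 1:(2 + 3 + n_back), residue_name = "X",
    role = c("receptor", "ligand", rep("solvent", 3 + n_back)),
    mass = 10, charge = 0, lj_sigma = 3, lj_epsilon = 0)
  set.seed(41)
  frames <- lapply(seq_len(n_fr), function(f) {
    pl <- t(vapply(1:3, function(k) {
      if (f %% 10 < 6) planted[k, ] - 0.5 else c(-40, -40, -40)
    }, numeric(3)))
    bg <- matrix(runif(3 * n_back, 0, 8), ncol = 3)
    rbind(c(-20, 0, 0), c(30, 0, 0), pl, bg)
  })
  sys <- cg_system(beads, frames[[1]], site_residues = 1,
                   ligand_residues = 2)
  g <- water_occupancy_map(traj_from_frames(frames), sys,
                           origin = c(0, 0, 0), dims = dims, spacing = 1,
                           align = FALSE)
  h <- hotspots(g, 0.10)
  found <- as.matrix(h[, c("i", "j", "k")])
  expect_equal(nrow(found), 3)
  expect_setequal(apply(found, 1, paste, collapse = ","),
                  apply(planted, 1, paste, collapse = ","))
})
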
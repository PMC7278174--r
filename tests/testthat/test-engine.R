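test_that("pair potentials reproduce their closed forms", {
  s <- 3.2
  eps <- 0.47
  expect_equal(lj_energy(s, s, eps), 0)
  expect_equal(lj_energy(2^(1 / 6) * s, s, eps), -eps)
  expect_equal(lj_energy(9, s, eps, cutoff = 9), 0)
  expect_equal(lj_energy(8.999, s, eps, cutoff = 9),
               4 * eps * ((s / 8.999)^12 - (s / 8.999)^6))
  expect_error(lj_energy(0, s, eps), "r must be > 0")

  expect_equal(coulomb_energy(1, 1, 1), 332.0637)
  expect_equal(coulomb_energy(2, 1, -1), -166.03185)
  expect_equal(coulomb_energy(9, 2, 3, cutoff = 9), 0)
  expect_equal(coulomb_energy(1, 1, 1, dielectric = 80), 332.0637 / 80)
  expect_error(coulomb_energy(-1, 1, 1), "r must be > 0")
})

test_that("analytic forces agree with the finite-difference gradient", {
  for (seed in 1:4) {
    box <- if (seed %% 2 == 0) 30 else NULL
    sys <- random_small_system(12 + seed, seed, box = box)
    cfg <- engine_config(dielectric = 1,
                         restraints = list(restraint(1:3, 2.5,
                                                     sys$coords[1:3, ])))
    ff <- compute_forces(sys, sys$coords, cfg)
    U <- function(x) compute_forces(sys, matrix(x, ncol = 3), cfg)$energy$total
    x0 <- as.vector(sys$coords)
    h <- 1e-5
    g <- vapply(seq_along(x0), function(i) {
      xp <- x0; xm <- x0
      xp[i] <- xp[i] + h
      xm[i] <- xm[i] - h
      (U(xp) - U(xm)) / (2 * h)
    }, numeric(1))
    fnum <- -matrix(g, ncol = 3)
    rel <- sqrt(sum((ff$forces - fnum)^2)) / sqrt(sum(fnum^2))
    expect_lt(rel, 1e-4)
  }
})

test_that("pair forces vanish at the LJ minimum and sum to zero overall", {
  s <- 3.0
  beads <- data.frame(id = 1:2, residue_id = 1:2, residue_name = "X",
                      role = c("receptor", "ligand"), mass = 10, charge = 0,
                      lj_sigma = s, lj_epsilon = 0.5)
  coords <- rbind(c(0, 0, 0), c(2^(1 / 6) * s, 0, 0))
  sys <- cg_system(beads, coords, site_residues = 1, ligand_residues = 2)
  f <- compute_forces(sys, coords, engine_config(dielectric = 1))
  expect_lt(max(abs(f$forces)), 1e-8)
  expect_equal(f$energy$lj, -0.5)

  sys2 <- random_small_system(15, 99)
  f2 <- compute_forces(sys2, sys2$coords, engine_config(dielectric = 1))
  expect_lt(max(abs(colSums(f2$forces))), 1e-8)
})

test_that("overlapping beads raise an error naming the pair", {
  sys <- tiny_stub_system()
  bad <- sys$coords
  bad[5, ] <- bad[1, ] + c(0.05, 0, 0)
  expect_error(compute_forces(sys, bad), "overlap")
})

test_that("zero friction and zero temperature give exact ballistic motion", {
  beads <- data.frame(id = 1, residue_id = 1, residue_name = "X",
                      role = "ligand", mass = 12, charge = 0,
                      lj_sigma = 3, lj_epsilon = 0)
  # a second, distant receptor bead so selections validate
  beads <- rbind(beads, transform(beads, id = 2, residue_id = 2,
                                  role = "receptor"))
  coords <- rbind(c(0, 0, 0), c(50, 0, 0))
  sys <- cg_system(beads, coords, site_residues = 2, ligand_residues = 1)
  st <- sim_state(sys, seed = 1, temperature = 0)
  st$velocities <- rbind(c(1.5, -0.5, 2), c(0, 0, 0))
  cfg <- engine_config(temperature = 0, friction = 0, save_interval = 0.1,
                       dielectric = 1)
  res <- langevin_segment(sys, st, 1, cfg)
  expect_equal(traj_frame(res$segment, 10)[1, ], c(0, 0, 0) + c(1.5, -0.5, 2),
               tolerance = 1e-12)
  expect_equal(res$state$coords[1, ], c(1.5, -0.5, 2), tolerance = 1e-12)
})

test_that("a restrained bead samples the equipartition positional variance", {
  beads <- data.frame(id = 1:2, residue_id = 1:2, residue_name = "X",
                      role = c("ligand", "receptor"), mass = 30, charge = 0,
                      lj_sigma = 3, lj_epsilon = 0)
  coords <- rbind(c(0, 0, 0), c(50, 0, 0))
  sys <- cg_system(beads, coords, site_residues = 2, ligand_residues = 1)
  k <- 1
  cfg <- engine_config(save_interval = 0.1, dielectric = 1,
                       restraints = list(restraint(1:2, k, coords)))
  st <- sim_state(sys, seed = 3)
  res <- langevin_segment(sys, st, 600, cfg)
  v <- mean(vapply(1:3, function(d) var(res$segment$frames[, 1, d]),
                   numeric(1)))
  expect_equal(v, 0.0019872041 * 310 / k, tolerance = 0.15)
})

test_that("segments are bitwise deterministic given the RNG token", {
  sys <- build_funnel_system(scenario_config(seed = 3))
  cfg <- default_funnel_engine_config(sys)
  st <- sim_state(sys, seed = 42)
  a <- langevin_segment(sys, st, 2, cfg)
  b <- langevin_segment(sys, st, 2, cfg)
  expect_identical(a$segment$frames, b$segment$frames)
  expect_identical(a$state$velocities, b$state$velocities)
  # and the per-frame energy terms are finite with consistent bookkeeping
  en <- a$segment$energies
  expect_true(all(is.finite(as.matrix(en))))
})

test_that("instantaneous temperature inverts the kinetic-energy definition", {
  expect_equal(instantaneous_temperature(matrix(0, 5, 3), rep(10, 5)), 0)
  # one bead, hand formula m v^2 / (3 kB) with the AKMA conversion
  v <- c(1.2, -0.3, 0.7)
  m <- 42
  hand <- m * sum(v^2) / 418.4 / (3 * 0.0019872041)
  expect_equal(instantaneous_temperature(matrix(v, 1, 3), m), hand)
  # velocities scaled so KE = (3/2) N kB 310 give exactly 310 K
  n <- 8
  vel <- matrix(rnorm(3 * n), n, 3)
  masses <- runif(n, 10, 50)
  ke <- 0.5 * sum(masses * rowSums(vel^2)) / 418.4
  target <- 1.5 * n * 0.0019872041 * 310
  vel <- vel * sqrt(target / ke)
  expect_equal(instantaneous_temperature(vel, masses), 310)
  expect_error(instantaneous_temperature(matrix(0, 0, 3), numeric(0)),
               "no beads")
})

test_that("staged equilibration runs stages in order and logs them", {
  sys <- build_funnel_system(scenario_config(seed = 5))
  cfg <- engine_config(save_interval = 0.1)
  st <- sim_state(sys, seed = 9)
  schedule <- default_equilibration_schedule(sys, durations = c(1, 1, 1, 1))
  out <- run_staged_equilibration(sys, st, schedule, cfg)
  log <- attr(out, "stages")
  expect_equal(nrow(log), 4)
  expect_equal(log$label, c("restrain-all", "restrain-receptor",
                            "restrain-site", "free"))
  expect_true(all(is.finite(log$mean_T)))

  # a zero-duration stage leaves the state untouched
  out0 <- run_staged_equilibration(sys, st,
                                   list(list(duration = 0)), cfg)
  expect_identical(out0$coords, st$coords)
  expect_identical(out0$velocities, st$velocities)
  expect_error(run_staged_equilibration(sys, st,
                                        list(list(duration = -1)), cfg),
               "negative")
})

test_that("tight restraints hold every bead near its reference", {
  sys <- build_funnel_system(scenario_config(seed = 6))
  all_idx <- seq_len(nrow(sys$beads))
  cfg <- engine_config(save_interval = 0.1,
                       restraints = list(restraint(all_idx, 100,
                                                   sys$coords)))
  st <- sim_state(sys, seed = 10)
  final <- run_staged_equilibration(
    sys, st, list(list(duration = 5,
                       restraints = cfg$restraints)), cfg)
  disp <- final$coords - sys$coords
  rmsd <- sqrt(mean(rowSums(disp^2)))
  # equipartition bound: sqrt(3 kB T / k) ~ 0.14 A at k = 100
  expect_lt(rmsd, 0.5)
})
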
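# Fixtures built in code: tiny systems, random parameterised systems, and
# scripted stub engines satisfying the supervisor's segment contract.

# Four receptor beads (the binding site) around the origin plus a one-bead
# ligand; used to exercise the supervisor with stub engines.
tiny_stub_system <- function(ligand_x = 12) {
  beads <- data.frame(
    id = 1:5,
    residue_id = c(1, 1, 1, 1, 2),
    residue_name = c(rep("POC", 4), "LIG"),
    role = c(rep("receptor", 4), "ligand"),
    mass = 10, charge = 0, lj_sigma = 3, lj_epsilon = 0.1)
  coords <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(ligand_x, 0, 0))
  cg_system(beads, coords, site_residues = 1, ligand_residues = 2)
}

# Engine stub whose ligand-site centroid distance follows distance_fn(t)
# (t = absolute accepted-trajectory time, ps); all other beads stay put.
stub_engine_from_distance <- function(distance_fn) {
  function(system, state, duration, config) {
    nf <- as.integer(round(duration / config$save_interval))
    times <- state$time + config$save_interval * seq_len(nf)
    site_c <- mass_weighted_centroid(system$coords,
                                     residue_beads(system,
                                                   system$site_residues),
                                     system$beads$mass)
    lig <- residue_beads(system, system$ligand_residues)
    nb <- nrow(system$beads)
    frames <- array(NA_real_, c(nf, nb, 3))
    for (f in seq_len(nf)) {
      X <- state$coords
      X[lig, ] <- matrix(site_c + c(distance_fn(times[f]), 0, 0),
                         nrow = length(lig), ncol = 3, byrow = TRUE)
      frames[f, , ] <- X
    }
    final <- matrix(frames[nf, , ], ncol = 3)
    new_state <- structure(list(coords = final,
                                velocities = state$velocities + 1,
                                time = state$time + duration,
                                rng_state = state$rng_state),
                           class = "sim_state")
    list(segment = cg_trajectory(frames, times), state = new_state)
  }
}

# Engine stub replaying a list of per-window distance series (one series
# per call, in order, regardless of accept/retry decisions).
stub_engine_from_series <- function(series_list) {
  counter <- new.env()
  counter$i <- 0L
  function(system, state, duration, config) {
    counter$i <- counter$i + 1L
    d <- series_list[[counter$i]]
    nf <- length(d)
    times <- state$time + (duration / nf) * seq_len(nf)
    site_c <- mass_weighted_centroid(system$coords,
                                     residue_beads(system,
                                                   system$site_residues),
                                     system$beads$mass)
    lig <- residue_beads(system, system$ligand_residues)
    nb <- nrow(system$beads)
    frames <- array(NA_real_, c(nf, nb, 3))
    for (f in seq_len(nf)) {
      X <- state$coords
      X[lig, ] <- matrix(site_c + c(d[f], 0, 0),
                         nrow = length(lig), ncol = 3, byrow = TRUE)
      frames[f, , ] <- X
    }
    new_state <- structure(list(coords = matrix(frames[nf, , ], ncol = 3),
                                velocities = state$velocities,
                                time = state$time + duration,
                                rng_state = state$rng_state),
                           class = "sim_state")
    list(segment = cg_trajectory(frames, times), state = new_state)
  }
}

# Random small system with bonds, charges and mixed LJ parameters; beads
# are pushed apart until no pair is closer than 2.2 A.
random_small_system <- function(n, seed, box = NULL) {
  set.seed(seed)
  beads <- data.frame(
    id = seq_len(n), residue_id = seq_len(n), residue_name = "X",
    role = c(rep("receptor", n - 2), "ligand", "ligand"),
    mass = runif(n, 10, 80), charge = round(runif(n, -1, 1), 2),
    lj_sigma = runif(n, 2.4, 3.4), lj_epsilon = runif(n, 0, 0.8))
  span <- if (is.null(box)) 14 else box
  coords <- matrix(runif(3 * n, 2, span - 2), ncol = 3)
  for (it in 1:500) {
    d <- as.matrix(dist(coords))
    diag(d) <- Inf
    if (min(d) > 2.2) break
    bad <- which(d < 2.2, arr.ind = TRUE)[1, ]
    coords[bad[1], ] <- 2 + (coords[bad[1], ] + runif(3, -1.5, 1.5) - 2) %%
      (span - 4)
  }
  bonds <- data.frame(i = n - 1, j = n, k = 80, r0 = 1.6)
  coords[n, ] <- coords[n - 1, ] + c(1.6, 0, 0)
  cg_system(beads, coords, bonds = bonds, box = box,
            site_residues = 1, ligand_residues = c(n - 1, n))
}

# Hand-written textbook covariance-formula slope, the independent oracle
# for the window-acceptance decision.
oracle_slope <- function(t, d) {
  tm <- mean(t)
  dm <- mean(d)
  sum((t - tm) * (d - dm)) / sum((t - tm)^2)
}

# Static trajectory from a list of coordinate matrices.
traj_from_frames <- function(frames, times = seq_along(frames)) {
  nb <- nrow(frames[[1]])
  arr <- array(NA_real_, c(length(frames), nb, 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  cg_trajectory(arr, times)
}
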
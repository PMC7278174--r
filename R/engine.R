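# R-side surface of the coarse-grained NVT Langevin engine.  The pairwise
# force field and the BAOAB integrator live in src/engine.cpp; everything
# here validates inputs, threads the RNG token, and shapes results.

#' Engine configuration
#'
#' @param dt integration time step (ps).
#' @param temperature thermostat target (K).
#' @param friction Langevin friction coefficient (1/ps).
#' @param cutoff nonbonded cutoff with plain truncation (A); applied to both
#'   Lennard-Jones and Coulomb terms.
#' @param save_interval interval between saved frames (ps); must be a
#'   multiple of `dt`.
#' @param dielectric relative permittivity dividing the Coulomb constant.
#'   The default of 80 is the implicit-aqueous-screening choice appropriate
#'   for a coarse-grained model whose solvent (when present) carries no
#'   charges; set to 1 for bare electrostatics.
#' @param restraints list of positional restraints, each created with
#'   [restraint()]; potential `1/2 k |x - ref|^2` per bead.
#' @param frozen integer bead indices excluded from integration (exact rigid
#'   limit).  Frozen-frozen pair interactions, a constant of the motion, are
#'   omitted from the reported energy terms.
#' @param overlap_floor hard floor on pair distances (A); closer approaches
#'   raise an error naming the pair.
#' @return A validated list of class `engine_config`.
#' @export
engine_config <- function(dt = 0.002, temperature = 310, friction = 1,
                          cutoff = 9, save_interval = 0.1, dielectric = 80,
                          restraints = list(), frozen = integer(0),
                          overlap_floor = 0.1) {
  if (dt <= 0) stop("dt must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (friction < 0) stop("friction must be >= 0")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (dielectric <= 0) stop("dielectric must be > 0")
  n_sub <- save_interval / dt
  if (save_interval <= 0 || abs(n_sub - round(n_sub)) > 1e-8)
    stop("save_interval must be a positive multiple of dt")
  cfg <- list(dt = dt, temperature = temperature, friction = friction,
              cutoff = cutoff, save_interval = save_interval,
              dielectric = dielectric, restraints = restraints,
              frozen = as.integer(frozen), overlap_floor = overlap_floor)
  class(cfg) <- "engine_config"
  cfg
}

#' Positional restraint
#'
#' @param sel integer bead indices.
#' @param k force constant (kcal/mol/A^2); potential `1/2 k |x - ref|^2`.
#' @param ref reference coordinates, `length(sel)` x 3 (A).
#' @return A restraint descriptor for [engine_config()].
#' @export
restraint <- function(sel, k, ref) {
  sel <- as.integer(sel)
  ref <- as.matrix(ref)
  if (nrow(ref) != length(sel)) stop("restraint ref must match sel length")
  if (k < 0) stop("restraint k must be >= 0")
  list(sel = sel, k = k, ref = ref)
}

.flatten_restraints <- function(restraints) {
  if (length(restraints) == 0)
    return(list(idx = integer(0), k = numeric(0),
                ref = matrix(0, 0, 3)))
  idx <- unlist(lapply(restraints, `[[`, "sel"))
  k <- unlist(lapply(restraints, function(r) rep(r$k, length(r$sel))))
  ref <- do.call(rbind, lapply(restraints, `[[`, "ref"))
  list(idx = as.integer(idx), k = as.numeric(k), ref = ref)
}

.check_cutoff <- function(sys, config) {
  if (config$cutoff <= max(sys$beads$lj_sigma))
    stop("cutoff must exceed the largest LJ sigma in the system")
}

#' Lennard-Jones 12-6 pair energy with plain truncation
#'
#' `4 eps ((sigma/r)^12 - (sigma/r)^6)` below the cutoff, 0 beyond.
#' Vectorised over `r`.
#'
#' @param r pair distance(s) (A); must be > 0.
#' @param sigma LJ sigma (A).
#' @param epsilon LJ well depth (kcal/mol).
#' @param cutoff truncation distance (A).
#' @return Energy (kcal/mol).
#' @export
#' @examples
#' lj_energy(2^(1 / 6) * 3, 3, 0.5) # the analytic minimum, -0.5
lj_energy <- function(r, sigma, epsilon, cutoff = 9) {
  if (any(r <= 0)) stop("r must be > 0")
  s6 <- (sigma / r)^6
  e <- 4 * epsilon * (s6^2 - s6)
  e[r >= cutoff] <- 0
  e
}

#' Coulomb pair energy with plain truncation
#'
#' `332.0637 q1 q2 / (dielectric r)` below the cutoff, 0 beyond.
#' Vectorised over `r`.
#'
#' @param r pair distance(s) (A); must be > 0.
#' @param q1,q2 charges (e).
#' @param cutoff truncation distance (A).
#' @param dielectric relative permittivity.
#' @return Energy (kcal/mol).
#' @export
#' @examples
#' coulomb_energy(1, 1, 1) # the Coulomb constant in these units
coulomb_energy <- function(r, q1, q2, cutoff = 9, dielectric = 1) {
  if (any(r <= 0)) stop("r must be > 0")
  e <- .coulomb_k * q1 * q2 / (dielectric * r)
  e[r >= cutoff] <- 0
  e
}

#' Forces and potential-energy terms of a configuration
#'
#' Analytic negative gradient of the total potential (bonds, Lennard-Jones,
#' Coulomb, positional restraints), with the minimum-image convention when
#' the system has a box.  All pairs are included regardless of
#' `config$frozen` (freezing is an integrator concern).
#'
#' @param system a `cg_system`.
#' @param coords N x 3 coordinates (A); defaults to the system's reference
#'   coordinates.
#' @param config an [engine_config()].
#' @return List with `forces` (N x 3, kcal/mol/A) and `energy` (named list:
#'   `bond`, `lj`, `coulomb`, `restraint`, `total`).
#' @export
compute_forces <- function(system, coords = system$coords,
                           config = engine_config()) {
  coords <- as.matrix(coords)
  if (nrow(coords) != n_beads(system) || ncol(coords) != 3)
    stop("coords shape does not match the system bead count")
  .check_cutoff(system, config)
  b <- system$beads
  bonds <- .bond_indices(system)
  rs <- .flatten_restraints(config$restraints)
  out <- cpp_forces(coords, b$mass, b$charge, b$lj_sigma, b$lj_epsilon,
                    bonds$i, bonds$j, bonds$k, bonds$r0,
                    if (is.null(system$box)) -1 else system$box,
                    config$cutoff, .coulomb_k / config$dielectric,
                    rs$idx, rs$k, rs$ref,
                    rep(FALSE, n_beads(system)), FALSE,
                    config$overlap_floor)
  energy <- list(bond = out$e_bond, lj = out$e_lj, coulomb = out$e_coul,
                 restraint = out$e_restraint)
  energy$total <- energy$bond + energy$lj + energy$coulomb + energy$restraint
  list(forces = out$forces, energy = energy)
}

# bonds as positional (row) indices
.bond_indices <- function(system) {
  bd <- system$bonds
  if (nrow(bd) == 0)
    return(list(i = integer(0), j = integer(0), k = numeric(0),
                r0 = numeric(0)))
  pos <- match(c(bd$i, bd$j), system$beads$id)
  list(i = as.integer(pos[seq_len(nrow(bd))]),
       j = as.integer(pos[nrow(bd) + seq_len(nrow(bd))]),
       k = as.numeric(bd$k), r0 = as.numeric(bd$r0))
}

#' Maxwell-Boltzmann velocities
#'
#' Independent normal components with variance `kB T / m` (in kcal/mol and
#' amu, converted to A/ps).
#'
#' @param masses bead masses (amu).
#' @param temperature target temperature (K).
#' @return `length(masses)` x 3 matrix of velocities (A/ps).  Draws from the
#'   current RNG stream.
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  sdv <- sqrt(.kB * temperature * .akma / masses)
  matrix(rnorm(3 * n, 0, rep(sdv, 3)), nrow = n)
}

#' Initial simulation state
#'
#' Coordinates from the system, Maxwell-Boltzmann velocities at
#' `temperature`, time 0, and a captured RNG token so all subsequent
#' dynamics are deterministic given `seed`.
#'
#' @param system a `cg_system`.
#' @param seed integer seed.
#' @param temperature velocity-initialisation temperature (K).
#' @return Object of class `sim_state` with fields `coords`, `velocities`,
#'   `time`, `rng_state`.
#' @export
sim_state <- function(system, seed = 1, temperature = 310) {
  res <- rng_eval(seed, function() {
    maxwell_velocities(system$beads$mass, temperature)
  })
  structure(list(coords = system$coords, velocities = res$value,
                 time = 0, rng_state = res$rng),
            class = "sim_state")
}

#' Instantaneous kinetic temperature
#'
#' `T = 2 KE / (3 N kB)` with `KE = 1/2 sum m v^2` (AKMA unit conversion
#' applied).
#'
#' @param velocities N x 3 velocities (A/ps).
#' @param masses N bead masses (amu).
#' @return Temperature (K).
#' @export
instantaneous_temperature <- function(velocities, masses) {
  velocities <- as.matrix(velocities)
  n <- nrow(velocities)
  if (n == 0) stop("no beads: temperature undefined")
  if (length(masses) != n) stop("masses do not match velocities")
  ke <- 0.5 * sum(masses * rowSums(velocities^2)) / .akma
  2 * ke / (3 * n * .kB)
}

#' Propagate one Langevin trajectory segment
#'
#' BAOAB splitting of underdamped Langevin dynamics at the configured
#' temperature and friction.  Deterministic given `state$rng_state`.
#'
#' @param system a `cg_system`.
#' @param state a [sim_state()].
#' @param duration segment length (ps); must be a multiple of
#'   `config$save_interval`.
#' @param config an [engine_config()].
#' @return List with `segment` (a `cg_trajectory` carrying `frames`, `times`
#'   and a per-frame `energies` data.frame with columns `time_ps`, `E_bond`,
#'   `E_lj`, `E_coul`, `E_restraint`, `T_inst`) and `state` (the advanced
#'   [sim_state()]).
#' @export
langevin_segment <- function(system, state, duration, config = engine_config()) {
  .check_cutoff(system, config)
  n_frames <- duration / config$save_interval
  if (duration <= 0 || abs(n_frames - round(n_frames)) > 1e-6)
    stop("duration must be a positive multiple of save_interval")
  n_frames <- as.integer(round(n_frames))
  save_every <- as.integer(round(config$save_interval / config$dt))
  n_steps <- n_frames * save_every
  b <- system$beads
  bonds <- .bond_indices(system)
  rs <- .flatten_restraints(config$restraints)
  frozen <- rep(FALSE, n_beads(system))
  frozen[config$frozen] <- TRUE

  res <- rng_eval(state$rng_state, function() {
    cpp_segment(state$coords, state$velocities,
                b$mass, b$charge, b$lj_sigma, b$lj_epsilon,
                bonds$i, bonds$j, bonds$k, bonds$r0,
                if (is.null(system$box)) -1 else system$box,
                config$cutoff, .coulomb_k / config$dielectric,
                rs$idx, rs$k, rs$ref, frozen, config$overlap_floor,
                config$dt, n_steps, save_every,
                config$temperature, config$friction, state$time)
  })
  out <- res$value
  times <- state$time + config$save_interval * seq_len(n_frames)
  energies <- data.frame(time_ps = out$energies[, 1],
                         E_bond = out$energies[, 2],
                         E_lj = out$energies[, 3],
                         E_coul = out$energies[, 4],
                         E_restraint = out$energies[, 5],
                         T_inst = out$energies[, 6])
  segment <- cg_trajectory(out$frames, times, energies = energies)
  new_state <- structure(list(coords = out$coords,
                              velocities = out$velocities,
                              time = state$time + duration,
                              rng_state = res$rng),
                         class = "sim_state")
  list(segment = segment, state = new_state)
}

#' Steepest-descent pre-relaxation
#'
#' A simple displacement-capped steepest descent to remove bad contacts
#' before dynamics; not a full minimiser.
#'
#' @param system a `cg_system`.
#' @param coords starting coordinates; defaults to the system's.
#' @param n_steps number of descent steps.
#' @param max_step displacement cap per bead per step (A).
#' @param config an [engine_config()].
#' @return Relaxed N x 3 coordinates.
#' @export
relax_system <- function(system, coords = system$coords, n_steps = 200,
                         max_step = 0.1, config = engine_config()) {
  x <- as.matrix(coords)
  for (s in seq_len(n_steps)) {
    f <- compute_forces(system, x, config)$forces
    fn <- sqrt(rowSums(f^2))
    scale <- ifelse(fn > 0, pmin(max_step, 0.01 * fn) / pmax(fn, 1e-12), 0)
    x <- x + f * scale
  }
  x
}

#' Staged equilibration
#'
#' Runs an ordered schedule of NVT stages, each with its own positional
#' restraint set (the classic protocol: restrain everything, then the
#' receptor, then the binding site, then run free), logging per-stage mean
#' temperature and the RMSD of the mobile beads relative to the stage start.
#'
#' @param system a `cg_system`.
#' @param state a [sim_state()].
#' @param schedule list of stages, each a list with `duration` (ps),
#'   optional `restraints` (list of [restraint()]) and optional `label`.
#' @param config an [engine_config()]; its `restraints` are replaced
#'   stage-by-stage.
#' @return The final [sim_state()], with the per-stage log as attribute
#'   `"stages"` (data.frame: stage, label, duration_ps, mean_T, rmsd_A).
#' @export
run_staged_equilibration <- function(system, state, schedule,
                                     config = engine_config()) {
  if (length(schedule) == 0) stop("schedule must be non-empty")
  log <- data.frame(stage = integer(0), label = character(0),
                    duration_ps = numeric(0), mean_T = numeric(0),
                    rmsd_A = numeric(0))
  for (s in seq_along(schedule)) {
    st <- schedule[[s]]
    if (is.null(st$duration) || st$duration < 0)
      stop("stage ", s, " has a negative or missing duration")
    label <- if (is.null(st$label)) paste0("stage", s) else st$label
    if (st$duration == 0) {
      log <- rbind(log, data.frame(stage = s, label = label,
                                   duration_ps = 0, mean_T = NA_real_,
                                   rmsd_A = 0))
      next
    }
    cfg <- config
    cfg$restraints <- if (is.null(st$restraints)) list() else st$restraints
    start_coords <- state$coords
    res <- langevin_segment(system, state, st$duration, cfg)
    state <- res$state
    mobile <- setdiff(seq_len(n_beads(system)), cfg$frozen)
    disp <- state$coords[mobile, , drop = FALSE] -
      start_coords[mobile, , drop = FALSE]
    log <- rbind(log, data.frame(
      stage = s, label = label, duration_ps = st$duration,
      mean_T = mean(res$segment$energies$T_inst),
      rmsd_A = sqrt(mean(rowSums(disp^2)))))
  }
  attr(state, "stages") <- log
  state
}

#' Four-stage equilibration schedule for a funnel system
#'
#' Mirrors the classic staged protocol: restrain all beads, then only the
#' receptor, then only the binding-site lining, then free dynamics, all at
#' restraint strength `k`.
#'
#' @param system a funnel `cg_system`.
#' @param durations length-4 vector of stage durations (ps).
#' @param k restraint force constant (kcal/mol/A^2); the classic value is 1.
#' @return A schedule list for [run_staged_equilibration()].
#' @export
default_equilibration_schedule <- function(system, durations = c(5, 10, 5, 50),
                                           k = 1) {
  if (length(durations) != 4) stop("durations must have length 4")
  all_idx <- seq_len(n_beads(system))
  rec <- role_beads(system, "receptor")
  site <- site_beads(system)
  ref <- system$coords
  list(
    list(duration = durations[1], label = "restrain-all",
         restraints = list(restraint(all_idx, k, ref))),
    list(duration = durations[2], label = "restrain-receptor",
         restraints = list(restraint(rec, k, ref[rec, , drop = FALSE]))),
    list(duration = durations[3], label = "restrain-site",
         restraints = list(restraint(site, k, ref[site, , drop = FALSE]))),
    list(duration = durations[4], label = "free", restraints = list()))
}
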
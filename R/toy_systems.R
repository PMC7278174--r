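# Synthetic coarse-grained receptor-ligand scenario generators.
#
# The generators emulate, at desk scale, the binding scenarios an adaptive
# ligand-binding protocol is exercised on: a hollow receptor shell with one
# aperture (funnel) leading to a buried low-energy pocket, an optionally
# positively charged vestibule flanking the aperture, optional cryptic
# hydrophobic sub-pockets, optional solvent beads, and a short three-bead
# ligand placed 35 A from the receptor centroid along the aperture axis.

# geometry constants of the funnel scenario (radians)
.aperture_half_angle <- 40 * pi / 180
.vestibule_band <- c(40, 58) * pi / 180
.pocket_opening <- 80 * pi / 180     # forward cone removed from the lining
.shell_spacing <- 3.0                # target bead spacing on the shell (A)
.lining_spacing <- 2.6

#' Scenario configuration for the synthetic funnel systems
#'
#' Defaults define the standard funnel scenario: a rigid receptor shell of
#' radius `shell_radius` with a buried pocket of depth `pocket_depth`
#' (calibrated exactly, see [build_funnel_system()]), a neutral vestibule, no
#' cryptic sub-pockets, no solvent, and the ligand placed 35 A away from the
#' receptor centroid.
#'
#' @param pocket_depth minimum ligand-receptor interaction energy in the
#'   pocket, as a positive depth (kcal/mol).
#' @param pocket_radius radius of the sphere carrying the pocket-lining beads
#'   (A).
#' @param vestibule_charge total charge placed on the aperture-flanking beads
#'   (e); 0 gives the neutral variant.
#' @param n_cryptic_pockets number of cryptic sub-pocket cups carved next to
#'   the main pocket.
#' @param n_solvent number of solvent beads to scatter in the box.
#' @param placement_distance initial ligand-centroid to receptor-centroid
#'   distance (A); default 35.
#' @param ligand_charge charge on the receptor-facing terminal ligand bead
#'   (e); emulates a charged amine substituent.
#' @param box cubic box edge length (A); origin at the corner.
#' @param shell_radius receptor shell radius (A).
#' @param seed integer seed; generators are pure functions of config + seed.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(pocket_depth = 8, pocket_radius = 3.5,
                            vestibule_charge = 0, n_cryptic_pockets = 0,
                            n_solvent = 0, placement_distance = 35,
                            ligand_charge = 0, box = 80, shell_radius = 9,
                            seed = 1) {
  cfg <- list(pocket_depth = pocket_depth, pocket_radius = pocket_radius,
              vestibule_charge = vestibule_charge,
              n_cryptic_pockets = as.integer(n_cryptic_pockets),
              n_solvent = as.integer(n_solvent),
              placement_distance = placement_distance,
              ligand_charge = ligand_charge, box = box,
              shell_radius = shell_radius, seed = as.integer(seed))
  if (cfg$pocket_depth <= 0) stop("pocket_depth must be > 0")
  if (cfg$pocket_radius <= 0) stop("pocket_radius must be > 0")
  if (cfg$n_cryptic_pockets < 0 || cfg$n_solvent < 0)
    stop("counts must be >= 0")
  if (cfg$placement_distance <= cfg$pocket_radius)
    stop("placement_distance must exceed pocket_radius")
  if (cfg$box <= 2 * cfg$placement_distance * 1.05)
    stop("box too small for the requested placement distance")
  class(cfg) <- "scenario_config"
  cfg
}

# Near-uniform points on the unit sphere with polar axis +x.
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  polar <- acos(1 - 2 * i / n)
  azi <- pi * (1 + sqrt(5)) * i
  cbind(cos(polar), sin(polar) * cos(azi), sin(polar) * sin(azi))
}

.bead_row <- function(n, residue_id, residue_name, role, mass, charge,
                      sigma, eps) {
  data.frame(residue_id = residue_id, residue_name = residue_name,
             role = role, mass = mass, charge = charge, lj_sigma = sigma,
             lj_epsilon = eps)[rep(1, n), , drop = FALSE]
}

# group a run of beads into residues of size `per`, starting at id `from`
.group_residues <- function(n, per, from) {
  from + (seq_len(n) - 1) %/% per
}

#' Build the funnel receptor-ligand scenario
#'
#' Constructs a rigid hollow receptor shell with one conical aperture, a
#' buried pocket lined by attractive beads, optional cryptic sub-pocket cups
#' and an optional charged vestibule, plus a three-bead ligand placed
#' `placement_distance` A from the receptor centroid along the aperture axis
#' (+x).  The pocket depth is calibrated exactly: the ligand-receptor
#' Lennard-Jones energy is minimised over rigid ligand translations from the
#' pocket centre and all receptor epsilons are rescaled so the minimum equals
#' `-pocket_depth`.
#'
#' Deterministic given `config$seed` (the seed drives a small symmetry-breaking
#' jitter of the receptor beads and solvent placement).
#'
#' @param config a [scenario_config()].
#' @return A [cg_system()].  `meta` records the scenario, the tagged
#'   vestibule beads, cryptic-pocket centres, the aperture axis, the pocket
#'   centre and the calibration scale.
#' @export
#' @examples
#' sys <- build_funnel_system(scenario_config(seed = 7))
#' sys
build_funnel_system <- function(config = scenario_config()) {
  if (!inherits(config, "scenario_config")) config <- do.call(scenario_config, config)
  R <- config$shell_radius
  p <- config$pocket_radius
  sigma_rec <- 3.1
  if (p + 2.5 >= R)
    stop("pocket_radius ", p, " too large for shell of radius ", R,
         ": need pocket_radius + 2.5 < shell_radius")

  built <- rng_eval(config$seed, function() {
    # --- receptor shell with aperture ---
    n_shell <- max(40L, round(4 * pi * R^2 / .shell_spacing^2))
    u <- fib_sphere(n_shell)
    ang <- acos(pmin(1, pmax(-1, u[, 1])))     # angle from +x (aperture axis)
    keep <- ang > .aperture_half_angle
    u <- u[keep, , drop = FALSE]
    ang <- ang[keep]
    shell_xyz <- R * u + matrix(runif(3 * nrow(u), -0.05, 0.05), ncol = 3)
    vestibule <- ang > .vestibule_band[1] & ang <= .vestibule_band[2]

    # --- pocket lining: cup opening toward +x ---
    n_lin <- max(12L, round(4 * pi * p^2 / .lining_spacing^2))
    ul <- fib_sphere(n_lin)
    angl <- acos(pmin(1, pmax(-1, ul[, 1])))
    ul <- ul[angl >= .pocket_opening, , drop = FALSE]
    lining_xyz <- p * ul + matrix(runif(3 * nrow(ul), -0.05, 0.05), ncol = 3)

    # --- cryptic sub-pocket cups, perpendicular to the aperture axis ---
    cryptic_xyz <- NULL
    cryptic_centers <- NULL
    if (config$n_cryptic_pockets > 0) {
      dirs <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
      if (config$n_cryptic_pockets > nrow(dirs))
        stop("at most ", nrow(dirs), " cryptic pockets supported")
      cup_r <- 2.2
      for (k in seq_len(config$n_cryptic_pockets)) {
        d <- dirs[k, ]
        center <- d * (p + 3.2)
        uc <- fib_sphere(24L)
        # open the cup toward the main pocket (-d direction)
        facing <- drop(uc %*% d)
        uc <- uc[facing > -0.3, , drop = FALSE]
        cryptic_xyz <- rbind(cryptic_xyz,
                             sweep(cup_r * uc, 2, center, "+"))
        cryptic_centers <- rbind(cryptic_centers, center)
      }
    }
    list(shell_xyz = shell_xyz, vestibule = vestibule,
         lining_xyz = lining_xyz, cryptic_xyz = cryptic_xyz,
         cryptic_centers = cryptic_centers)
  })$value

  shell_xyz <- built$shell_xyz
  vestibule <- built$vestibule
  lining_xyz <- built$lining_xyz
  cryptic_xyz <- built$cryptic_xyz

  # drop cryptic beads clashing with existing receptor beads
  if (!is.null(cryptic_xyz)) {
    existing <- rbind(shell_xyz, lining_xyz)
    ok <- vapply(seq_len(nrow(cryptic_xyz)), function(i) {
      d2 <- rowSums(sweep(existing, 2, cryptic_xyz[i, ])^2)
      all(d2 > 2.0^2)
    }, logical(1))
    cryptic_xyz <- cryptic_xyz[ok, , drop = FALSE]
    if (nrow(cryptic_xyz) == 0) cryptic_xyz <- NULL
  }

  center <- rep(config$box / 2, 3)
  rec_local <- rbind(lining_xyz, shell_xyz, cryptic_xyz)
  rec_xyz <- sweep(rec_local, 2, center, "+")
  n_lining <- nrow(lining_xyz)
  n_shell_kept <- nrow(shell_xyz)
  n_cry <- if (is.null(cryptic_xyz)) 0L else nrow(cryptic_xyz)

  # --- bead table: pocket lining first, then shell, then cryptic ---
  res_lin <- .group_residues(n_lining, 3L, 1L)
  lin_beads <- .bead_row(n_lining, 0L, "POC", "receptor", 50, 0, sigma_rec, 1.0)
  lin_beads$residue_id <- res_lin

  res0 <- max(res_lin) + 1L
  shell_names <- ifelse(vestibule, "VST", "SHL")
  res_shell <- .group_residues(n_shell_kept, 4L, res0)
  shell_beads <- .bead_row(n_shell_kept, 0L, "SHL", "receptor", 50, 0,
                           sigma_rec, 0.05)
  shell_beads$residue_id <- res_shell
  shell_beads$residue_name <- shell_names

  beads <- rbind(lin_beads, shell_beads)
  if (n_cry > 0) {
    res1 <- max(res_shell) + 1L
    cry_beads <- .bead_row(n_cry, 0L, "CRY", "receptor", 50, 0, sigma_rec, 0.3)
    cry_beads$residue_id <- .group_residues(n_cry, 6L, res1)
    beads <- rbind(beads, cry_beads)
  }

  # --- ligand: 3 beads along the aperture axis ---
  rec_mass <- beads$mass
  rec_centroid <- colSums(rec_xyz * rec_mass) / sum(rec_mass)
  lig_res <- max(beads$residue_id) + 1L
  # xanthine-sized ligand: ~195 amu total over three beads
  lig_beads <- .bead_row(3L, lig_res, "LIG", "ligand", 65, 0, 3.0, 0.15)
  # receptor-facing terminal bead (smallest x) carries the optional charge
  lig_beads$charge <- c(config$ligand_charge, 0, 0)
  lig_local <- cbind(c(-1.5, 0, 1.5), 0, 0)
  lig_xyz <- sweep(lig_local, 2,
                   rec_centroid + c(config$placement_distance, 0, 0), "+")

  beads <- rbind(beads, lig_beads)
  coords <- rbind(rec_xyz, lig_xyz)
  beads$id <- seq_len(nrow(beads))
  rownames(beads) <- NULL

  lig_ids <- beads$id[beads$role == "ligand"]
  bonds <- data.frame(i = lig_ids[c(1, 2)], j = lig_ids[c(2, 3)],
                      k = 100, r0 = 1.5)

  sys <- cg_system(
    beads = beads, coords = coords, bonds = bonds, box = config$box,
    site_residues = sort(unique(res_lin)),
    ligand_residues = lig_res,
    meta = list(scenario = unclass(config),
                vestibule_beads = n_lining + which(vestibule),
                cryptic_centers = if (is.null(built$cryptic_centers)) NULL
                                  else sweep(built$cryptic_centers, 2, center, "+"),
                aperture_axis = c(1, 0, 0),
                pocket_center = center))

  # --- exact pocket-depth calibration ---
  cal <- .calibrate_pocket_depth(sys, config$pocket_depth)
  sys$beads$lj_epsilon[sys$beads$role == "receptor"] <-
    sys$beads$lj_epsilon[sys$beads$role == "receptor"] * cal$scale
  sys$meta$calibration <- cal

  if (config$vestibule_charge != 0)
    sys <- make_vestibule_variant(sys, config$vestibule_charge)
  if (config$n_solvent > 0)
    sys <- add_solvent(sys, config$n_solvent, seed = config$seed + 1L)
  validate_system(sys)
  sys
}

# Minimise the rigid-translation ligand-receptor LJ energy from the pocket
# centre and return the receptor-epsilon scale that maps the minimum onto
# -depth exactly.
.calibrate_pocket_depth <- function(sys, depth) {
  rec <- role_beads(sys, "receptor")
  lig <- ligand_beads(sys)
  lig_local <- sweep(sys$coords[lig, , drop = FALSE], 2,
                     colMeans(sys$coords[lig, , drop = FALSE]))
  rxyz <- sys$coords[rec, , drop = FALSE]
  sij <- outer(sys$beads$lj_sigma[lig], sys$beads$lj_sigma[rec], "+") / 2
  eij <- sqrt(outer(sys$beads$lj_epsilon[lig], sys$beads$lj_epsilon[rec]))
  energy_at <- function(pos) {
    lx <- sweep(lig_local, 2, pos, "+")
    e <- 0
    for (a in seq_len(nrow(lx))) {
      d2 <- rowSums(sweep(rxyz, 2, lx[a, ])^2)
      s2 <- sij[a, ]^2 / d2
      s6 <- s2^3
      term <- 4 * eij[a, ] * (s6^2 - s6)
      term[d2 >= 81] <- 0  # 9 A cutoff
      e <- e + sum(term)
    }
    e
  }
  opt <- optim(sys$meta$pocket_center, energy_at, method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-12))
  if (!is.finite(opt$value) || opt$value >= -1e-3)
    stop("pocket geometry infeasible: no attractive minimum found ",
         "(E_min = ", signif(opt$value, 4), " kcal/mol)")
  # pair energies carry sqrt(eps_receptor) through Lorentz-Berthelot
  # mixing, so rescaling receptor epsilons by s^2 scales the ligand
  # interaction energy by s exactly (at fixed geometry)
  list(scale = (depth / abs(opt$value))^2, min_pos = opt$par,
       min_energy_unscaled = opt$value)
}

#' Charged-vestibule variant of a funnel system
#'
#' Returns a copy of the system in which the beads flanking the aperture
#' (tagged `VST` by [build_funnel_system()]) carry a total charge of
#' `vestibule_charge`, split equally; coordinates and all other parameters
#' are unchanged.  Emulates positively charged extracellular-loop residues
#' repelling a charged ligand on its way into the pocket.
#'
#' @param system a funnel `cg_system`.
#' @param vestibule_charge total charge to place on the vestibule beads (e).
#' @return The modified `cg_system`.
#' @export
make_vestibule_variant <- function(system, vestibule_charge) {
  vb <- system$meta$vestibule_beads
  if (is.null(vb) || length(vb) == 0)
    stop("system has no aperture-flanking (vestibule) beads tagged")
  system$beads$charge[vb] <- vestibule_charge / length(vb)
  system$meta$vestibule_charge <- vestibule_charge
  validate_system(system)
  system
}

#' Scatter solvent beads into the box
#'
#' Places `n_solvent` solvent-role beads uniformly at random inside the box,
#' rejecting positions whose centre-centre distance to any existing bead is
#' below `0.8 * sigma_ij` (Lorentz mixing).  Deterministic given `seed`.
#'
#' @param system a `cg_system` with a box.
#' @param n_solvent number of beads to add.
#' @param seed integer seed.
#' @param max_tries_per_bead bound on rejection-sampling attempts per bead.
#' @return The augmented `cg_system`; errors (reporting how many beads were
#'   placed) if the box cannot accommodate them.
#' @export
add_solvent <- function(system, n_solvent, seed,
                        max_tries_per_bead = 200L) {
  n_solvent <- as.integer(n_solvent)
  if (n_solvent == 0) return(system)
  if (is.null(system$box)) stop("add_solvent requires a system with a box")
  sigma_sol <- 2.8
  res <- rng_eval(seed, function() {
    placed <- matrix(NA_real_, n_solvent, 3)
    coords <- system$coords
    sigmas <- system$beads$lj_sigma
    for (k in seq_len(n_solvent)) {
      ok <- FALSE
      for (try in seq_len(max_tries_per_bead)) {
        pos <- runif(3, 0, system$box)
        dmin2 <- rowSums(sweep(coords, 2, pos)^2)
        lim <- (0.8 * (sigmas + sigma_sol) / 2)^2
        if (all(dmin2 >= lim)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place solvent bead ", k, " of ", n_solvent,
             " without overlap (", k - 1, " placed)")
      placed[k, ] <- pos
      coords <- rbind(coords, pos)
      sigmas <- c(sigmas, sigma_sol)
    }
    placed
  })
  placed <- res$value
  res0 <- max(system$beads$residue_id) + 1L
  sol <- .bead_row(n_solvent, 0L, "SOL", "solvent", 18, 0, sigma_sol, 0.1)
  sol$residue_id <- res0 + seq_len(n_solvent) - 1L
  sol$id <- max(system$beads$id) + seq_len(n_solvent)
  system$beads <- rbind(system$beads, sol[names(system$beads)])
  system$coords <- rbind(system$coords, placed)
  rownames(system$beads) <- NULL
  validate_system(system)
  system
}
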
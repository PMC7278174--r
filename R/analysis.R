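# Trajectory analytics: distance profiles, per-residue interaction-energy
# decomposition, interaction-energy landscapes, RMSD and RMSF.

#' Ligand-site distance profile
#'
#' Distance between the mass-weighted centroids of the ligand and of the
#' binding site, one value per frame (minimum image when the system has a
#' box).
#'
#' @param trajectory a `cg_trajectory`.
#' @param system a `cg_system`.
#' @param centroid `"mass"` (default) or `"geometric"`.
#' @return data.frame with columns `time_ps`, `distance_A`.
#' @export
distance_profile <- function(trajectory, system, centroid = "mass") {
  if (is.null(trajectory) || n_frames(trajectory) == 0)
    stop("empty trajectory")
  data.frame(time_ps = trajectory$times,
             distance_A = .distance_series(trajectory, system, centroid))
}

#' Per-residue ligand interaction energies
#'
#' For every frame and receptor residue, the electrostatic and
#' Lennard-Jones interaction energies with the ligand, summed over all
#' (residue bead, ligand bead) pairs under plain cutoff truncation.  Summing
#' `E_elec + E_vdw` over residues within a frame reproduces the total
#' ligand-receptor nonbonded energy of that frame.
#'
#' @param trajectory a `cg_trajectory`.
#' @param system a `cg_system`.
#' @param cutoff nonbonded cutoff (A).
#' @param dielectric relative permittivity (match the engine run to make the
#'   decomposition reproduce the simulated energies).
#' @return data.frame of class `energy_table` with columns `frame`,
#'   `time_ps`, `residue_id`, `residue_name`, `E_elec`, `E_vdw` (kcal/mol).
#' @export
per_residue_interaction_energy <- function(trajectory, system, cutoff = 9,
                                           dielectric = 1) {
  b <- system$beads
  bad <- which(!stats::complete.cases(
    b[, c("mass", "charge", "lj_sigma", "lj_epsilon")]))
  if (length(bad) > 0)
    stop("missing force-field parameters for bead id ", b$id[bad[1]])
  lig <- ligand_beads(system)
  rec <- role_beads(system, "receptor")
  nf <- n_frames(trajectory)
  sij <- outer(b$lj_sigma[lig], b$lj_sigma[rec], "+") / 2
  eij <- sqrt(outer(b$lj_epsilon[lig], b$lj_epsilon[rec]))
  qq <- .coulomb_k * outer(b$charge[lig], b$charge[rec]) / dielectric
  box <- system$box
  res_ids <- b$residue_id[rec]
  ures <- sort(unique(res_ids))
  res_names <- b$residue_name[rec][match(ures, res_ids)]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    x <- traj_frame(trajectory, f)
    r2 <- matrix(0, length(lig), length(rec))
    for (d in 1:3) {
      dd <- outer(x[lig, d], x[rec, d], "-")
      if (!is.null(box)) dd <- dd - box * round(dd / box)
      r2 <- r2 + dd^2
    }
    r <- sqrt(r2)
    within <- r < cutoff
    elec <- ifelse(within & qq != 0, qq / r, 0)
    s6 <- (sij / r)^6
    vdw <- ifelse(within & eij > 0, 4 * eij * (s6^2 - s6), 0)
    pe <- colSums(elec)   # per receptor bead over ligand beads
    pv <- colSums(vdw)
    out[[f]] <- data.frame(
      frame = f, time_ps = trajectory$times[f], residue_id = ures,
      residue_name = res_names,
      E_elec = as.numeric(rowsum(pe, res_ids)[as.character(ures), ]),
      E_vdw = as.numeric(rowsum(pv, res_ids)[as.character(ures), ]))
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("energy_table", "data.frame")
  tab
}

#' Total ligand-receptor nonbonded energy per frame
#'
#' @param energy_table output of [per_residue_interaction_energy()].
#' @return data.frame with `frame`, `time_ps`, `E_total` (kcal/mol).
#' @export
total_interaction_energy <- function(energy_table) {
  agg <- rowsum(energy_table$E_elec + energy_table$E_vdw,
                energy_table$frame)
  frames <- as.integer(rownames(agg))
  data.frame(frame = frames,
             time_ps = energy_table$time_ps[match(frames,
                                                  energy_table$frame)],
             E_total = as.numeric(agg))
}

#' Interaction-energy landscape over the ligand-site distance
#'
#' Bins the per-frame total interaction energy by the ligand-site centroid
#' distance into half-open bins `[k w, (k+1) w)` and reports per-bin mean,
#' standard deviation and frame count; empty bins are omitted.
#'
#' @param distances per-frame centroid distances (A).
#' @param energies per-frame interaction energies (kcal/mol), same length.
#' @param bin_width bin width (A).
#' @return data.frame with `distance_lo`, `distance_hi`, `mean_energy`,
#'   `sd_energy` (0 for single-frame bins), `n_frames`.
#' @export
interaction_energy_landscape <- function(distances, energies, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (length(distances) != length(energies))
    stop("distances and energies must have equal length")
  if (length(distances) == 0) stop("empty series")
  k <- floor(distances / bin_width)
  ks <- sort(unique(k))
  out <- data.frame(
    distance_lo = ks * bin_width,
    distance_hi = (ks + 1) * bin_width,
    mean_energy = as.numeric(tapply(energies, factor(k, ks), mean)),
    sd_energy = as.numeric(tapply(energies, factor(k, ks), function(x)
      if (length(x) > 1) sd(x) else 0)),
    n_frames = as.integer(tapply(energies, factor(k, ks), length)))
  rownames(out) <- NULL
  out
}

# Kabsch rotation: R such that (centered P) %*% R best fits (centered Q)
.kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# superpose X onto ref using the fit selection; returns transformed X
.superpose <- function(X, ref, fit_sel) {
  cx <- colMeans(X[fit_sel, , drop = FALSE])
  cr <- colMeans(ref[fit_sel, , drop = FALSE])
  R <- .kabsch_rotation(sweep(X[fit_sel, , drop = FALSE], 2, cx),
                        sweep(ref[fit_sel, , drop = FALSE], 2, cr))
  sweep(sweep(X, 2, cx) %*% R, 2, cr, "+")
}

#' Per-frame RMSD against a reference structure
#'
#' @param trajectory a `cg_trajectory`.
#' @param reference N x 3 reference coordinates or a `cg_system` (its
#'   reference coordinates are used).
#' @param selection bead indices to compare (default: all).
#' @param superpose optimal rigid-body (Kabsch) superposition on the
#'   selection before measuring (default TRUE).
#' @return data.frame with `time_ps`, `rmsd_A`.
#' @export
rmsd_series <- function(trajectory, reference, selection = NULL,
                        superpose = TRUE) {
  ref <- if (inherits(reference, "cg_system")) reference$coords else
    as.matrix(reference)
  nb <- dim(trajectory$frames)[2]
  if (nrow(ref) != nb)
    stop("reference size does not match the trajectory")
  if (is.null(selection)) selection <- seq_len(nb)
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    X <- traj_frame(trajectory, f)
    if (superpose) X <- .superpose(X, ref, selection)
    sqrt(mean(rowSums((X[selection, , drop = FALSE] -
                         ref[selection, , drop = FALSE])^2)))
  }, numeric(1))
  data.frame(time_ps = trajectory$times, rmsd_A = vals)
}

#' Per-bead root-mean-square fluctuation
#'
#' RMS deviation of each selected bead from its time-average position,
#' after (optional) superposition of every frame onto the mean structure;
#' the fit selection can differ from the measured selection (e.g. fit on a
#' rigid core, measure flexible beads).
#'
#' @param trajectory a `cg_trajectory` with at least two frames.
#' @param selection bead indices to measure (default: all).
#' @param fit_selection bead indices used for the superposition fit
#'   (default: `selection`).
#' @param superpose apply Kabsch superposition (default TRUE).
#' @return data.frame with `bead`, `rmsf_A`.
#' @export
rmsf <- function(trajectory, selection = NULL, fit_selection = selection,
                 superpose = TRUE) {
  nf <- n_frames(trajectory)
  if (nf < 2) stop("RMSF needs at least two frames")
  nb <- dim(trajectory$frames)[2]
  if (is.null(selection)) selection <- seq_len(nb)
  if (is.null(fit_selection)) fit_selection <- selection
  frames <- lapply(seq_len(nf), function(f) traj_frame(trajectory, f))
  if (superpose) {
    ref <- frames[[1]]
    frames <- lapply(frames, .superpose, ref = ref, fit_sel = fit_selection)
    mean_xyz <- Reduce(`+`, frames) / nf
    frames <- lapply(frames, .superpose, ref = mean_xyz,
                     fit_sel = fit_selection)
  }
  mean_xyz <- Reduce(`+`, frames) / nf
  dev2 <- Reduce(`+`, lapply(frames, function(X)
    rowSums((X - mean_xyz)^2))) / nf
  data.frame(bead = selection, rmsf_A = sqrt(dev2[selection]))
}
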
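# Grid-based analyses: pocket volumetry and solvent-occupancy maps.
# Voxel membership is half-open per axis, [origin + i s, origin + (i+1) s),
# so voxels partition space without double counting.

#' Grid-based pocket volume
#'
#' Measures the free volume of a pocket as the number of grid points inside
#' an inclusion sphere that lie farther than `probe_radius + sigma/2` from
#' every receptor bead centre (sigma/2 acting as the bead radius), times the
#' grid-cell volume.
#'
#' @param coords N x 3 coordinates of one frame (A); defaults to the
#'   system's reference coordinates.
#' @param system a `cg_system`; only receptor beads occlude.
#' @param center inclusion-sphere centre (length-3, A); defaults to the
#'   pocket centre recorded by the generator, if any.
#' @param radius inclusion-sphere radius (A).
#' @param spacing grid spacing (A).
#' @param probe_radius probe radius (A); default 1.4, the classic water
#'   probe.
#' @return Pocket volume (A^3).
#' @export
pocket_volume <- function(coords = system$coords, system, center = NULL,
                          radius = 5, spacing = 0.5, probe_radius = 1.4) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (is.null(center)) center <- system$meta$pocket_center
  if (is.null(center)) stop("no inclusion center given or recorded")
  center <- as.numeric(center)
  if (!is.null(system$box) &&
      (any(center - radius < 0) || any(center + radius > system$box)))
    stop("inclusion sphere extends outside the box")
  ax <- lapply(1:3, function(d)
    seq(center[d] - radius, center[d] + radius, by = spacing))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  inside <- rowSums(sweep(pts, 2, center)^2) <= radius^2
  pts <- pts[inside, , drop = FALSE]
  rec <- role_beads(system, "receptor")
  if (length(rec) > 0) {
    rxyz <- as.matrix(coords)[rec, , drop = FALSE]
    rad <- probe_radius + system$beads$lj_sigma[rec] / 2
    free <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(rxyz))) {
      d2 <- rowSums(sweep(pts, 2, rxyz[i, ])^2)
      free <- free & d2 > rad[i]^2
      if (!any(free)) break
    }
    pts <- pts[free, , drop = FALSE]
  }
  nrow(pts) * spacing^3
}

#' Solvent-occupancy grid
#'
#' Fraction of frames in which each voxel contains at least one
#' solvent-bead centre, after superposing every frame onto the first
#' frame's receptor (so the map is receptor-fixed).  Occupancies are
#' invariant under frame reordering.
#'
#' @param trajectory a `cg_trajectory`.
#' @param system a `cg_system` with at least one solvent bead.
#' @param origin grid origin (length-3, A); default: receptor bounding box
#'   minus a 2 A margin.
#' @param dims number of voxels per axis (length-3 integer); default: cover
#'   the receptor bounding box plus margins.
#' @param spacing voxel edge (A).
#' @param align superpose frames onto the first frame's receptor before
#'   binning (default TRUE).
#' @return Object of class `occupancy_grid`: `origin`, `spacing`, `dims`,
#'   `occupancy` (3-D array of per-voxel fractions between 0 and 1),
#'   `n_frames`.
#' @export
water_occupancy_map <- function(trajectory, system, origin = NULL,
                                dims = NULL, spacing = 1, align = TRUE) {
  sol <- role_beads(system, "solvent")
  if (length(sol) == 0) stop("system has no solvent beads")
  rec <- role_beads(system, "receptor")
  nf <- n_frames(trajectory)
  if (is.null(origin) || is.null(dims)) {
    rxyz <- traj_frame(trajectory, 1)[rec, , drop = FALSE]
    lo <- apply(rxyz, 2, min) - 2
    hi <- apply(rxyz, 2, max) + 2
    if (is.null(origin)) origin <- lo
    if (is.null(dims)) dims <- ceiling((hi - origin) / spacing)
  }
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  counts <- array(0L, dims)
  ref <- traj_frame(trajectory, 1)
  for (f in seq_len(nf)) {
    X <- traj_frame(trajectory, f)
    if (align && length(rec) >= 3) X <- .superpose(X, ref, rec)
    ix <- floor(sweep(X[sol, , drop = FALSE], 2, origin) / spacing) + 1
    ok <- ix[, 1] >= 1 & ix[, 1] <= dims[1] &
      ix[, 2] >= 1 & ix[, 2] <= dims[2] &
      ix[, 3] >= 1 & ix[, 3] <= dims[3]
    ix <- unique(ix[ok, , drop = FALSE])  # >= 1 bead occupies the voxel
    if (nrow(ix) > 0) counts[ix] <- counts[ix] + 1L
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 occupancy = counts / nf, n_frames = nf),
            class = "occupancy_grid")
}

#' High-occupancy voxels (hydration hotspots)
#'
#' Voxels with occupancy strictly greater than `threshold`, sorted by
#' occupancy (descending), ties broken by linear voxel index.
#'
#' @param grid an [water_occupancy_map()] result.
#' @param threshold occupancy threshold in [0, 1); the classic reporting
#'   threshold for hydration maps is 0.10.
#' @return data.frame with voxel indices `i`, `j`, `k`, voxel-centre
#'   coordinates `x`, `y`, `z` (A) and `occupancy`.
#' @export
hotspots <- function(grid, threshold = 0.10) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  lin <- which(grid$occupancy > threshold)
  idx <- arrayInd(lin, grid$dims)
  occ <- grid$occupancy[lin]
  ord <- order(-occ, lin)
  idx <- idx[ord, , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
             x = grid$origin[1] + (idx[, 1] - 0.5) * grid$spacing,
             y = grid$origin[2] + (idx[, 2] - 0.5) * grid$spacing,
             z = grid$origin[3] + (idx[, 3] - 0.5) * grid$spacing,
             occupancy = occ[ord])
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat("<occupancy_grid> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", x$spacing, " A, ", x$n_frames, " frames, max ",
      signif(max(x$occupancy), 3), "\n", sep = "")
  invisible(x)
}
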
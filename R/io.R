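# Readers and writers.  Topologies travel as PDB (viewable in standard
# structure viewers) plus a JSON parameter sidecar carrying the force-field
# terms PDB cannot hold; trajectories as multi-frame XYZ; occupancy grids as
# OpenDX scalar grids; tables as CSV.

#' Write a system as PDB plus JSON parameter sidecar
#'
#' @param system a `cg_system`.
#' @param pdb_path output PDB path (beads as atoms, residue labels kept).
#' @param params_path output JSON path (masses, charges, LJ parameters,
#'   bonds, box, selections, provenance).
#' @return Invisibly, the two paths.
#' @export
write_system <- function(system, pdb_path, params_path) {
  b <- system$beads
  chain <- c(receptor = "A", ligand = "B", solvent = "C")[b$role]
  bio3d::write.pdb(file = pdb_path, xyz = as.vector(t(system$coords)),
                   resno = b$residue_id, resid = b$residue_name,
                   chain = chain, eleno = b$id,
                   elety = rep("C", nrow(b)), o = rep(1, nrow(b)),
                   b = rep(0, nrow(b)))
  params <- list(
    beads = b[, c("id", "residue_id", "residue_name", "role", "mass",
                  "charge", "lj_sigma", "lj_epsilon")],
    bonds = system$bonds, box = system$box,
    site_residues = system$site_residues,
    ligand_residues = system$ligand_residues,
    meta = .serializable_meta(system$meta))
  jsonlite::write_json(params, params_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(pdb = pdb_path, params = params_path))
}

.serializable_meta <- function(meta) {
  lapply(meta, function(x) if (is.matrix(x)) as.data.frame(x) else x)
}

#' Read a system from PDB plus JSON parameter sidecar
#'
#' Round-trips with [write_system()]: coordinates to PDB precision (1e-3 A),
#' parameters exactly.
#'
#' @param pdb_path PDB file with one atom per bead.
#' @param params_path JSON sidecar written by [write_system()].
#' @return A [cg_system()].
#' @export
read_system <- function(pdb_path, params_path) {
  pdb <- bio3d::read.pdb(pdb_path)
  coords <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  if (nrow(coords) == 0) stop("PDB file contains no atoms: ", pdb_path)
  params <- jsonlite::read_json(params_path, simplifyVector = TRUE)
  beads <- as.data.frame(params$beads)
  if (nrow(beads) != nrow(coords))
    stop("bead count mismatch: PDB has ", nrow(coords), " atoms, params ",
         nrow(beads), " beads")
  need <- c("mass", "charge", "lj_sigma", "lj_epsilon")
  bad <- which(!stats::complete.cases(beads[, need]))
  if (length(bad) > 0)
    stop("parameters missing for bead id ", beads$id[bad[1]])
  bonds <- if (is.null(params$bonds) || length(params$bonds) == 0) NULL
    else as.data.frame(params$bonds)
  if (!is.null(bonds) && nrow(bonds) == 0) bonds <- NULL
  meta <- params$meta
  if (!is.null(meta)) {
    for (nm in c("cryptic_centers")) {
      if (!is.null(meta[[nm]])) meta[[nm]] <- as.matrix(meta[[nm]])
    }
  }
  cg_system(beads = beads, coords = coords, bonds = bonds,
            box = params$box, site_residues = params$site_residues,
            ligand_residues = params$ligand_residues,
            meta = if (is.null(meta)) list() else meta)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Standard XYZ framing: per frame an atom-count line, a comment line
#' carrying the time, then one `element x y z` line per bead (6 decimals).
#'
#' @param trajectory a `cg_trajectory`.
#' @param path output path.
#' @param elements per-bead element labels; defaults to the residue names.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(trajectory, path, elements = NULL) {
  nb <- dim(trajectory$frames)[2]
  if (is.null(elements)) elements <- rep("C", nb)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    X <- traj_frame(trajectory, f)
    writeLines(c(as.character(nb),
                 sprintf("t= %.6f ps", trajectory$times[f]),
                 sprintf("%s %.6f %.6f %.6f", elements, X[, 1], X[, 2],
                         X[, 3])), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file; every frame must carry a consistent atom count and
#'   a complete coordinate block (a truncated or inconsistent frame is an
#'   error naming the frame index).
#' @return A `cg_trajectory`; frame times are parsed from `t= <value>`
#'   comments when present, otherwise 1, 2, ... .
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  pos <- 1L
  fidx <- 0L
  nb <- NA_integer_
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    fidx <- fidx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n <= 0)
      stop("frame ", fidx, ": invalid atom-count line at line ", pos)
    if (!is.na(nb) && n != nb)
      stop("frame ", fidx, ": inconsistent atom count (", n, " vs ", nb, ")")
    nb <- n
    if (pos + 1L + n > length(lines))
      stop("frame ", fidx, " is truncated")
    comment <- lines[pos + 1L]
    tm <- regmatches(comment,
                     regexpr("t=\\s*[-+0-9.eE]+", comment))
    times <- c(times, if (length(tm) == 1)
      as.numeric(sub("t=\\s*", "", tm)) else fidx)
    block <- lines[pos + 1L + seq_len(n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(vapply(parts, length, integer(1)) < 4))
      stop("frame ", fidx, " is truncated or malformed")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("frame ", fidx, ": non-numeric coordinates")
    frames[[fidx]] <- xyz
    pos <- pos + 2L + n
  }
  if (fidx == 0) stop("no frames in ", path)
  arr <- array(NA_real_, c(fidx, nb, 3))
  for (f in seq_len(fidx)) arr[f, , ] <- frames[[f]]
  cg_trajectory(arr, times)
}

#' Write an occupancy grid in OpenDX scalar-field format
#'
#' @param grid an `occupancy_grid`.
#' @param path output `.dx` path.
#' @return Invisibly, `path`.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  n <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# occupancy grid (fraction of frames with a solvent bead per voxel)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d ",
                   "data follows"), n)), con)
  # DX convention: z runs fastest, then y, then x
  vals <- as.vector(aperm(grid$occupancy, c(3, 2, 1)))
  full_rows <- seq_len(n %/% 3) * 3
  txt <- character(0)
  for (start in seq(1, n, by = 3)) {
    end <- min(start + 2, n)
    txt <- c(txt, paste(sprintf("%.6f", vals[start:end]), collapse = " "))
  }
  writeLines(txt, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Sections `scenario`, `engine` and `supervision` are merged over the
#' package defaults ([scenario_config()], [engine_config()],
#' [supervision_config()]); top-level `seed` (default 1) and `outdir` are
#' kept as given.
#'
#' @param path YAML file.
#' @return List with validated `scenario`, `engine`, `supervision`, plus
#'   `seed` and `outdir`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  mk <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    do.call(ctor, args)
  }
  list(scenario = mk("scenario", scenario_config),
       engine = mk("engine", engine_config),
       supervision = mk("supervision", supervision_config),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       outdir = raw$outdir)
}

# machine-readable record of a resolved run configuration + seeds
.write_run_record <- function(dir, record) {
  jsonlite::write_json(record, file.path(dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}
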
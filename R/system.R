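#' Construct a coarse-grained system
#'
#' A `cg_system` bundles the bead table (topology + force-field parameters),
#' reference coordinates, bonds, an optional cubic box, and the two residue
#' selections the supervision protocol needs: the binding-site residues and
#' the ligand residues.
#'
#' @param beads data.frame with columns `id` (integer), `residue_id`
#'   (integer), `residue_name` (short label), `role` (one of `"receptor"`,
#'   `"ligand"`, `"solvent"`), `mass` (amu), `charge` (e), `lj_sigma` (A),
#'   `lj_epsilon` (kcal/mol).
#' @param coords numeric N x 3 matrix of reference coordinates (A).
#' @param bonds data.frame with columns `i`, `j` (bead ids), `k`
#'   (kcal/mol/A^2; potential is `1/2 k (r - r0)^2`) and `r0` (A), or NULL.
#' @param box cubic box edge length (A, origin at the corner) or NULL.
#' @param site_residues integer residue ids defining the binding site; must
#'   be receptor-role residues.
#' @param ligand_residues integer residue ids of the ligand.
#' @param meta free-form provenance list (scenario parameters, tagged bead
#'   groups, calibration record).
#' @return Object of class `cg_system`.
#' @export
cg_system <- function(beads, coords, bonds = NULL, box = NULL,
                      site_residues, ligand_residues, meta = list()) {
  beads <- as.data.frame(beads)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        k = numeric(0), r0 = numeric(0))
  }
  sys <- structure(
    list(beads = beads, coords = coords, bonds = as.data.frame(bonds),
         box = if (is.null(box)) NULL else as.numeric(box),
         site_residues = as.integer(site_residues),
         ligand_residues = as.integer(ligand_residues),
         meta = meta),
    class = "cg_system")
  validate_system(sys)
  sys
}

#' Validate a coarse-grained system
#'
#' Checks every structural invariant: positive masses and sigmas,
#' non-negative epsilons, legal roles, unique bead ids, bonds referencing
#' existing beads, non-empty receptor-only site selection and non-empty
#' ligand-only ligand selection, and coordinate/bead count agreement.
#'
#' @param sys a `cg_system`.
#' @return `sys`, invisibly; signals an error on the first violated invariant.
#' @export
validate_system <- function(sys) {
  b <- sys$beads
  need <- c("id", "residue_id", "residue_name", "role", "mass", "charge",
            "lj_sigma", "lj_epsilon")
  miss <- setdiff(need, names(b))
  if (length(miss) > 0)
    stop("bead table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(b$id)) stop("duplicate bead ids")
  if (!all(b$role %in% c("receptor", "ligand", "solvent")))
    stop("bead role must be one of receptor, ligand, solvent")
  if (any(b$mass <= 0)) stop("all bead masses must be > 0")
  if (any(b$lj_sigma <= 0)) stop("all lj_sigma must be > 0")
  if (any(b$lj_epsilon < 0)) stop("all lj_epsilon must be >= 0")
  if (nrow(sys$coords) != nrow(b) || ncol(sys$coords) != 3)
    stop("coords must be an N x 3 matrix matching the bead table")
  if (nrow(sys$bonds) > 0) {
    if (!all(sys$bonds$i %in% b$id) || !all(sys$bonds$j %in% b$id))
      stop("bond indices reference non-existing beads")
    if (any(sys$bonds$k < 0) || any(sys$bonds$r0 <= 0))
      stop("bond constants must be k >= 0, r0 > 0")
  }
  if (length(sys$site_residues) == 0) stop("site_selection must be non-empty")
  if (length(sys$ligand_residues) == 0)
    stop("ligand_selection must be non-empty")
  site_roles <- unique(b$role[b$residue_id %in% sys$site_residues])
  if (length(site_roles) == 0 || !identical(site_roles, "receptor"))
    stop("site_selection must name existing receptor-role residues")
  lig_roles <- unique(b$role[b$residue_id %in% sys$ligand_residues])
  if (length(lig_roles) == 0 || !identical(lig_roles, "ligand"))
    stop("ligand_selection must name existing ligand-role residues")
  if (!is.null(sys$box) && (length(sys$box) != 1 || sys$box <= 0))
    stop("box must be a single positive edge length")
  invisible(sys)
}

n_beads <- function(sys) nrow(sys$beads)

#' Bead indices (row numbers) for a set of residue ids
#' @param sys a `cg_system`.
#' @param residues integer residue ids.
#' @return integer vector of bead row indices.
#' @export
residue_beads <- function(sys, residues) {
  which(sys$beads$residue_id %in% residues)
}

#' Bead indices by role
#' @param sys a `cg_system`.
#' @param role `"receptor"`, `"ligand"` or `"solvent"`.
#' @return integer vector of bead row indices.
#' @export
role_beads <- function(sys, role) which(sys$beads$role == role)

site_beads <- function(sys) residue_beads(sys, sys$site_residues)
ligand_beads <- function(sys) residue_beads(sys, sys$ligand_residues)

#' Total system charge
#' @param sys a `cg_system`.
#' @return Sum of per-bead charges (e).
#' @export
system_charge <- function(sys) sum(sys$beads$charge)

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system> ", nrow(x$beads), " beads (",
      sum(x$beads$role == "receptor"), " receptor, ",
      sum(x$beads$role == "ligand"), " ligand, ",
      sum(x$beads$role == "solvent"), " solvent), ",
      nrow(x$bonds), " bonds, box = ",
      if (is.null(x$box)) "none" else paste0(x$box, " A"),
      ", total charge = ", signif(system_charge(x), 4), " e\n", sep = "")
  invisible(x)
}
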
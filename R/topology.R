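#' Construct a topology
#'
#' A \code{topology} is the static half of a simulation system: one row per
#' atom with identity, residue membership, subunit (chain) assignment,
#' partial charge and mass, plus a coarse group label used by the analyses
#' to select protein, ion, water or lipid atoms.
#'
#' @param atoms data.frame with columns \code{atom_id} (integer, unique,
#'   contiguous from 0), \code{name}, \code{element}, \code{residue_index},
#'   \code{residue_name}, \code{subunit_id}, \code{partial_charge} (e),
#'   \code{mass} (amu). A \code{group} column (one of \code{"protein"},
#'   \code{"ion"}, \code{"water"}, \code{"lipid"}, \code{"other"}) is
#'   derived from residue names when absent.
#' @return object of class \code{topology}
#' @export
topology <- function(atoms) {
  req <- c("atom_id", "name", "element", "residue_index", "residue_name",
           "subunit_id", "partial_charge", "mass")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("topology: missing columns: ", paste(missing_cols, collapse = ", "))
  atoms$atom_id <- as.integer(atoms$atom_id)
  if (anyDuplicated(atoms$atom_id))
    stop("topology: duplicated atom_id (reference error)")
  if (!identical(sort(atoms$atom_id), seq(0L, nrow(atoms) - 1L)))
    stop("topology: atom_ids must be contiguous from 0")
  if (any(!is.finite(atoms$partial_charge)))
    stop("topology: partial charges must be finite")
  if (is.null(atoms$group))
    atoms$group <- classify_atoms(atoms$residue_name)
  bad <- setdiff(unique(atoms$group),
                 c("protein", "ion", "water", "lipid", "other"))
  if (length(bad)) stop("topology: unknown group label: ", bad[1])
  atoms <- atoms[order(atoms$atom_id), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_atoms = nrow(atoms)), class = "topology")
}

# residue-name heuristics for group labels
classify_atoms <- function(resname) {
  rn <- toupper(trimws(resname))
  water_names <- c("HOH", "WAT", "TIP3", "TIP4", "SOL", "SPC", "W")
  ion_names <- c("K", "POT", "CL", "CLA", "NA", "SOD", "MG", "CA2", "KCL")
  lipid_names <- c("POPC", "POPE", "DPPC", "DOPC", "DMPC", "POPG", "LIP",
                   "PLC", "CHL1")
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
          "SER", "THR", "TRP", "TYR", "VAL")
  out <- rep("other", length(rn))
  out[rn %in% aa] <- "protein"
  out[rn %in% water_names] <- "water"
  out[rn %in% ion_names] <- "ion"
  out[rn %in% lipid_names] <- "lipid"
  out
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,",
      length(unique(paste(x$atoms$subunit_id, x$atoms$residue_index))),
      "residues\n")
  cat("  groups:", paste(names(table(x$atoms$group)),
                         table(x$atoms$group), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' Per-frame coordinates (Angstrom) with orthorhombic box lengths and times.
#'
#' @param coords numeric array \code{[n_frames, n_atoms, 3]} in Angstrom
#' @param box numeric matrix \code{[n_frames, 3]} of box lengths (Angstrom)
#' @param times numeric vector of frame times in ps, strictly increasing
#' @return object of class \code{trajectory}
#' @export
trajectory <- function(coords, box, times = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("trajectory: coords must be [n_frames, n_atoms, 3]")
  n_frames <- dim(coords)[1]
  if (is.vector(box)) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  if (nrow(box) != n_frames || ncol(box) != 3)
    stop("trajectory: box must be [n_frames, 3]")
  if (any(box <= 0)) stop("trajectory: box lengths must be strictly positive")
  if (is.null(times)) times <- seq_len(n_frames) - 1
  if (length(times) != n_frames || any(diff(times) <= 0 & n_frames > 1))
    stop("trajectory: times must be strictly increasing, one per frame")
  structure(list(coords = coords, box = box, times = as.numeric(times),
                 n_frames = n_frames, n_atoms = dim(coords)[2]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms,",
      "t =", x$times[1], "..", x$times[x$n_frames], "ps\n")
  invisible(x)
}

# frame coordinates as an n_atoms x 3 matrix
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

check_traj_topo <- function(traj, topo) {
  if (traj$n_atoms != topo$n_atoms)
    stop("trajectory atom count (", traj$n_atoms,
         ") does not match topology (", topo$n_atoms, ")")
  invisible(TRUE)
}

#' Select atom ids by group, name or residue
#'
#' @param topo a \code{topology}
#' @param group optional group label(s)
#' @param name optional atom name(s)
#' @param residue_index optional residue index(es)
#' @param subunit_id optional subunit id(s)
#' @return integer vector of atom ids (0-based)
#' @export
select_atoms <- function(topo, group = NULL, name = NULL,
                         residue_index = NULL, subunit_id = NULL) {
  a <- topo$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(group)) keep <- keep & a$group %in% group
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(residue_index)) keep <- keep & a$residue_index %in% residue_index
  if (!is.null(subunit_id)) keep <- keep & a$subunit_id %in% subunit_id
  a$atom_id[keep]
}
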
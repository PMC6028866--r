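#' Read a structure file into a topology and single-frame trajectory
#'
#' Reads a PDB (fixed-column, via bio3d) or GRO file. Partial charges are
#' zero unless a sidecar charge table is supplied. Group labels are derived
#' from residue names (water models, K/CL ions, common lipid names).
#' Alternate locations other than blank or 'A' are rejected; occupancy and
#' B-factor columns are ignored. On read, each residue is made contiguous
#' across the periodic box (atoms are shifted by whole box lengths toward
#' the residue's first atom) so that distance-based analyses see whole
#' molecules.
#'
#' @param path PDB or GRO file path
#' @param charge_table optional CSV path with columns \code{atom_id,charge}
#' @return list with \code{topology} and single-frame \code{trajectory}
#' @export
read_structure <- function(path, charge_table = NULL) {
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    pdb = read_pdb_structure(path),
    gro = read_gro_structure(path),
    stop("read_structure: unsupported format '.", ext, "' (PDB or GRO)"))
  topo <- parsed$topology
  traj <- parsed$trajectory
  if (!is.null(charge_table)) {
    ct <- utils::read.csv(charge_table)
    if (!all(c("atom_id", "charge") %in% names(ct)))
      stop("charge table needs columns atom_id,charge")
    unknown <- setdiff(ct$atom_id, topo$atoms$atom_id)
    if (length(unknown))
      stop("charge table references unknown atom_id: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    idx <- match(ct$atom_id, topo$atoms$atom_id)
    topo$atoms$partial_charge[idx] <- ct$charge
  }
  traj <- rewrap_residues(traj, topo)
  list(topology = topo, trajectory = traj)
}

read_pdb_structure <- function(path) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e)
                    stop("read_structure: unparsable PDB '", path, "': ",
                         conditionMessage(e)))
  a <- pdb$atom
  if (anyDuplicated(a$eleno))
    stop("read_structure: duplicated atom serial in ", path,
         " (reference error)")
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(!alt %in% c("", "A")))
    stop("read_structure: alternate location codes other than blank/'A' ",
         "are not supported")
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)))
    elem <- substr(trimws(a$elety), 1, 1)
  atoms <- data.frame(
    atom_id = seq_len(nrow(a)) - 1L,
    name = trimws(a$elety),
    element = trimws(ifelse(is.na(elem), substr(trimws(a$elety), 1, 1), elem)),
    residue_index = a$resno,
    residue_name = trimws(a$resid),
    subunit_id = chain,
    partial_charge = 0,
    mass = guess_mass(trimws(ifelse(is.na(elem),
                                    substr(trimws(a$elety), 1, 1), elem))),
    stringsAsFactors = FALSE)
  coords <- array(0, dim = c(1, nrow(a), 3))
  coords[1, , ] <- cbind(a$x, a$y, a$z)
  box <- read_cryst1(path)
  if (is.null(box)) box <- apply(coords[1, , , drop = FALSE], 3, function(v)
    max(diff(range(v)), 1) + 20)
  list(topology = topology(atoms),
       trajectory = trajectory(coords, matrix(box, 1, 3)))
}

read_cryst1 <- function(path) {
  lines <- readLines(path, n = 500, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) return(NULL)
  as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
               substr(cr[1], 25, 33)))
}

# GRO fixed columns: resno(5) resname(5) atom(5) atomno(5) x,y,z (%8.3f, nm)
read_gro_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("read_structure: truncated GRO file ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("read_structure: GRO format error at line 2 of ", path,
                     " (atom count)")
  if (length(lines) < n + 3)
    stop("read_structure: GRO file shorter than declared atom count")
  al <- lines[3:(n + 2)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resnm <- trimws(substr(al, 6, 10))
  atnm <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("read_structure: GRO format error at line ", bad[1] + 2,
         " of ", path)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                               "\\s+")[[1]]))
  if (length(boxv) < 3 || any(is.na(boxv[1:3])))
    stop("read_structure: GRO format error at box line of ", path)
  elem <- sub("^([A-Za-z]).*", "\\1", atnm)
  atoms <- data.frame(
    atom_id = seq_len(n) - 1L, name = atnm, element = elem,
    residue_index = resno, residue_name = resnm, subunit_id = "A",
    partial_charge = 0, mass = guess_mass(elem), stringsAsFactors = FALSE)
  coords <- array(0, dim = c(1, n, 3))
  coords[1, , ] <- cbind(x, y, z) * 10   # nm -> Angstrom
  list(topology = topology(atoms),
       trajectory = trajectory(coords, matrix(boxv[1:3] * 10, 1, 3)))
}

guess_mass <- function(elem) {
  tbl <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06, K = 39.098, CL = 35.45, NA2 = 22.990)
  m <- tbl[toupper(elem)]
  m[is.na(m)] <- 12.0
  unname(m)
}

# shift atoms by whole box lengths so each residue is contiguous
rewrap_residues <- function(traj, topo) {
  key <- paste(topo$atoms$subunit_id, topo$atoms$residue_index)
  groups <- split(seq_len(topo$n_atoms), key)
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    box <- traj$box[f, ]
    for (idx in groups) {
      if (length(idx) < 2) next
      ref <- xyz[idx[1], ]
      for (d in 1:3) {
        dd <- xyz[idx, d] - ref[d]
        shift <- round(dd / box[d])
        xyz[idx, d] <- xyz[idx, d] - shift * box[d]
      }
    }
    traj$coords[f, , ] <- xyz
  }
  traj
}

#' Read a coordinate trajectory
#'
#' Supports CHARMM/NAMD-style DCD (via bio3d) and multi-MODEL PDB files.
#'
#' @param path trajectory file (.dcd or .pdb)
#' @param topo topology the frames must match
#' @param dt frame spacing in ps for formats without times (default 1)
#' @param box fallback box lengths (Angstrom, length 3) when the file
#'   carries none
#' @return a \code{trajectory}
#' @export
read_trajectory <- function(path, topo, dt = 1, box = NULL) {
  if (!file.exists(path)) stop("read_trajectory: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                     error = function(e) NULL)
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nf, ncol(xyz) / 3, 3))
    for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3,
                                                   byrow = TRUE)
    bx <- if (!is.null(cell)) as.matrix(cell[, 1:3, drop = FALSE])
          else if (!is.null(box)) matrix(box, nf, 3, byrow = TRUE)
          else stop("read_trajectory: DCD carries no cell; supply box=")
    traj <- trajectory(coords, bx, times = (seq_len(nf) - 1) * dt)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nf, ncol(xyz) / 3, 3))
    for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3,
                                                   byrow = TRUE)
    bx <- read_cryst1(path)
    if (is.null(bx)) {
      if (is.null(box)) box <- apply(coords, 3, function(v)
        max(diff(range(v)), 1) + 20)
      bx <- box
    }
    traj <- trajectory(coords, matrix(bx, nf, 3, byrow = TRUE),
                       times = (seq_len(nf) - 1) * dt)
  } else stop("read_trajectory: unsupported format '.", ext, "'")
  check_traj_topo(traj, topo)
  rewrap_residues(traj, topo)
}

#' Write a structure (or multi-frame trajectory) as PDB
#'
#' Multi-frame input produces a multi-MODEL PDB readable by
#' \code{\link{read_trajectory}}.
#'
#' @param topo topology
#' @param traj trajectory (1 or more frames)
#' @param path output path
#' @export
write_structure <- function(topo, traj, path) {
  check_traj_topo(traj, topo)
  a <- topo$atoms
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj$box[1, ]
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  multi <- traj$n_frames > 1
  for (f in seq_len(traj$n_frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (a$atom_id %% 99999L) + 1L, substr(nm, 1, 4),
      substr(a$residue_name, 1, 3), substr(a$subunit_id, 1, 1),
      a$residue_index %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(a$element, 1, 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
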
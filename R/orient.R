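# Least-squares rigid superposition (Kabsch): rotation R and translation t
# such that R %*% (x - centroid(x)) + centroid(y) best fits y.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  H <- t(xc) %*% yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, center_x = cx, center_y = cy)
}

apply_rigid <- function(xyz, R, center_x, center_y) {
  sweep(sweep(xyz, 2, center_x) %*% t(R), 2, center_y, `+`)
}

#' Superpose all frames and fix the pore-axis convention
#'
#' Each frame is rigidly superposed (optimal least-squares rotation and
#' translation over \code{align_selection}) onto the reference frame. A
#' single global transform then maps the principal axis of the alignment
#' selection in the reference frame to +z and moves the selection's center
#' of geometry to the origin, so downstream analyses can take the pore
#' axis as +z with the intracellular side at low z and the extracellular
#' side at high z.
#'
#' @param traj a \code{trajectory}
#' @param topo matching \code{topology}
#' @param align_selection atom ids (0-based) used for the fit
#' @param reference reference frame index (1-based, default 1)
#' @return object of class \code{oriented_frames}: the trajectory plus
#'   \code{reference} and \code{axis} metadata
#' @export
orient_frames <- function(traj, topo, align_selection, reference = 1) {
  check_traj_topo(traj, topo)
  if (!length(align_selection)) stop("orient_frames: empty align_selection")
  if (reference > traj$n_frames) stop("orient_frames: reference out of range")
  rows <- match(align_selection, topo$atoms$atom_id)
  if (anyNA(rows)) stop("orient_frames: selection ids not in topology")
  ref_xyz <- frame_coords(traj, reference)[rows, , drop = FALSE]
  if (nrow(ref_xyz) < 3 || qr(sweep(ref_xyz, 2, colMeans(ref_xyz)))$rank < 2)
    stop("orient_frames: selection has < 3 non-collinear atoms ",
         "(degenerate fit)")
  # global transform for the reference: principal axis -> +z, centroid -> 0
  cen <- colMeans(ref_xyz)
  cc <- sweep(ref_xyz, 2, cen)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  if (axis[3] < 0) axis <- -axis            # keep closest to current +z
  R0 <- rotation_onto_z(axis)
  out <- traj
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    if (f != reference) {
      fit <- kabsch(xyz[rows, , drop = FALSE], ref_xyz)
      xyz <- apply_rigid(xyz, fit$R, fit$center_x, fit$center_y)
    }
    out$coords[f, , ] <- sweep(xyz, 2, cen) %*% t(R0)
  }
  structure(list(trajectory = out, topology_n_atoms = topo$n_atoms,
                 reference = reference,
                 axis = c(0, 0, 1), align_selection = align_selection),
            class = "oriented_frames")
}

# minimal rotation taking unit vector v to (0,0,1)
rotation_onto_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  u <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
         v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(u^2)); u <- u / s
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(acos(c_)) * K + (1 - c_) * K %*% K
}

#' @export
print.oriented_frames <- function(x, ...) {
  cat("oriented_frames:", x$trajectory$n_frames, "frames, reference",
      x$reference, "(pore axis = +z)\n")
  invisible(x)
}

#' Per-frame RMSD to the reference frame
#'
#' Root-mean-square deviation over a selection, in Angstrom, computed on
#' already superposed (oriented) frames; the reference frame therefore has
#' RMSD 0 by construction.
#'
#' @param oriented an \code{oriented_frames} object
#' @param selection atom ids (0-based)
#' @return numeric vector, one RMSD (Angstrom) per frame
#' @export
rmsd_series <- function(oriented, selection) {
  if (!length(selection)) stop("rmsd_series: empty selection")
  traj <- oriented$trajectory
  rows <- selection + 1L
  if (any(rows < 1 | rows > traj$n_atoms))
    stop("rmsd_series: selection out of range")
  ref <- frame_coords(traj, oriented$reference)[rows, , drop = FALSE]
  vapply(seq_len(traj$n_frames), function(f) {
    d <- frame_coords(traj, f)[rows, , drop = FALSE] - ref
    sqrt(sum(d^2) / nrow(d))
  }, numeric(1))
}

#' Trajectory-averaged residue contact map
#'
#' Entry (a, b) is the minimum inter-atomic distance between protein
#' residues a and b, truncated at \code{truncation} nm within each frame,
#' then averaged over \code{n_samples} equidistant frames. Distances are
#' reported in nm.
#'
#' @param oriented \code{oriented_frames}
#' @param topo matching topology
#' @param n_samples number of equidistant frames to average (default 370)
#' @param truncation cap in nm applied per frame before averaging
#'   (default 1.5)
#' @return object of class \code{contact_map}: \code{matrix} (nm),
#'   \code{residues} labels, \code{n_frames_used}
#' @export
contact_map <- function(oriented, topo, n_samples = 370, truncation = 1.5) {
  traj <- oriented$trajectory
  check_traj_topo(traj, topo)
  prot <- topo$atoms[topo$atoms$group == "protein", , drop = FALSE]
  key <- paste(prot$subunit_id, prot$residue_index, sep = ":")
  res_labels <- unique(key)
  nr <- length(res_labels)
  if (nr < 2) stop("contact_map: fewer than 2 protein residues")
  n_samples <- min(n_samples, traj$n_frames)
  frames <- unique(round(seq(1, traj$n_frames, length.out = n_samples)))
  res_rows <- split(match(prot$atom_id, topo$atoms$atom_id), key)[res_labels]
  acc <- matrix(0, nr, nr)
  for (f in frames) {
    xyz <- frame_coords(traj, f)
    m <- matrix(0, nr, nr)
    for (i in seq_len(nr - 1)) {
      xi <- xyz[res_rows[[i]], , drop = FALSE]
      for (j in (i + 1):nr) {
        xj <- xyz[res_rows[[j]], , drop = FALSE]
        d2 <- outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * xi %*% t(xj)
        dm <- sqrt(max(min(d2), 0)) / 10    # Angstrom -> nm
        m[i, j] <- m[j, i] <- min(dm, truncation)
      }
    }
    acc <- acc + m
  }
  acc <- acc / length(frames)
  dimnames(acc) <- list(res_labels, res_labels)
  structure(list(matrix = acc, residues = res_labels,
                 n_frames_used = length(frames), truncation = truncation),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", length(x$residues), "residues, averaged over",
      x$n_frames_used, "frames, truncated at", x$truncation, "nm\n")
  invisible(x)
}

#' Write a contact map as CSV
#' @param cm a \code{contact_map}
#' @param path output CSV path
#' @export
write_contact_map <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$matrix), path, row.names = TRUE)
  invisible(path)
}
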
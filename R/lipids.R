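#' Time-averaged lipid occupancy map
#'
#' A voxel counts as occupied in a frame when any lipid atom center lies
#' within \code{atom_radius} of the voxel center; the map holds the
#' fraction of sampled frames in which each voxel was occupied.
#'
#' @param oriented \code{oriented_frames} (or a plain trajectory-bearing
#'   list; coordinates are used as-is)
#' @param topo matching topology with a non-empty lipid group
#' @param frame_stride sample every k-th frame (default 1; with 1 ns
#'   frame spacing this reproduces one-frame-per-ns sampling)
#' @param voxel voxel edge length (Angstrom, default 1)
#' @param atom_radius spherical atom radius (Angstrom, default 1)
#' @return object of class \code{occupancy_map}: \code{grid},
#'   \code{values} in [0, 1], \code{n_frames_used}, \code{atom_radius}
#' @export
occupancy_map <- function(oriented, topo, frame_stride = 1, voxel = 1,
                          atom_radius = 1) {
  traj <- oriented$trajectory
  check_traj_topo(traj, topo)
  lip <- which(topo$atoms$group == "lipid")
  if (!length(lip)) stop("occupancy_map: empty lipid group")
  frames <- seq(1, traj$n_frames, by = frame_stride)
  # grid anchored at the coordinate minimum over sampled lipid positions
  all_min <- rep(Inf, 3); all_max <- rep(-Inf, 3)
  for (f in frames) {
    xyz <- frame_coords(traj, f)[lip, , drop = FALSE]
    all_min <- pmin(all_min, apply(xyz, 2, min))
    all_max <- pmax(all_max, apply(xyz, 2, max))
  }
  origin <- all_min - atom_radius - voxel
  dims <- pmax(2L, as.integer(ceiling((all_max - origin + atom_radius +
                                         voxel) / voxel)) + 1L)
  counts <- array(0L, dim = dims)
  reach <- ceiling(atom_radius / voxel)
  off <- as.matrix(expand.grid(dx = -reach:reach, dy = -reach:reach,
                               dz = -reach:reach))
  for (f in frames) {
    xyz <- frame_coords(traj, f)[lip, , drop = FALSE]
    marked <- array(FALSE, dim = dims)
    for (i in seq_len(nrow(xyz))) {
      ctr <- (xyz[i, ] - origin) / voxel          # fractional index
      base <- round(ctr)
      cand <- sweep(off, 2, base, `+`)
      ok <- cand[, 1] >= 0 & cand[, 1] < dims[1] &
        cand[, 2] >= 0 & cand[, 2] < dims[2] &
        cand[, 3] >= 0 & cand[, 3] < dims[3]
      cand <- cand[ok, , drop = FALSE]
      cc <- sweep(cand, 2, ctr)
      within <- rowSums((cc * voxel)^2) <= atom_radius^2
      sel <- cand[within, , drop = FALSE] + 1L
      if (nrow(sel)) marked[sel] <- TRUE
    }
    counts <- counts + marked
  }
  grid <- structure(list(origin = origin, spacing = rep(voxel, 3),
                         dims = dims, box = dims * voxel),
                    class = "grid_spec")
  structure(list(grid = grid, values = counts / length(frames),
                 n_frames_used = length(frames),
                 atom_radius = atom_radius), class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat("occupancy_map:", paste(x$grid$dims, collapse = " x "),
      "voxels over", x$n_frames_used, "frames; max occupancy",
      signif(max(x$values), 3), "\n")
  invisible(x)
}

#' Voxel centers exceeding an occupancy threshold
#' @param map an \code{occupancy_map}
#' @param threshold occupancy cutoff (default 0.15)
#' @return matrix of voxel-center coordinates (Angstrom)
#' @export
occupied_regions <- function(map, threshold = 0.15) {
  idx <- which(map$values > threshold, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(), 0, 3))
  sweep(sweep(idx - 1, 2, map$grid$spacing, `*`), 2, map$grid$origin, `+`)
}

#' Per-residue lipid contact counts
#'
#' For each protein residue and frame, the number of lipid atoms within
#' \code{cutoff} of any atom of the residue; reported as the per-frame
#' mean and maximum. The 1 Angstrom default is deliberately tight
#' (near-overlap contacts only) and should be widened for
#' less-conservative contact definitions.
#'
#' @param oriented \code{oriented_frames}
#' @param topo matching topology (protein and lipid groups non-empty)
#' @param cutoff contact distance (Angstrom, default 1)
#' @return data.frame: residue_index, subunit_id, mean_count, max_count
#' @export
residue_contacts <- function(oriented, topo, cutoff = 1) {
  traj <- oriented$trajectory
  check_traj_topo(traj, topo)
  a <- topo$atoms
  prot <- which(a$group == "protein")
  lip <- which(a$group == "lipid")
  if (!length(prot) || !length(lip))
    stop("residue_contacts: protein and lipid groups must be non-empty")
  key <- paste(a$subunit_id[prot], a$residue_index[prot], sep = ":")
  res_rows <- split(prot, key)
  counts <- matrix(0, traj$n_frames, length(res_rows))
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    lx <- xyz[lip, , drop = FALSE]
    for (r in seq_along(res_rows)) {
      rx <- xyz[res_rows[[r]], , drop = FALSE]
      d2 <- outer(rowSums(lx^2), rowSums(rx^2), `+`) - 2 * lx %*% t(rx)
      counts[f, r] <- sum(apply(d2, 1, min) <= cutoff^2 + 1e-12)
    }
  }
  parts <- strsplit(names(res_rows), ":", fixed = TRUE)
  data.frame(
    subunit_id = vapply(parts, `[`, "", 1),
    residue_index = as.integer(vapply(parts, `[`, "", 2)),
    mean_count = colMeans(counts),
    max_count = apply(counts, 2, max),
    stringsAsFactors = FALSE)
}
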
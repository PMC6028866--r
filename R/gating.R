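#' Torsion angle of four ordered points
#'
#' Right-hand-rule dihedral about the p2-p3 axis, in degrees in
#' (-180, 180]. For the carbonyl descriptor the quadruple is
#' (C, CA, N, O), so the rotation axis is CA-N.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom)
#' @return angle in degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  b2n <- b2 / sqrt(sum(b2^2))
  # praxeolitic formulation: project the outer bonds off the axis
  v <- b0 - sum(b0 * b2n) * b2n
  w <- b3 - sum(b3 * b2n) * b2n
  x <- sum(v * w)
  y <- sum(cross3(b2n, v) * w)
  ang <- atan2(y, x) * 180 / pi
  wrap_angle(ang)
}

#' Carbonyl orientation descriptors along a trajectory
#'
#' For each requested (residue, subunit) and frame: the (C, CA, N, O)
#' dihedral and the radial distance of the carbonyl oxygen to the pore
#' axis (+z in oriented coordinates).
#'
#' @param oriented \code{oriented_frames}
#' @param topo matching topology
#' @param residues residue indices
#' @param subunits subunit ids (default: all subunits carrying the
#'   residues)
#' @return data.frame with frame, residue_index, subunit_id,
#'   dihedral_deg, radial_A
#' @export
carbonyl_descriptors <- function(oriented, topo, residues,
                                 subunits = NULL) {
  traj <- oriented$trajectory
  check_traj_topo(traj, topo)
  a <- topo$atoms
  if (is.null(subunits))
    subunits <- sort(unique(a$subunit_id[a$residue_index %in% residues &
                                           a$group == "protein"]))
  pairs <- expand.grid(residue_index = residues, subunit_id = subunits,
                       stringsAsFactors = FALSE)
  present <- unique(a$residue_index[a$group == "protein"])
  if (!nrow(pairs) || !all(residues %in% present))
    stop("carbonyl_descriptors: residue ",
         setdiff(residues, present)[1], " missing from the topology")
  idx <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- a$residue_index == pairs$residue_index[i] &
      a$subunit_id == pairs$subunit_id[i]
    ids <- vapply(c("C", "CA", "N", "O"), function(nm) {
      j <- a$atom_id[sel & a$name == nm]
      if (!length(j))
        stop("carbonyl_descriptors: atom ", nm, " missing in residue ",
             pairs$residue_index[i], " subunit ", pairs$subunit_id[i])
      j[1] + 1L
    }, integer(1))
    ids
  })
  out <- vector("list", traj$n_frames * nrow(pairs))
  n <- 0L
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    for (i in seq_len(nrow(pairs))) {
      ii <- idx[[i]]
      o <- xyz[ii[4], ]
      n <- n + 1L
      out[[n]] <- data.frame(
        frame = f, residue_index = pairs$residue_index[i],
        subunit_id = pairs$subunit_id[i],
        dihedral_deg = dihedral_angle(xyz[ii[1], ], xyz[ii[2], ],
                                      xyz[ii[3], ], xyz[ii[4], ]),
        radial_A = sqrt(o[1]^2 + o[2]^2), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Density-based clustering of (dihedral, radial) points
#'
#' DBSCAN on standardized features: each coordinate is divided by its
#' standard deviation, and the dihedral is treated circularly by
#' replicating every point at +/-360 degrees before clustering and
#' folding labels back, so clusters spanning the +/-180 seam are not
#' split. Core points need at least \code{min_samples} neighbors within
#' \code{eps} (the point itself included).
#'
#' @param points data.frame with columns \code{dihedral} (degrees) and
#'   \code{radial} (Angstrom)
#' @param eps neighborhood radius in standardized space (default 0.5)
#' @param min_samples minimum neighborhood size for a core point
#'   (default 10)
#' @return integer vector of cluster labels, -1 for noise
#' @export
cluster_states <- function(points, eps = 0.5, min_samples = 10) {
  n <- nrow(points)
  if (n < min_samples)
    return(rep(-1L, n))
  sdd <- stats::sd(points$dihedral); sdr <- stats::sd(points$radial)
  if ((sdd == 0 && sdr == 0) || eps <= 0) {
    if (eps <= 0) stop("cluster_states: degenerate input (eps <= 0 with ",
                       "identical points)")
    sdd <- 1; sdr <- 1   # all identical: one cluster below
  }
  if (sdd == 0) sdd <- 1
  if (sdr == 0) sdr <- 1
  # replicate at +/-360 deg to honor circularity
  rep_d <- c(points$dihedral, points$dihedral + 360, points$dihedral - 360)
  rep_r <- rep(points$radial, 3)
  X <- cbind(rep_d / sdd, rep_r / sdr)
  lab3 <- dbscan_labels(X, eps, min_samples)
  # merge replica clusters that share an original point
  lab <- merge_replica_labels(lab3, n)
  lab[seq_len(n)]
}

# plain DBSCAN on a point matrix; labels 1..k, -1 = noise
dbscan_labels <- function(X, eps, min_samples) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  eps2 <- eps^2
  nbr <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps2))
  core <- vapply(nbr, length, integer(1)) >= min_samples
  lab <- rep(0L, n)   # 0 = unvisited
  k <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    k <- k + 1L
    queue <- i; lab[i] <- k
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!core[j]) next
      for (m in nbr[[j]]) {
        if (lab[m] == 0L || lab[m] == -1L) {
          newly <- lab[m] == 0L
          lab[m] <- k
          if (newly && core[m]) queue <- c(queue, m)
        }
      }
    }
  }
  lab[lab == 0L] <- -1L
  lab
}

# union clusters containing any replica of the same original point
merge_replica_labels <- function(lab3, n) {
  k <- max(lab3, 0L)
  if (k == 0L) return(lab3)
  parent <- seq_len(k)
  findr <- function(x) { r <- x; while (parent[r] != r) r <- parent[r]; r }
  for (i in seq_len(n)) {
    ls <- unique(lab3[c(i, i + n, i + 2L * n)])
    ls <- ls[ls > 0]
    if (length(ls) > 1) {
      r0 <- findr(ls[1])
      for (l in ls[-1]) parent[findr(l)] <- r0
    }
  }
  out <- lab3
  pos <- out > 0
  out[pos] <- vapply(out[pos], findr, integer(1))
  # compact to 1..k'
  u <- sort(unique(out[pos]))
  out[pos] <- match(out[pos], u)
  out
}

#' Reference anchors for orientation naming
#'
#' Two (dihedral, radial) anchors naming the pore-facing and helix-facing
#' carbonyl states. The packaged defaults are synthetic values matched to
#' the scaffold generator; with real data, supply anchors measured from
#' conductive-state reference structures.
#'
#' @param pore_facing,helix_facing numeric c(dihedral_deg, radial_A)
#' @return object of class \code{reference_points}
#' @export
reference_points <- function(pore_facing = c(153.6, 1.4),
                             helix_facing = c(-86.4, 2.2)) {
  if (isTRUE(all.equal(pore_facing, helix_facing)))
    stop("reference_points: anchors must be distinct")
  structure(list(pore_facing = pore_facing, helix_facing = helix_facing),
            class = "reference_points")
}

#' Name clusters as pore-facing or helix-facing
#'
#' Each cluster is labeled by the reference anchor nearest its centroid
#' (Euclidean distance in the same standardized space used for
#' clustering, circular in the dihedral); noise points get state "noise".
#'
#' @param labels cluster labels from \code{\link{cluster_states}}
#' @param points the clustered points (dihedral, radial)
#' @param refs a \code{\link{reference_points}}
#' @return character vector of states per point: "pore_facing",
#'   "helix_facing" or "noise"
#' @export
assign_orientation <- function(labels, points, refs = reference_points()) {
  sdd <- stats::sd(points$dihedral); sdr <- stats::sd(points$radial)
  if (is.na(sdd) || sdd == 0) sdd <- 1
  if (is.na(sdr) || sdr == 0) sdr <- 1
  circ_d <- function(a, b) abs(wrap_angle(a - b))
  state <- rep("noise", nrow(points))
  for (k in setdiff(unique(labels), -1L)) {
    in_k <- labels == k
    cd <- mean_circular(points$dihedral[in_k])
    cr <- mean(points$radial[in_k])
    dists <- vapply(list(refs$pore_facing, refs$helix_facing), function(a)
      (circ_d(cd, a[1]) / sdd)^2 + ((cr - a[2]) / sdr)^2, numeric(1))
    if (abs(dists[1] - dists[2]) < 1e-12)
      stop("assign_orientation: cluster ", k,
           " equidistant to both anchors (tie)")
    state[in_k] <- if (dists[1] < dists[2]) "pore_facing" else "helix_facing"
  }
  state
}

mean_circular <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' Full orientation series for carbonyls
#'
#' Convenience wrapper: computes descriptors, clusters each
#' (residue, subunit) pair independently, and names the states.
#'
#' @inheritParams carbonyl_descriptors
#' @param eps,min_samples DBSCAN parameters (standardized space)
#' @param refs \code{\link{reference_points}}
#' @param pool cluster all pairs together instead of per pair
#' @return data.frame: frame, residue_index, subunit_id, dihedral_deg,
#'   radial_A, state
#' @export
orientation_series <- function(oriented, topo, residues, subunits = NULL,
                               eps = 0.5, min_samples = 10,
                               refs = reference_points(), pool = FALSE) {
  d <- carbonyl_descriptors(oriented, topo, residues, subunits)
  d$state <- "noise"
  groups <- if (pool) list(seq_len(nrow(d)))
            else split(seq_len(nrow(d)),
                       paste(d$residue_index, d$subunit_id))
  for (idx in groups) {
    pts <- data.frame(dihedral = d$dihedral_deg[idx],
                      radial = d$radial_A[idx])
    lab <- cluster_states(pts, eps, min_samples)
    d$state[idx] <- assign_orientation(lab, pts, refs)
  }
  d
}

#' Coincidence of carbonyl flips and ion relocations
#'
#' A flip is a state change (between non-noise states) of one
#' (residue, subunit) carbonyl; a relocation is any site-label change of
#' a tracked ion. For each flip the nearest-in-time relocation is found
#' and flagged when within the window.
#'
#' @param orient data.frame from \code{\link{orientation_series}}
#' @param relocations a \code{site_assignment} of the ions
#' @param window coincidence window in ns
#' @param dt_ns frame spacing in ns
#' @return list with \code{table} (one row per flip: frame, residue,
#'   subunit, nearest relocation frame, lag_ns, within_window) and
#'   \code{fraction_within}
#' @export
coincidence <- function(orient, relocations, window, dt_ns) {
  reloc_frames <- sort(unique(unlist(lapply(
    seq_along(relocations$tracked), function(k) {
      L <- relocations$labels[, k]
      which(L[-1] != L[-length(L)]) + 1L
    }))))
  flips <- list()
  for (key in unique(paste(orient$residue_index, orient$subunit_id))) {
    d <- orient[paste(orient$residue_index, orient$subunit_id) == key, ]
    d <- d[order(d$frame), ]
    s <- d$state[d$state != "noise"]
    fr <- d$frame[d$state != "noise"]
    if (length(s) < 2) next
    ch <- which(s[-1] != s[-length(s)]) + 1L
    for (i in ch)
      flips[[length(flips) + 1]] <- data.frame(
        frame = fr[i], residue_index = d$residue_index[1],
        subunit_id = d$subunit_id[1], stringsAsFactors = FALSE)
  }
  if (!length(flips) || !length(reloc_frames)) {
    tab <- data.frame(frame = integer(), residue_index = integer(),
                      subunit_id = character(),
                      relocation_frame = integer(), lag_ns = numeric(),
                      within_window = logical())
    return(list(table = tab, fraction_within = NA_real_))
  }
  tab <- do.call(rbind, flips)
  tab$relocation_frame <- vapply(tab$frame, function(f)
    reloc_frames[which.min(abs(reloc_frames - f))], integer(1))
  tab$lag_ns <- (tab$relocation_frame - tab$frame) * dt_ns
  tab$within_window <- abs(tab$lag_ns) <= window
  list(table = tab, fraction_within = mean(tab$within_window))
}
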
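# Independent oracles used across the suite. These deliberately use
# different formulations than the package code paths they check.

# dihedral via explicit plane normals and atan2 (right-hand rule)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- xp(b1, b2); n2 <- xp(b2, b3)
  m1 <- xp(b2 / sqrt(sum(b2^2)), n1)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# place a 4th point at given torsion about p2->p3 (NeRF construction)
place_by_torsion <- function(p1, p2, p3, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180; tor <- torsion_deg * pi / 180
  bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n <- xp(ab, bc); n <- n / sqrt(sum(n^2))
  m <- xp(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

# brute-force minimum inter-residue atom distance for one frame (nm)
oracle_min_dist_nm <- function(xyz_a, xyz_b) {
  best <- Inf
  for (i in seq_len(nrow(xyz_a)))
    for (j in seq_len(nrow(xyz_b)))
      best <- min(best, sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2)))
  best / 10
}

# geometric site assignment recomputed independently for one particle
# position, from explicit slab bounds
oracle_assign <- function(pos, bounds, labels, radial_cutoff,
                          cavity_radius) {
  r <- sqrt(pos[1]^2 + pos[2]^2)
  zmin <- min(bounds[, 1]); zmax <- max(bounds[, 2])
  for (i in order(bounds[, 1]))
    if (pos[3] > bounds[i, 1] && pos[3] <= bounds[i, 2] &&
        r <= radial_cutoff)
      return(labels[i])
  if (pos[3] <= zmin && r <= cavity_radius) return("cavity")
  if (pos[3] > zmax) return("extracellular")
  "bulk"
}

# periodic potential of Gaussian charges by direct structure-factor
# summation over all grid k-modes (no FFT, no mesh deposition)
oracle_periodic_phi <- function(positions, charges, box, dims, sigma,
                                eval_points) {
  ks <- lapply(1:3, function(d) {
    n <- dims[d]
    2 * pi * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / box[d]
  })
  out <- numeric(nrow(eval_points))
  V <- prod(box)
  for (a in ks[[1]]) for (b in ks[[2]]) for (cc in ks[[3]]) {
    k2 <- a^2 + b^2 + cc^2
    if (k2 == 0) next
    sf_re <- sum(charges * cos(-(a * positions[, 1] + b * positions[, 2] +
                                   cc * positions[, 3])))
    sf_im <- sum(charges * sin(-(a * positions[, 1] + b * positions[, 2] +
                                   cc * positions[, 3])))
    damp <- exp(-k2 * sigma^2 / 2) * 4 * pi / k2
    ph <- a * eval_points[, 1] + b * eval_points[, 2] +
      cc * eval_points[, 3]
    out <- out + damp * (sf_re * cos(ph) - sf_im * sin(ph))
  }
  out / V
}

erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# small hand-written PDB fixture
write_tiny_pdb <- function(path, dup_serial = FALSE, altloc = FALSE) {
  lines <- c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.250   3.300   3.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       2.750   4.400   3.100  1.00  0.00           O",
    "ATOM      5  K     K B   2       5.000   5.000   5.000  1.00  0.00           K",
    "END")
  if (dup_serial)
    lines[3] <- sub("ATOM      2", "ATOM      1", lines[3])
  if (altloc)
    lines[3] <- sub(" CA  ALA", " CA BALA", lines[3])
  writeLines(lines, path)
  path
}

# standard small scripted system: one ion walking outward plus a parked
# water, used by several suites
build_scripted <- function(n_frames = 100, jitter_sd = 0, seed = 7) {
  sc <- make_filter_scaffold()
  fr <- function(x) as.integer(round(x * n_frames))
  hops <- rbind(
    data.frame(frame = 1L, particle = "K1", destination = "cavity"),
    data.frame(frame = fr(0.20), particle = "K1", destination = "S5"),
    data.frame(frame = fr(0.35), particle = "K1", destination = "S4"),
    data.frame(frame = fr(0.50), particle = "K1", destination = "S3"),
    data.frame(frame = fr(0.65), particle = "K1", destination = "S2"),
    data.frame(frame = fr(0.80), particle = "K1", destination = "S1"),
    data.frame(frame = fr(0.90), particle = "K1",
               destination = "extracellular"),
    data.frame(frame = 1L, particle = "W1", destination = "S1"),
    data.frame(frame = fr(0.75), particle = "W1", destination = "S0"))
  sys <- script_trajectory(sc,
    hop_schedule(hops, jitter_sd = jitter_sd, seed = seed), n_frames,
    particle_kind = c(K1 = "ion", W1 = "water"))
  sys$scaffold <- sc
  sys
}

orient_identity <- function(sys) {
  # oriented wrapper without re-fitting (scaffold is already on-axis)
  structure(list(trajectory = sys$trajectory,
                 reference = 1, axis = c(0, 0, 1)),
            class = "oriented_frames")
}
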
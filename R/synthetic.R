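# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification for a synthetic selectivity-filter scaffold
#'
#' Describes an idealized four-fold filter: six stacked square cages of
#' oxygen atoms whose planes bound the ion-binding sites S0-S5 (S5
#' innermost / lowest z, S1 outermost, S0 above the top plane). Geometry
#' mimics canonical K+-filter dimensions (3.1 A plane spacing, 1.4 A cage
#' radius); it is a test scaffold, not a model of any real channel.
#'
#' @param n_subunits number of subunits (default 4)
#' @param site_plane_z six strictly increasing z-levels (Angstrom) of the
#'   oxygen planes
#' @param cage_radius radial distance of cage oxygens from the pore axis
#'   (Angstrom)
#' @param s0_offset height of the S0 upper bound above the top plane
#' @param box box lengths (Angstrom)
#' @return object of class \code{scaffold_spec}
#' @export
scaffold_spec <- function(n_subunits = 4,
                          site_plane_z = seq(-7.75, 7.75, by = 3.1),
                          cage_radius = 1.4, s0_offset = 3.1,
                          box = c(30, 30, 44)) {
  if (length(site_plane_z) != 6 || any(diff(site_plane_z) <= 0))
    stop("scaffold_spec: site_plane_z must be 6 strictly increasing levels")
  if (cage_radius <= 0) stop("scaffold_spec: cage_radius must be > 0")
  structure(list(n_subunits = n_subunits, site_plane_z = site_plane_z,
                 cage_radius = cage_radius, s0_offset = s0_offset,
                 box = box),
            class = "scaffold_spec")
}

#' Build the synthetic filter scaffold
#'
#' Each subunit carries five residues (TVGFG-like, indices 63-67), each
#' with backbone C, CA, N and carbonyl O atoms; the carbonyl O of residue
#' 63+j-1 sits exactly on the cage of plane j+1, and residue 63 carries an
#' additional hydroxyl-like OG1 oxygen forming the lowest plane, giving
#' 6 planes x n_subunits cage oxygens. All carbonyls start pore-facing.
#'
#' @param spec a \code{scaffold_spec}
#' @return list with \code{topology}, single-frame \code{trajectory}, and
#'   \code{spec}
#' @export
make_filter_scaffold <- function(spec = scaffold_spec()) {
  ns <- spec$n_subunits
  pz <- spec$site_plane_z
  rc <- spec$cage_radius
  resnames <- c("THR", "VAL", "GLY", "PHE", "GLY")
  rows <- list(); xyz <- list(); id <- 0L
  for (s in seq_len(ns)) {
    phi <- 2 * pi * (s - 1) / ns
    rhat <- c(cos(phi), sin(phi), 0)
    that <- c(-sin(phi), cos(phi), 0)
    zhat <- c(0, 0, 1)
    sub <- LETTERS[s]
    for (j in 1:5) {
      z <- pz[j + 1]
      resno <- 62L + j
      # backbone behind the cage; carbonyl O exactly on the cage.
      # CA-N runs mostly tangentially so a rotation about it (a carbonyl
      # flip) swings O away from the pore axis, as in real filters.
      pos <- list(
        C  = (rc + 2.8) * rhat - 0.5 * that + (z - 0.5) * zhat,
        CA = (rc + 1.2) * rhat + 1.8 * that + (z + 0.3) * zhat,
        N  = (rc + 1.0) * rhat + 1.0 * that + z * zhat,
        O  = rc * rhat + z * zhat)
      if (j == 1) pos$OG1 <- rc * rhat + pz[1] * zhat
      for (nm in names(pos)) {
        rows[[length(rows) + 1]] <- data.frame(
          atom_id = id, name = nm,
          element = substr(nm, 1, 1), residue_index = resno,
          residue_name = resnames[j], subunit_id = sub,
          partial_charge = 0, mass = guess_mass(substr(nm, 1, 1)),
          group = "protein", stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1]] <- pos[[nm]]
        id <- id + 1L
      }
    }
  }
  atoms <- do.call(rbind, rows)
  coords <- array(0, dim = c(1, nrow(atoms), 3))
  coords[1, , ] <- do.call(rbind, xyz)
  list(topology = topology(atoms),
       trajectory = trajectory(coords, matrix(spec$box, 1, 3)),
       spec = spec)
}

# ids of the cage oxygens (carbonyl O + OG1), lowest plane first
cage_oxygen_ids <- function(scaffold) {
  a <- scaffold$topology$atoms
  ids <- a$atom_id[a$name %in% c("O", "OG1")]
  xyz <- frame_coords(scaffold$trajectory, 1)[ids + 1L, , drop = FALSE]
  split(ids, round(xyz[, 3], 3))
}

#' Site centers and slab bounds of a scaffold
#'
#' @param spec a \code{scaffold_spec}
#' @return data.frame with \code{label}, \code{z_lo}, \code{z_hi},
#'   \code{z_center} for S0..S5 plus cavity and extracellular anchors
#' @export
scaffold_site_table <- function(spec) {
  pz <- spec$site_plane_z
  lab <- paste0("S", 5:1)
  df <- data.frame(label = lab, z_lo = pz[1:5], z_hi = pz[2:6])
  df <- rbind(data.frame(label = "S0", z_lo = pz[6],
                         z_hi = pz[6] + spec$s0_offset), df)
  df$z_center <- (df$z_lo + df$z_hi) / 2
  df <- rbind(df,
    data.frame(label = "cavity", z_lo = pz[1] - 8, z_hi = pz[1],
               z_center = pz[1] - 4),
    data.frame(label = "extracellular", z_lo = pz[6] + spec$s0_offset,
               z_hi = pz[6] + spec$s0_offset + 8,
               z_center = pz[6] + spec$s0_offset + 4))
  df[order(-df$z_center), ]
}

#' Build a hop schedule
#'
#' @param hops data.frame with columns \code{frame} (1-based),
#'   \code{particle} (name, e.g. "K1"), \code{destination} (one of
#'   S0..S5, cavity, extracellular); each particle needs a frame-1 entry
#' @param jitter_sd isotropic Gaussian positional noise sd (Angstrom)
#' @param seed RNG seed
#' @return object of class \code{hop_schedule}
#' @export
hop_schedule <- function(hops, jitter_sd = 0, seed = 1) {
  valid <- c(paste0("S", 0:5), "cavity", "extracellular")
  if (!all(hops$destination %in% valid))
    stop("hop_schedule: invalid destination label")
  if (!all(c("frame", "particle", "destination") %in% names(hops)))
    stop("hop_schedule: need columns frame, particle, destination")
  for (p in unique(hops$particle))
    if (!any(hops$frame[hops$particle == p] == 1))
      stop("hop_schedule: particle ", p, " has no frame-1 entry")
  structure(list(hops = hops[order(hops$frame), ], jitter_sd = jitter_sd,
                 seed = seed), class = "hop_schedule")
}

#' Script an ion/water trajectory on a scaffold
#'
#' Tracked particles sit at their current destination's center (slab
#' midpoint on the pore axis) plus seeded isotropic Gaussian jitter; hops
#' are instantaneous at the scheduled frame. Scaffold atoms stay fixed.
#'
#' @param scaffold output of \code{\link{make_filter_scaffold}}
#' @param schedule a \code{hop_schedule}
#' @param n_frames trajectory length
#' @param particle_kind named character vector mapping particle names to
#'   \code{"ion"} or \code{"water"} (default: all ions)
#' @return list with combined \code{topology}, \code{trajectory},
#'   \code{particle_ids} (atom id per particle name), \code{site_table},
#'   and \code{ground_truth} (per-frame planted labels)
#' @export
script_trajectory <- function(scaffold, schedule, n_frames,
                              particle_kind = NULL) {
  if (max(schedule$hops$frame) > n_frames)
    stop("script_trajectory: schedule frame beyond n_frames")
  st <- scaffold_site_table(scaffold$spec)
  parts <- unique(schedule$hops$particle)
  if (is.null(particle_kind))
    particle_kind <- stats::setNames(rep("ion", length(parts)), parts)
  # planted per-frame destination labels
  truth <- matrix("", n_frames, length(parts),
                  dimnames = list(NULL, parts))
  for (p in parts) {
    h <- schedule$hops[schedule$hops$particle == p, ]
    cur <- NA_character_
    hi <- 1
    for (f in seq_len(n_frames)) {
      while (hi <= nrow(h) && h$frame[hi] <= f) { cur <- h$destination[hi]
        hi <- hi + 1 }
      truth[f, p] <- cur
    }
  }
  # schedule-conflict check on binding sites
  for (f in seq_len(n_frames)) {
    occ <- truth[f, truth[f, ] %in% paste0("S", 0:5)]
    if (anyDuplicated(occ))
      stop("script_trajectory: schedule conflict at frame ", f,
           " (two particles in ", occ[duplicated(occ)][1], ")")
  }
  base_topo <- scaffold$topology
  n0 <- base_topo$n_atoms
  prows <- do.call(rbind, lapply(seq_along(parts), function(i) {
    kind <- particle_kind[[parts[i]]]
    data.frame(atom_id = n0 + i - 1L,
               name = if (kind == "ion") "K" else "OW",
               element = if (kind == "ion") "K" else "O",
               residue_index = 1000L + i,
               residue_name = if (kind == "ion") "K" else "SOL",
               subunit_id = "X",
               partial_charge = if (kind == "ion") 1 else 0,
               mass = if (kind == "ion") 39.098 else 15.999,
               group = if (kind == "ion") "ion" else "water",
               stringsAsFactors = FALSE)
  }))
  topo <- topology(rbind(base_topo$atoms, prows))
  centers <- stats::setNames(st$z_center, st$label)
  coords <- array(0, dim = c(n_frames, n0 + length(parts), 3))
  scaffold_xyz <- frame_coords(scaffold$trajectory, 1)
  jit <- with_seed(schedule$seed,
    array(stats::rnorm(n_frames * length(parts) * 3, 0, schedule$jitter_sd),
          dim = c(n_frames, length(parts), 3)))
  if (schedule$jitter_sd == 0) jit[] <- 0
  for (f in seq_len(n_frames)) {
    coords[f, 1:n0, ] <- scaffold_xyz
    for (i in seq_along(parts))
      coords[f, n0 + i, ] <- c(0, 0, centers[truth[f, parts[i]]]) +
        jit[f, i, ]
  }
  list(topology = topo,
       trajectory = trajectory(coords, matrix(scaffold$spec$box, n_frames, 3,
                                              byrow = TRUE)),
       particle_ids = stats::setNames(n0 + seq_along(parts) - 1L, parts),
       particle_kind = particle_kind,
       site_table = st,
       ground_truth = truth)
}

#' Flip a carbonyl between pore-facing and helix-facing in chosen frames
#'
#' Rotates the carbonyl O of one (residue, subunit) about the CA-N axis by
#' \code{delta_deg}, changing the (C, CA, N, O) dihedral by exactly that
#' amount and moving the oxygen away from the pore axis.
#'
#' @param sys list with \code{topology} and \code{trajectory}
#' @param residue_index,subunit_id residue to modify
#' @param frames frame indices to modify
#' @param delta_deg rotation in degrees (default 120)
#' @return the system with modified trajectory
#' @export
flip_carbonyl <- function(sys, residue_index, subunit_id, frames,
                          delta_deg = 120) {
  a <- sys$topology$atoms
  sel <- a$residue_index == residue_index & a$subunit_id == subunit_id
  get_id <- function(nm) {
    i <- a$atom_id[sel & a$name == nm]
    if (!length(i)) stop("flip_carbonyl: atom ", nm, " missing in residue ",
                         residue_index, subunit_id)
    i[1] + 1L
  }
  iCA <- get_id("CA"); iN <- get_id("N"); iO <- get_id("O")
  th <- delta_deg * pi / 180
  for (f in frames) {
    ca <- sys$trajectory$coords[f, iCA, ]
    nn <- sys$trajectory$coords[f, iN, ]
    o <- sys$trajectory$coords[f, iO, ]
    ax <- (nn - ca); ax <- ax / sqrt(sum(ax^2))
    v <- o - nn
    # Rodrigues rotation about the CA->N axis through N
    vr <- v * cos(th) + cross3(ax, v) * sin(th) +
      ax * sum(ax * v) * (1 - cos(th))
    sys$trajectory$coords[f, iO, ] <- nn + vr
  }
  sys
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Parallel-plate voltage system pair
#'
#' A periodic-box analogue of a membrane under a transmembrane voltage:
#' two uniformly charged lattice planes at \code{z1} and \code{z2} drop
#' exactly \code{target_drop} mV across the slab, and a compensating
#' plate pair hugging the periodic boundary carries the return drop (the
#' role electrode/electrolyte screening plays in a real system), so the
#' potential is strictly flat in both bulk regions and linear inside the
#' slab. The reference system has identical geometry with zero charge.
#'
#' @param box box lengths (Angstrom)
#' @param slab_bounds c(z1, z2) with 0 < z1 < z2 < box z
#' @param target_drop transmembrane drop in mV (nonzero): analytic
#'   potential at z2 minus potential at z1
#' @param plane_spacing lattice spacing of the plane point charges
#' @param return_width thickness of the boundary return-path slab
#'   (Angstrom, default 2); keep bulk anchor ranges clear of it
#' @return list with \code{charged} and \code{reference}
#'   \code{\link{charge_system}}s, \code{slab_bounds}, \code{target_drop},
#'   and \code{analytic_phi}: function(z) giving the closed-form potential
#'   (mV, gauge: mean over z = 0)
#' @export
make_plate_capacitor <- function(box = c(30, 30, 60),
                                 slab_bounds = c(20, 40),
                                 target_drop = 500, plane_spacing = 1.5,
                                 return_width = 2) {
  z1 <- slab_bounds[1]; z2 <- slab_bounds[2]; lz <- box[3]
  if (!(z1 > 0 && z2 > z1 && z2 < lz))
    stop("make_plate_capacitor: need 0 < z1 < z2 < box_z")
  if (target_drop == 0)
    stop("make_plate_capacitor: target_drop must be nonzero ",
         "(degenerate normalization)")
  drop_int <- target_drop / MV_PER_EA   # mV -> e/Angstrom units
  lin <- z2 - z1
  w <- return_width
  e_in <- -drop_int / lin           # field inside the slab
  e_ret <- drop_int / w             # field inside the return slab
  sig_slab <- e_in / (4 * pi)       # sheet at z1 (+), z2 (-)
  sig_ret <- e_ret / (4 * pi)       # sheet at lz - w/2 (+), w/2 (-)
  nx <- max(2, round(box[1] / plane_spacing))
  ny <- max(2, round(box[2] / plane_spacing))
  gx <- (seq_len(nx) - 0.5) * box[1] / nx
  gy <- (seq_len(ny) - 0.5) * box[2] / ny
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  area <- (box[1] / nx) * (box[2] / ny)
  zl <- lz - w / 2; zh <- w / 2
  pos <- rbind(cbind(pts, z1), cbind(pts, z2),
               cbind(pts, zl), cbind(pts, zh))
  np <- nrow(pts)
  q <- c(rep(sig_slab * area, np), rep(-sig_slab * area, np),
         rep(sig_ret * area, np), rep(-sig_ret * area, np))
  phi_unref <- function(z) {  # piecewise linear; Phi(bulk intra) = 0
    z <- z %% lz
    ifelse(z <= zh, -e_ret * (z - zh),
      ifelse(z <= z1, 0,
        ifelse(z <= z2, -e_in * (z - z1),
          ifelse(z <= zl, drop_int, drop_int - e_ret * (z - zl)))))
  }
  zz <- seq(0, lz, length.out = 4001)
  offset <- mean(phi_unref(zz))
  list(charged = charge_system(pos, q, box),
       reference = charge_system(pos, q * 0, box),
       slab_bounds = slab_bounds, target_drop = target_drop,
       analytic_phi = function(z) (phi_unref(z) - offset) * MV_PER_EA)
}

#' Toy bilayer with an optional planted bound lipid
#'
#' Pseudo-lipids (3-atom chains) jitter inside a slab around a small fixed
#' "protein" of three 2-atom residues. With \code{binder = TRUE}, the
#' first lipid's head atom is held within 1 Angstrom of the first atom of
#' the target residue in at least 95\% of frames.
#'
#' @param n_lipids number of lipids
#' @param binder plant a bound lipid at the target residue?
#' @param seed RNG seed
#' @param n_frames trajectory length (default 50)
#' @param box box lengths
#' @return list with \code{topology}, \code{trajectory},
#'   \code{target_residue} (index), \code{binder_lipid_atom} (atom id of
#'   the held head atom, or NA), \code{held_frames}
#' @export
make_toy_bilayer <- function(n_lipids = 8, binder = TRUE, seed = 1,
                             n_frames = 50, box = c(40, 40, 30)) {
  rows <- list(); id <- 0L
  protein_xyz <- list()
  for (r in 1:3) {
    for (k in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        atom_id = id, name = paste0("A", k), element = "C",
        residue_index = r, residue_name = "ALA", subunit_id = "A",
        partial_charge = 0, mass = 12.011, group = "protein",
        stringsAsFactors = FALSE)
      protein_xyz[[length(protein_xyz) + 1]] <-
        c(18 + 1.5 * k, 20, 10 + 4 * r)
      id <- id + 1L
    }
  }
  lipid_ids <- list()
  for (l in seq_len(n_lipids)) {
    for (k in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        atom_id = id, name = paste0("C", k), element = "C",
        residue_index = 100L + l, residue_name = "LIP", subunit_id = "L",
        partial_charge = 0, mass = 12.011, group = "lipid",
        stringsAsFactors = FALSE)
      id <- id + 1L
    }
    lipid_ids[[l]] <- (id - 3L):(id - 1L)
  }
  atoms <- do.call(rbind, rows)
  n_atoms <- nrow(atoms)
  target_res <- 2L
  target_xyz <- protein_xyz[[3]]   # first atom of residue 2
  coords <- array(0, dim = c(n_frames, n_atoms, 3))
  n_held <- if (binder && n_lipids >= 1) ceiling(0.96 * n_frames) else 0
  held_frames <- seq_len(n_held)
  with_seed(seed, {
    base <- matrix(stats::runif(n_lipids * 3, 2, 38), n_lipids, 3)
    base[, 3] <- stats::runif(n_lipids, 12, 18)
    # free lipids drift laterally so no voxel stays occupied for long
    ang <- stats::runif(n_lipids, 0, 2 * pi)
    speed <- stats::runif(n_lipids, 1.0, 1.6)
    vel <- cbind(speed * cos(ang), speed * sin(ang), 0)
    for (f in seq_len(n_frames)) {
      for (p in seq_along(protein_xyz))
        coords[f, p, ] <- protein_xyz[[p]]
      for (l in seq_len(n_lipids)) {
        head <- base[l, ] + vel[l, ] * (f - 1) + stats::rnorm(3, 0, 0.2)
        head[1:2] <- head[1:2] %% box[1:2]
        if (binder && l == 1) {
          if (f %in% held_frames) {
            u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
            head <- target_xyz + u * stats::runif(1, 0, 0.8)
          } else head <- target_xyz + c(6, 6, 0)
        }
        for (k in 1:3)
          coords[f, lipid_ids[[l]][k] + 1L, ] <-
            head + c(0, 0, -1.5 * (k - 1))
      }
    }
  })
  list(topology = topology(atoms),
       trajectory = trajectory(coords, matrix(box, n_frames, 3,
                                              byrow = TRUE)),
       target_residue = target_res,
       binder_lipid_atom = if (binder && n_lipids >= 1)
         lipid_ids[[1]][1] else NA_integer_,
       held_frames = held_frames)
}

#' Planted 2-D Gaussian clusters in (dihedral, radial-distance) space
#'
#' @param n_per_cluster points per cluster
#' @param centers list of c(dihedral_deg, radius_A) centers
#' @param sd isotropic Gaussian sd (applied on both axes, degrees / A)
#' @param seed RNG seed
#' @return list with \code{points} (data.frame dihedral, radial) and
#'   \code{labels} (1-based planted cluster index)
#' @export
make_planted_clusters <- function(n_per_cluster, centers, sd = 1, seed = 1) {
  with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_along(centers), function(i) {
      data.frame(
        dihedral = wrap_angle(centers[[i]][1] +
                                stats::rnorm(n_per_cluster, 0, sd)),
        radial = pmax(0, centers[[i]][2] +
                        stats::rnorm(n_per_cluster, 0, sd)))
    }))
    list(points = pts,
         labels = rep(seq_along(centers), each = n_per_cluster))
  })
}

# wrap degrees into (-180, 180]
wrap_angle <- function(a) {
  w <- a - 360 * floor((a + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}
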
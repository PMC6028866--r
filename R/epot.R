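# potential unit conversion: 1 e/Angstrom (Gaussian-style reduced units)
MV_PER_EA <- 14399.645   # mV

#' A set of point charges in a periodic orthorhombic box
#'
#' @param positions numeric matrix [n, 3] in Angstrom
#' @param charges numeric vector of length n, in elementary charges
#' @param box box lengths (Angstrom, length 3)
#' @return object of class \code{charge_system}
#' @export
charge_system <- function(positions, charges, box) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) != length(charges))
    stop("charge_system: positions must be [n, 3] matching charges")
  if (any(!is.finite(positions)) || any(!is.finite(charges)))
    stop("charge_system: entries must be finite")
  for (d in 1:3) positions[, d] <- positions[, d] %% box[d]
  structure(list(positions = positions, charges = as.numeric(charges),
                 box = as.numeric(box)), class = "charge_system")
}

#' Charge system from a topology + trajectory frame
#' @param topo topology carrying partial charges
#' @param traj trajectory
#' @param frame frame index
#' @return a \code{charge_system}
#' @export
frame_charge_system <- function(topo, traj, frame = 1) {
  check_traj_topo(traj, topo)
  charge_system(frame_coords(traj, frame), topo$atoms$partial_charge,
                traj$box[frame, ])
}

#' Regular grid specification spanning a periodic box
#'
#' @param box box lengths (Angstrom)
#' @param spacing requested voxel size (Angstrom, default 1.5); actual
#'   per-axis spacing is box/dims after rounding dims
#' @return object of class \code{grid_spec} with \code{origin},
#'   \code{spacing} (length 3), \code{dims}, \code{box}
#' @export
grid_spec <- function(box, spacing = 1.5) {
  if (spacing <= 0) stop("grid_spec: spacing must be > 0")
  dims <- pmax(4L, as.integer(round(box / spacing)))
  structure(list(origin = c(0, 0, 0), spacing = box / dims, dims = dims,
                 box = as.numeric(box)), class = "grid_spec")
}

scalar_field <- function(grid, values, unit) {
  stopifnot(identical(dim(values), as.integer(grid$dims)))
  structure(list(grid = grid, values = values, unit = unit),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("scalar_field:", paste(x$grid$dims, collapse = " x "),
      "voxels,", x$unit, " range",
      signif(min(x$values), 4), "..", signif(max(x$values), 4), "\n")
  invisible(x)
}

# angular frequencies per FFT index
fft_freqs <- function(n, L) {
  m <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  2 * pi * m / L
}

#' Spread point charges onto a grid as Gaussian densities
#'
#' Charges are deposited with cloud-in-cell weights, the interpolation
#' window is deconvolved in reciprocal space, and a spherical Gaussian of
#' width \code{max(sigma, min(spacing)/2)} is applied (the clamp keeps
#' the density representable on the grid when \code{sigma} is below the
#' voxel size). Total gridded charge equals the sum of the point charges
#' to machine precision.
#'
#' @param system a \code{charge_system}
#' @param grid a \code{grid_spec} spanning the system box
#' @param sigma Gaussian width (Angstrom, default 0.15)
#' @return \code{scalar_field} of charge density (e/Angstrom^3)
#' @export
spread_charges <- function(system, grid, sigma = 0.15) {
  if (sigma <= 0) stop("spread_charges: sigma must be > 0")
  if (max(abs(system$box - grid$box)) > 1e-6 * max(system$box))
    stop("spread_charges: grid does not span the system box")
  dims <- grid$dims; h <- grid$spacing
  rho <- array(0, dim = dims)
  n <- nrow(system$positions)
  if (n > 0) {
    for (i in seq_len(n)) {
      q <- system$charges[i]
      if (q == 0) next
      u <- system$positions[i, ] / h          # grid coordinates
      i0 <- floor(u); fr <- u - i0
      w <- list(c(1 - fr[1], fr[1]), c(1 - fr[2], fr[2]),
                c(1 - fr[3], fr[3]))
      for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
        ix <- (i0[1] + a) %% dims[1] + 1
        iy <- (i0[2] + b) %% dims[2] + 1
        iz <- (i0[3] + cc) %% dims[3] + 1
        rho[ix, iy, iz] <- rho[ix, iy, iz] +
          q * w[[1]][a + 1] * w[[2]][b + 1] * w[[3]][cc + 1]
      }
    }
  }
  sig <- max(sigma, min(h) / 2)
  rk <- stats::fft(rho)
  kx <- fft_freqs(dims[1], grid$box[1])
  ky <- fft_freqs(dims[2], grid$box[2])
  kz <- fft_freqs(dims[3], grid$box[3])
  # CIC window per axis: sinc^2(k h / 2)
  win <- function(k, hd) { s <- ifelse(k == 0, 1, sin(k * hd / 2) /
                                         (k * hd / 2)); s^2 }
  wx <- win(kx, h[1]); wy <- win(ky, h[2]); wz <- win(kz, h[3])
  gx <- exp(-kx^2 * sig^2 / 2); gy <- exp(-ky^2 * sig^2 / 2)
  gz <- exp(-kz^2 * sig^2 / 2)
  fx <- gx / wx; fy <- gy / wy; fz <- gz / wz
  filt <- outer(outer(fx, fy), fz)
  rk <- rk * filt
  out <- Re(stats::fft(rk, inverse = TRUE)) / prod(dims)
  scalar_field(grid, out / prod(h), "e/A^3")   # charge/voxel -> density
}

#' Solve the periodic Poisson equation on the grid
#'
#' Spectral solution of laplacian(Phi) = -4 pi rho with periodic
#' boundaries; the k = 0 mode of the density is removed (uniform
#' neutralizing background) and the potential is gauged to zero mean.
#'
#' @param density \code{scalar_field} of charge density (e/Angstrom^3)
#' @return \code{scalar_field} of potential in internal units
#'   (e/Angstrom); multiply by \code{MV_PER_EA} via
#'   \code{\link{field_as_mV}} for mV
#' @export
solve_poisson <- function(density) {
  g <- density$grid
  rk <- stats::fft(density$values)
  kx <- fft_freqs(g$dims[1], g$box[1])
  ky <- fft_freqs(g$dims[2], g$box[2])
  kz <- fft_freqs(g$dims[3], g$box[3])
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  k2[1, 1, 1] <- Inf   # neutralizing background, zero-mean gauge
  pk <- 4 * pi * rk / k2
  phi <- Re(stats::fft(pk, inverse = TRUE)) / prod(g$dims)
  scalar_field(g, phi, "e/A")
}

#' Convert a potential field from internal units to mV
#' @param field \code{scalar_field} with unit "e/A"
#' @return \code{scalar_field} in mV
#' @export
field_as_mV <- function(field) {
  if (field$unit == "mV") return(field)
  if (field$unit != "e/A") stop("field_as_mV: field is not a potential")
  scalar_field(field$grid, field$values * MV_PER_EA, "mV")
}

#' Frame-averaged electrostatic potential
#'
#' @param systems list of \code{charge_system} frames
#' @param grid \code{grid_spec}
#' @param sigma Gaussian spreading width (Angstrom)
#' @return \code{scalar_field}: per-voxel mean of per-frame potentials
#' @export
average_potential <- function(systems, grid, sigma = 0.15) {
  if (!length(systems)) stop("average_potential: need >= 1 frame")
  boxes <- do.call(rbind, lapply(systems, `[[`, "box"))
  if (any(abs(sweep(boxes, 2, boxes[1, ])) > 0.01 * boxes[1, ]))
    stop("average_potential: boxes differ by more than 1% across frames")
  acc <- array(0, dim = grid$dims)
  for (s in systems)
    acc <- acc + solve_poisson(spread_charges(s, grid, sigma))$values
  scalar_field(grid, acc / length(systems), "e/A")
}

#' Electrical-distance profile along the pore axis
#'
#' Forms the cylinder-averaged axial profile of the potential difference
#' between a voltage-imposing and a reference field, then normalizes it
#' to 0 at the intracellular bulk and 1 at the extracellular bulk: the
#' fraction of the applied voltage dropped up to each z.
#'
#' @param phi_v potential field under applied voltage
#' @param phi_0 reference potential field (matching grid)
#' @param cylinder_radius averaging cylinder radius (Angstrom, default 5)
#' @param bulk_intra,bulk_extra z-intervals c(lo, hi) (Angstrom) of the
#'   intracellular and extracellular bulk used as anchors
#' @param axis_center c(x, y) of the pore axis (default box center)
#' @return object of class \code{electrical_distance_profile}: \code{z}
#'   (Angstrom), \code{delta} (dimensionless), plus the measured
#'   bulk-to-bulk drop in the field's units
#' @export
electrical_distance <- function(phi_v, phi_0, cylinder_radius = 5,
                                bulk_intra, bulk_extra,
                                axis_center = NULL) {
  g <- phi_v$grid
  if (!identical(g$dims, phi_0$grid$dims))
    stop("electrical_distance: grids do not match")
  if (max(bulk_intra) > min(bulk_extra) &&
      max(bulk_extra) > min(bulk_intra))
    stop("electrical_distance: bulk ranges overlap")
  if (is.null(axis_center)) axis_center <- g$box[1:2] / 2
  dphi <- phi_v$values - phi_0$values
  xs <- (seq_len(g$dims[1]) - 1) * g$spacing[1]
  ys <- (seq_len(g$dims[2]) - 1) * g$spacing[2]
  zs <- (seq_len(g$dims[3]) - 1) * g$spacing[3]
  r2 <- outer((xs - axis_center[1])^2, (ys - axis_center[2])^2, `+`)
  in_cyl <- r2 <= cylinder_radius^2
  if (!any(in_cyl)) stop("electrical_distance: empty cylinder")
  d <- vapply(seq_len(g$dims[3]), function(iz)
    mean(dphi[, , iz][in_cyl]), numeric(1))
  intra <- zs >= bulk_intra[1] & zs <= bulk_intra[2]
  extra <- zs >= bulk_extra[1] & zs <= bulk_extra[2]
  if (!any(intra) || !any(extra))
    stop("electrical_distance: empty bulk anchor range")
  v_intra <- mean(d[intra]); v_extra <- mean(d[extra])
  drop <- v_extra - v_intra
  if (abs(drop) < 1e-9 * max(abs(d), 1e-30) || drop == 0)
    stop("electrical_distance: degenerate voltage ",
         "(bulk-to-bulk drop below tolerance)")
  structure(list(z = zs, delta = (d - v_intra) / drop,
                 cylinder_radius = cylinder_radius,
                 bulk_intra = bulk_intra, bulk_extra = bulk_extra,
                 measured_drop = drop, unit = phi_v$unit),
            class = "electrical_distance_profile")
}

#' @export
print.electrical_distance_profile <- function(x, ...) {
  cat("electrical_distance_profile:", length(x$z), "z-levels,",
      "drop =", signif(x$measured_drop, 4), x$unit,
      "; delta range", signif(min(x$delta), 3), "..",
      signif(max(x$delta), 3), "\n")
  invisible(x)
}

# linear interpolation of delta at z (error outside the profile)
delta_at <- function(profile, z) {
  if (any(z < min(profile$z) - 1e-9 | z > max(profile$z) + 1e-9))
    stop("gating_charge: z outside the profile range")
  stats::approx(profile$z, profile$delta, xout = z, rule = 2)$y
}

#' Gating charge between two charge configurations
#'
#' Q = sum_i q_i [delta(z_i in state2) - delta(z_i in state1)]: the
#' charge effectively transferred across the transmembrane voltage when
#' the system rearranges, in elementary charge units.
#'
#' @param profile an \code{electrical_distance_profile}
#' @param state1,state2 data.frames with columns \code{charge} (e) and
#'   \code{z} (Angstrom); rows correspond to the same charges
#' @return gating charge in e
#' @export
gating_charge <- function(profile, state1, state2) {
  if (nrow(state1) != nrow(state2) ||
      any(abs(state1$charge - state2$charge) > 1e-12))
    stop("gating_charge: states must list the same charges")
  sum(state1$charge * (delta_at(profile, state2$z) -
                         delta_at(profile, state1$z)))
}

#' Write a scalar field in OpenDX grid format
#' @param field a \code{scalar_field}
#' @param path output .dx path
#' @export
write_dx <- function(field, path) {
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# poremd scalar field (%s)", field$unit),
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %g %g %g", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %g 0 0", g$spacing[1]),
    sprintf("delta 0 %g 0", g$spacing[2]),
    sprintf("delta 0 0 %g", g$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d",
                   " data follows"), prod(g$dims))), con)
  # DX order: z fastest
  v <- aperm(field$values, c(3, 2, 1))
  v <- as.vector(v)  # now x slowest after aperm -> iterate x, y, z
  pad <- (3 - length(v) %% 3) %% 3
  v <- c(v, rep(NA, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(stats::na.omit(r), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "field" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Write an electrical-distance profile as CSV
#' @param profile an \code{electrical_distance_profile}
#' @param path output CSV path
#' @export
write_delta_profile <- function(profile, path) {
  utils::write.csv(data.frame(z_A = profile$z, delta = profile$delta),
                   path, row.names = FALSE)
  invisible(path)
}
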
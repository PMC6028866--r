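test_that("charge spreading conserves charge and is linear", {
  box <- c(24, 24, 24)
  g <- grid_spec(box, 1.5)
  vol <- prod(g$spacing)
  one <- charge_system(matrix(c(5.3, 12.1, 7.7), 1, 3), 1, box)
  rho <- spread_charges(one, g, 0.15)
  expect_equal(sum(rho$values) * vol, 1, tolerance = 1e-9)

  none <- charge_system(matrix(numeric(), 0, 3), numeric(), box)
  expect_true(all(spread_charges(none, g)$values == 0))

  two <- charge_system(rbind(c(5.3, 12.1, 7.7), c(15, 3, 20)),
                       c(1, 1), box)
  a <- spread_charges(charge_system(matrix(c(5.3, 12.1, 7.7), 1, 3), 1,
                                    box), g, 0.5)
  b <- spread_charges(charge_system(matrix(c(15, 3, 20), 1, 3), 1, box),
                      g, 0.5)
  ab <- spread_charges(two, g, 0.5)
  expect_equal(ab$values, a$values + b$values, tolerance = 1e-12)
})

test_that("Poisson solver is linear, gauge-free and translation-equivariant", {
  box <- c(24, 24, 24)
  g <- grid_spec(box, 1.5)
  zero <- spread_charges(charge_system(matrix(numeric(), 0, 3),
                                       numeric(), box), g)
  expect_true(all(solve_poisson(zero)$values == 0))

  set.seed(5)
  pos <- matrix(runif(9, 2, 22), 3, 3)
  q <- c(1, -2, 0.5)
  r1 <- spread_charges(charge_system(pos[1, , drop = FALSE], q[1], box),
                       g, 1)
  r23 <- spread_charges(charge_system(pos[2:3, ], q[2:3], box), g, 1)
  rall <- spread_charges(charge_system(pos, q, box), g, 1)
  p1 <- solve_poisson(r1); p23 <- solve_poisson(r23)
  pall <- solve_poisson(rall)
  expect_equal(pall$values, p1$values + p23$values,
               tolerance = 1e-10 * max(abs(pall$values)))
  expect_equal(mean(pall$values), 0, tolerance = 1e-12)

  # shifting all charges by one grid spacing shifts the field one voxel
  shifted <- charge_system(sweep(pos, 2, c(g$spacing[1], 0, 0), `+`),
                           q, box)
  ps <- solve_poisson(spread_charges(shifted, g, 1))
  rolled <- pall$values[c(g$dims[1], 1:(g$dims[1] - 1)), , ]
  expect_equal(ps$values, rolled, tolerance = 1e-12 * max(abs(rolled)))
})

test_that("single Gaussian charge matches direct summation and the closed form", {
  box <- c(36, 36, 36)
  sig <- 1.5
  ctr <- c(18, 18, 18)
  g <- grid_spec(box, 1.5)
  cs <- charge_system(matrix(ctr, 1, 3), 1, box)
  phi <- solve_poisson(spread_charges(cs, g, sig))
  ic <- as.integer(18 / g$spacing[2]) + 1L
  xs <- (seq_len(g$dims[1]) - 1) * g$spacing[1]
  r <- abs(xs - 18)
  sel <- which(r >= 3 * sig & r <= box[1] / 4)
  pts <- cbind(xs[sel], 18, 18)
  # independent oracle: direct structure-factor summation (no mesh/FFT)
  oracle <- oracle_periodic_phi(matrix(ctr, 1, 3), 1, box, g$dims, sig,
                                pts)
  got <- phi$values[sel, ic, ic]
  expect_lt(max(abs(got - oracle) / abs(oracle)), 0.01)
  # closed form after removing the periodic background (images +
  # neutralizing term, from the direct sum)
  cf <- erf_(r[sel] / (sig * sqrt(2))) / r[sel]
  background <- oracle - cf
  expect_lt(max(abs((got - background) - cf) / cf), 0.01)
})

test_that("frame-averaged potentials behave like means", {
  box <- c(24, 24, 24)
  g <- grid_spec(box, 1.5)
  cs <- charge_system(matrix(c(12, 12, 12), 1, 3), 1, box)
  single <- solve_poisson(spread_charges(cs, g, 1))
  avg <- average_potential(list(cs, cs, cs), g, 1)
  expect_equal(avg$values, single$values, tolerance = 1e-12)

  neg <- charge_system(matrix(c(12, 12, 12), 1, 3), -1, box)
  cancel <- average_potential(list(cs, neg), g, 1)
  expect_lt(max(abs(cancel$values)), 1e-12)

  # jittered charge positions average close to the unjittered potential
  # (grid-resolved Gaussian width)
  singler <- solve_poisson(spread_charges(cs, g, 1.5))
  set.seed(10)
  frames <- lapply(1:250, function(i)
    charge_system(matrix(c(12, 12, 12) + rnorm(3, 0, 0.1), 1, 3), 1,
                  box))
  javg <- average_potential(frames, g, 1.5)
  ix <- as.integer(12 / g$spacing[1]) + 1L
  # read beyond two voxels of the source: mesh deposition carries
  # first-order interpolation error in the voxels adjacent to a charge
  xs <- (seq_len(g$dims[1]) - 1) * g$spacing[1]
  far <- abs(xs - 12) >= 3 & abs(xs - 12) <= 7.5
  rel <- abs(javg$values[far, ix, ix] - singler$values[far, ix, ix]) /
    abs(singler$values[far, ix, ix])
  expect_lt(max(rel), 0.01)

  big <- charge_system(matrix(c(12, 12, 12), 1, 3), 1, box * 1.5)
  expect_error(average_potential(list(cs, big), g, 1), "boxes differ")
})

test_that("electrical distance rises 0 to 1 across the capacitor slab", {
  cap <- make_plate_capacitor(c(30, 30, 60), c(20, 40), 500)
  g <- grid_spec(cap$charged$box, 1.5)
  phi_v <- solve_poisson(spread_charges(cap$charged, g, 0.15))
  phi_0 <- solve_poisson(spread_charges(cap$reference, g, 0.15))
  expect_error(electrical_distance(phi_0, phi_0, 5, c(4, 16), c(44, 56)),
               "degenerate")
  prof <- electrical_distance(phi_v, phi_0, cylinder_radius = 5,
                              bulk_intra = c(4, 16),
                              bulk_extra = c(44, 56))
  zz <- prof$z
  intra <- zz >= 4 & zz <= 16
  extra <- zz >= 44 & zz <= 56
  expect_lt(max(abs(prof$delta[intra])), 0.01)
  expect_equal(prof$delta[which(zz == 51)], 1.00, tolerance = 0.01)
  expect_lt(max(abs(prof$delta[extra] - 1)), 0.01)
  # linear closed form inside the slab
  inside <- zz >= 20 & zz <= 40
  expect_lt(max(abs(prof$delta[inside] - (zz[inside] - 20) / 20)), 0.02)
  # measured drop close to the imposed 500 mV
  expect_equal(prof$measured_drop * 14399.645, 500, tolerance = 5)

  # gauge invariance: adding constants changes nothing
  phi_v2 <- phi_v; phi_v2$values <- phi_v$values + 0.37
  phi_02 <- phi_0; phi_02$values <- phi_0$values - 1.2
  prof2 <- electrical_distance(phi_v2, phi_02, 5, c(4, 16), c(44, 56))
  expect_equal(prof2$delta, prof$delta, tolerance = 1e-12)
})

test_that("capacitor with slab at fractional box heights follows (z-z1)/(z2-z1)", {
  # slab occupying [0.3, 0.6] of a 60 A box: z1 = 18, z2 = 36
  cap <- make_plate_capacitor(c(30, 30, 60), c(18, 36), 500)
  g <- grid_spec(cap$charged$box, 1.5)
  phi_v <- solve_poisson(spread_charges(cap$charged, g, 0.15))
  phi_0 <- solve_poisson(spread_charges(cap$reference, g, 0.15))
  prof <- electrical_distance(phi_v, phi_0, 5, bulk_intra = c(4, 14),
                              bulk_extra = c(40, 56))
  zz <- prof$z
  ref <- ifelse(zz < 18, 0, ifelse(zz > 36, 1, (zz - 18) / 18))
  ok <- zz >= 3 & zz <= 57   # away from the boundary return path
  expect_lt(max(abs(prof$delta[ok] - ref[ok])), 0.02)
})

test_that("gating charge integrates charge moves against the profile", {
  # hand-built linear profile
  prof <- structure(list(z = seq(0, 60, by = 1.5),
                         delta = pmin(1, pmax(0, (seq(0, 60, 1.5) - 20) /
                                                20)),
                         measured_drop = 1, unit = "e/A"),
                    class = "electrical_distance_profile")
  s <- function(z) data.frame(charge = 1, z = z)
  expect_equal(gating_charge(prof, s(30), s(30)), 0)
  # delta levels 0.10 and 0.35 -> Q = 0.25 e
  expect_equal(gating_charge(prof, s(22), s(27)), 0.25,
               tolerance = 1e-12)
  # full intra -> extra traversal carries ~1 e on the solved profile
  cap <- make_plate_capacitor(c(30, 30, 60), c(20, 40), 500)
  g <- grid_spec(cap$charged$box, 1.5)
  solved <- electrical_distance(
    solve_poisson(spread_charges(cap$charged, g, 0.15)),
    solve_poisson(spread_charges(cap$reference, g, 0.15)),
    5, c(4, 16), c(44, 56))
  expect_equal(gating_charge(solved, s(10), s(50)), 1.00,
               tolerance = 0.01)
  # telescoping is exact and step partitions sum to the full transfer
  qab <- gating_charge(solved, s(10), s(26))
  qbc <- gating_charge(solved, s(26), s(50))
  expect_equal(qab + qbc, gating_charge(solved, s(10), s(50)),
               tolerance = 1e-12)
  steps <- seq(10, 50, length.out = 6)
  parts <- vapply(seq_len(5), function(i)
    gating_charge(solved, s(steps[i]), s(steps[i + 1])), numeric(1))
  expect_equal(sum(parts), gating_charge(solved, s(10), s(50)),
               tolerance = 1e-12)
  expect_error(gating_charge(solved, s(10), s(300)), "outside")
  expect_error(gating_charge(solved, data.frame(charge = 1, z = 10),
                             data.frame(charge = 2, z = 20)),
               "same charges")
})

test_that("scalar fields write to parseable OpenDX", {
  g <- grid_spec(c(6, 6, 6), 1.5)
  f <- scalar_field(g, array(seq_len(prod(g$dims)), dim = g$dims),
                    "mV")
  path <- tempfile(fileext = ".dx")
  write_dx(f, path)
  lines <- readLines(path)
  expect_true(any(grepl("gridpositions counts 4 4 4", lines)))
  expect_true(any(grepl("items 64", lines)))
  dat <- as.numeric(unlist(strsplit(
    lines[grep("data follows", lines) + seq_len(ceiling(64 / 3))],
    " +")))
  expect_equal(sort(dat), as.numeric(1:64))
})
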
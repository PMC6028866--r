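test_that("site assignment matches geometry, with radial gating", {
  sys <- build_scripted(n_frames = 100, jitter_sd = 0)
  or <- orient_identity(sys)
  sites <- scaffold_binding_sites(sys$scaffold)
  k1 <- unname(sys$particle_ids["K1"])

  parked <- script_trajectory(sys$scaffold,
    hop_schedule(data.frame(frame = 1, particle = "K1",
                            destination = "S4")), 10)
  ser <- assign_sites(orient_identity(parked), parked$topology, sites,
                      unname(parked$particle_ids["K1"]))
  expect_true(all(ser$labels == "S4"))

  # same z as S4 but 10 A off axis -> bulk
  shifted <- parked
  shifted$trajectory$coords[, k1 + 1L, 1] <-
    shifted$trajectory$coords[, k1 + 1L, 1] + 10
  ser2 <- assign_sites(orient_identity(shifted), parked$topology, sites,
                       unname(parked$particle_ids["K1"]))
  expect_true(all(ser2$labels == "bulk"))

  # hop at frame 50 switches the label at frame 50
  hop <- script_trajectory(sys$scaffold, hop_schedule(rbind(
    data.frame(frame = 1, particle = "K1", destination = "S4"),
    data.frame(frame = 50, particle = "K1", destination = "S3"))), 100)
  ser3 <- assign_sites(orient_identity(hop), hop$topology, sites,
                       unname(hop$particle_ids["K1"]))
  expect_true(all(ser3$labels[1:49, 1] == "S4"))
  expect_true(all(ser3$labels[50:100, 1] == "S3"))
})

test_that("site assignment agrees with an independent geometric oracle", {
  sys <- build_scripted(n_frames = 100, jitter_sd = 0.25, seed = 9)
  or <- orient_identity(sys)
  sites <- scaffold_binding_sites(sys$scaffold)
  tracked <- unname(sys$particle_ids)
  ser <- assign_sites(or, sys$topology, sites, tracked)
  labels <- vapply(sites$sites, `[[`, "", "label")
  mism <- 0L
  for (f in seq_len(100)) {
    xyz <- sys$trajectory$coords[f, , ]
    bounds <- t(vapply(sites$sites, function(s) {
      lo <- mean(xyz[s$lower + 1L, 3])
      hi <- if (is.null(s$upper)) lo + sites$s0_offset
            else mean(xyz[s$upper + 1L, 3])
      c(lo, hi)
    }, numeric(2)))
    for (k in seq_along(tracked)) {
      want <- oracle_assign(xyz[tracked[k] + 1L, ], bounds, labels,
                            sites$radial_cutoff, 5)
      if (ser$labels[f, k] != want) mism <- mism + 1L
    }
  }
  expect_equal(mism, 0L)
})

test_that("every particle gets exactly one label per frame (partition)", {
  sys <- build_scripted(n_frames = 60, jitter_sd = 0.3, seed = 4)
  ser <- assign_sites(orient_identity(sys), sys$topology,
                      scaffold_binding_sites(sys$scaffold),
                      unname(sys$particle_ids))
  all_labels <- c(paste0("S", 0:5), "cavity", "extracellular", "bulk")
  # each cell carries one valid label; indicator sums to 1 by construction
  expect_true(all(ser$labels %in% all_labels))
  expect_equal(dim(ser$labels), c(60, 2))
})

test_that("jitter-free assignment reproduces the planted schedule; small jitter barely misassigns", {
  sys0 <- build_scripted(n_frames = 100, jitter_sd = 0)
  sites <- scaffold_binding_sites(sys0$scaffold)
  ser0 <- assign_sites(orient_identity(sys0), sys0$topology, sites,
                       unname(sys0$particle_ids))
  truth <- sys0$ground_truth
  expect_equal(unname(ser0$labels[, 1]), unname(truth[, "K1"]))
  expect_equal(unname(ser0$labels[, 2]), unname(truth[, "W1"]))

  sysj <- build_scripted(n_frames = 100, jitter_sd = 0.3, seed = 21)
  serj <- assign_sites(orient_identity(sysj), sysj$topology, sites,
                       unname(sysj$particle_ids))
  mis <- mean(serj$labels != sysj$ground_truth[, c("K1", "W1")])
  expect_lt(mis, 0.01)
})

test_that("occupancy implements the per-frame indicator average", {
  sys <- build_scripted(n_frames = 100, jitter_sd = 0)
  sites <- scaffold_binding_sites(sys$scaffold)
  ser <- assign_sites(orient_identity(sys), sys$topology, sites,
                      unname(sys$particle_ids["K1"]))
  # planted: K1 sits in S3 for frames 50..64 -> 15/100
  expect_equal(occupancy(ser, "S3"),
               sum(sys$ground_truth[, "K1"] == "S3") / 100)
  expect_equal(occupancy(ser, "S3"), 0.15)
  # a parked ion gives occupancy exactly 1
  parked <- script_trajectory(sys$scaffold,
    hop_schedule(data.frame(frame = 1, particle = "K1",
                            destination = "S2")), 40)
  serp <- assign_sites(orient_identity(parked), parked$topology, sites,
                       unname(parked$particle_ids["K1"]))
  expect_equal(occupancy(serp, "S2"), 1.0)
  # no tracked particles -> 0
  empty <- ser; empty$labels <- ser$labels[, 0, drop = FALSE]
  expect_equal(occupancy(empty, "S2"), 0)
  expect_error(occupancy(ser, "S9"), "unknown site")
})

test_that("occupancy counts co-occupying ions (formula-faithful)", {
  sc <- make_filter_scaffold()
  sys <- script_trajectory(sc, hop_schedule(rbind(
    data.frame(frame = 1, particle = "K1", destination = "S2"),
    data.frame(frame = 1, particle = "K2", destination = "cavity"))), 10)
  # move K2 physically into S2 (bypassing the schedule conflict check)
  k1 <- sys$particle_ids[["K1"]] + 1L; k2 <- sys$particle_ids[["K2"]] + 1L
  sys$trajectory$coords[, k2, ] <- sys$trajectory$coords[, k1, ] +
    rep(c(0.4, 0, 0), each = 10)
  ser <- assign_sites(orient_identity(sys), sys$topology,
                      scaffold_binding_sites(sc),
                      unname(sys$particle_ids))
  expect_equal(occupancy(ser, "S2"), 2.0)
})

test_that("configuration strings render ions over waters over vacancies", {
  sc <- make_filter_scaffold()
  ions <- script_trajectory(sc, hop_schedule(rbind(
    data.frame(frame = 1, particle = "K1", destination = "S2"),
    data.frame(frame = 1, particle = "K2", destination = "S4"),
    data.frame(frame = 1, particle = "K3", destination = "S5"),
    data.frame(frame = 1, particle = "W1", destination = "S1"),
    data.frame(frame = 1, particle = "W2", destination = "S3"))), 3,
    particle_kind = c(K1 = "ion", K2 = "ion", K3 = "ion",
                      W1 = "water", W2 = "water"))
  sites <- scaffold_binding_sites(sc)
  or <- orient_identity(ions)
  ion_ids <- unname(ions$particle_ids[c("K1", "K2", "K3")])
  wat_ids <- unname(ions$particle_ids[c("W1", "W2")])
  iser <- assign_sites(or, ions$topology, sites, ion_ids)
  wser <- assign_sites(or, ions$topology, sites, wat_ids)
  expect_equal(configuration_series(iser, wser),
               rep("{W,S2,W,S4,S5}", 3))

  # empty filter renders all-vacant
  empty <- script_trajectory(sc, hop_schedule(
    data.frame(frame = 1, particle = "K1", destination = "cavity")), 2)
  eser <- assign_sites(orient_identity(empty), empty$topology, sites,
                       unname(empty$particle_ids))
  expect_equal(configuration_series(eser),
               rep("{0,0,0,0,0}", 2))
})

test_that("a scripted knock-on cycle reproduces the canonical string sequence", {
  # {W,W,W,S4,S5} -> {W,W,S3,0,S5} -> {W,W,S3,S4,W} -> {W,S2,0,S4,W}
  sc <- make_filter_scaffold()
  hops <- rbind(
    data.frame(frame = 1, particle = "Ka", destination = "S4"),
    data.frame(frame = 2, particle = "Ka", destination = "S3"),
    data.frame(frame = 4, particle = "Ka", destination = "S2"),
    data.frame(frame = 1, particle = "Kb", destination = "S5"),
    data.frame(frame = 3, particle = "Kb", destination = "S4"),
    data.frame(frame = 1, particle = "Wa", destination = "S1"),
    data.frame(frame = 1, particle = "Wb", destination = "S2"),
    data.frame(frame = 4, particle = "Wb", destination = "extracellular"),
    data.frame(frame = 1, particle = "Wc", destination = "S3"),
    data.frame(frame = 2, particle = "Wc", destination = "cavity"),
    data.frame(frame = 3, particle = "Wd", destination = "S5"))
  kinds <- c(Ka = "ion", Kb = "ion", Wa = "water", Wb = "water",
             Wc = "water", Wd = "water")
  # Wd needs a frame-1 entry: park it extracellular first
  hops <- rbind(hops, data.frame(frame = 1, particle = "Wd",
                                 destination = "extracellular"))
  sys <- script_trajectory(sc, hop_schedule(hops), 4,
                           particle_kind = kinds)
  sites <- scaffold_binding_sites(sc)
  or <- orient_identity(sys)
  iser <- assign_sites(or, sys$topology, sites,
                       unname(sys$particle_ids[c("Ka", "Kb")]))
  wser <- assign_sites(or, sys$topology, sites,
                       unname(sys$particle_ids[c("Wa", "Wb", "Wc", "Wd")]))
  expect_equal(configuration_series(iser, wser),
               c("{W,W,W,S4,S5}", "{W,W,S3,0,S5}",
                 "{W,W,S3,S4,W}", "{W,S2,0,S4,W}"))
})

test_that("permeation counting requires complete traversals", {
  sc <- make_filter_scaffold()
  sites <- scaffold_binding_sites(sc)
  run <- function(hops, nf, kinds = NULL) {
    sys <- script_trajectory(sc, hop_schedule(hops), nf,
                             particle_kind = kinds)
    count_permeations(assign_sites(orient_identity(sys), sys$topology,
                                   sites, unname(sys$particle_ids)))
  }
  # static ion: no events
  ev <- run(data.frame(frame = 1, particle = "K1", destination = "S3"),
            10)
  expect_equal(nrow(ev), 0)
  # incomplete traversal (cavity -> filter -> cavity): no events
  ev <- run(rbind(
    data.frame(frame = 1, particle = "K1", destination = "cavity"),
    data.frame(frame = 3, particle = "K1", destination = "S5"),
    data.frame(frame = 6, particle = "K1", destination = "cavity")), 10)
  expect_equal(nrow(ev), 0)
  # three planted outward traversals by one particle
  legs <- function(f0, p) rbind(
    data.frame(frame = f0, particle = p, destination = "cavity"),
    data.frame(frame = f0 + 2, particle = p, destination = "S4"),
    data.frame(frame = f0 + 4, particle = p, destination = "S1"),
    data.frame(frame = f0 + 6, particle = p,
               destination = "extracellular"))
  hops <- rbind(legs(1, "K1"), legs(11, "K1"), legs(21, "K1"))
  ev <- run(hops, 30)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$direction == "outward"))
  expect_true(all(ev$exit_frame > ev$entry_frame))
  # inward mirror
  inward <- rbind(
    data.frame(frame = 1, particle = "K1",
               destination = "extracellular"),
    data.frame(frame = 3, particle = "K1", destination = "S1"),
    data.frame(frame = 6, particle = "K1", destination = "cavity"))
  ev <- run(inward, 10)
  expect_equal(ev$direction, "inward")
})

test_that("permeation counting survives subsampling that keeps state changes", {
  sys <- build_scripted(n_frames = 100, jitter_sd = 0)
  sites <- scaffold_binding_sites(sys$scaffold)
  ser <- assign_sites(orient_identity(sys), sys$topology, sites,
                      unname(sys$particle_ids["K1"]))
  full <- count_permeations(ser)
  keep <- sort(unique(c(1, which(c(TRUE, ser$labels[-1, 1] !=
                                     ser$labels[-100, 1])), 100)))
  sub <- ser
  sub$labels <- ser$labels[keep, , drop = FALSE]
  sub$n_frames <- length(keep)
  expect_equal(nrow(count_permeations(sub)), nrow(full))
})

test_that("inferred current follows I = n e / t in pA", {
  expect_equal(inferred_current(0, 344), 0)
  i2 <- inferred_current(2, 344)
  expect_equal(i2, 2 * 1.602176634e-19 / 344e-9 * 1e12, tolerance = 1e-12)
  expect_equal(inferred_current(4, 344), 2 * i2, tolerance = 1e-12)
  expect_error(inferred_current(2, 0), "duration")
})
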
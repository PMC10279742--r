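# Synthetic-data module: bundle construction, topology invariants,
# ensemble generator ground-truth recovery, membrane mode, ion fields,
# swap ledgers, Boltzmann inversion and radius of gyration.

test_that("ideal bundle realises the designed geometry", {
  topo <- ref_bundle$topology
  xyz <- ref_bundle$conformation
  # 21 bp at 3.4 A rise span 68 A
  bb <- topo$role == "backbone"
  expect_equal(diff(range(xyz[bb, 3L])), 20 * 3.4)
  # opposing helix axes sit exactly two spacings apart
  info <- attr(xyz, "bundle_info")
  expect_equal(sqrt(sum((info$axis_xy[1L, ] - info$axis_xy[4L, ])^2)),
               2 * 21)
  # deterministic construction
  again <- build_ideal_bundle()
  expect_identical(again$conformation, xyz)
  # too-tight spacing is a steric error
  expect_error(build_ideal_bundle(geom = distortion_params(
    axis_spacing_s = 15)), "steric overlap")
})

test_that("topology pairing is symmetric, involutive and region-split", {
  topo <- ref_bundle$topology
  has <- which(!is.na(topo$partner))
  expect_true(all(topo$partner[topo$partner[has]] == topo$bead[has]))
  expect_true(all(topo$role[has] == "base"))
  pairs <- base_pair_table(topo)
  expect_equal(nrow(pairs), 6L * 21L)
  expect_equal(sum(pairs$region == "top"), 6L * 14L)
  expect_equal(sum(pairs$region == "bottom"), 6L * 7L)
  # loops are unpaired
  expect_true(all(is.na(topo$partner[topo$role == "loop"])))
})

test_that("closest inter-helix approach matches the exhaustive oracle", {
  topo <- ref_bundle$topology
  xyz <- unclass(ref_bundle$conformation)
  i1 <- which(topo$role == "backbone" & topo$helix == 1L)
  i4 <- which(topo$role == "backbone" & topo$helix == 4L)
  brute <- oracle_min_dist(xyz[i1, , drop = FALSE],
                           xyz[i4, , drop = FALSE])
  d <- as.matrix(stats::dist(rbind(xyz[i1, ], xyz[i4, ])))
  fast <- min(d[seq_along(i1), length(i1) + seq_along(i4)])
  expect_equal(fast, brute, tolerance = 1e-12)
  expect_equal(brute, 23.512344, tolerance = 1e-5)
})

test_that("generator is deterministic and replica-stable", {
  p <- distortion_params(noise_sigma = 1, fray_prob = 0.2,
                         breathing_amplitude = 2, seed = 42L)
  e1 <- generate_ensemble(ref_bundle$topology, ref_bundle$conformation,
                          p, n_replicas = 2L, n_frames = 4L)
  e2 <- generate_ensemble(ref_bundle$topology, ref_bundle$conformation,
                          p, n_replicas = 3L, n_frames = 4L)
  expect_identical(e1$replicas[[1L]]$coords, e2$replicas[[1L]]$coords)
  expect_identical(e1$replicas[[2L]]$coords, e2$replicas[[2L]]$coords)
  # distinct replicas differ
  expect_gt(max(abs(e1$replicas[[1L]]$coords - e1$replicas[[2L]]$coords)),
            0.1)
})

test_that("zero distortions reproduce the base conformation", {
  e <- generate_ensemble(ref_bundle$topology, ref_bundle$conformation,
                         distortion_params(), n_replicas = 1L,
                         n_frames = 3L)
  for (f in 1:3)
    expect_equal(e$replicas[[1L]]$coords[, , f],
                 unclass(ref_bundle$conformation), tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("imposed hinge rotations are recovered by the kink angle", {
  for (ang in c(10, 40, 52.4, 90, 120)) {
    p <- distortion_params(kink_per_helix = c(ang, 0, 0, 0, 0, 0))
    e <- generate_ensemble(ref_bundle$topology, ref_bundle$conformation,
                           p, n_replicas = 1L, n_frames = 1L)
    expect_equal(kink_angle(get_frame(e), e$topology, 1L), ang,
                 tolerance = 0.5 / ang)
  }
})

test_that("fraying breaks the targeted region at the set rate", {
  p <- distortion_params(fray_prob = 0.302, fray_residues = 15:21,
                         seed = 7L)
  e <- generate_ensemble(ref_bundle$topology, ref_bundle$conformation,
                         p, n_replicas = 1L, n_frames = 300L)
  rep <- broken_base_pairs(e)
  n <- 6L * 7L * 300L
  se <- sqrt(0.302 * 0.698 / n)
  expect_lt(abs(rep$per_region[["bottom"]] - 0.302), 4 * se)
  expect_equal(rep$per_region[["top"]], 0)
})

test_that("membrane compression is a no-op at the solution spacing and
           recovers the inserted outer width", {
  info <- attr(ref_bundle$conformation, "bundle_info")
  noop <- generate_membrane_system(
    ref_bundle$topology, ref_bundle$conformation,
    membrane_params(compressed_spacing = info$circumradius,
                    toroid_inner_radius = 32), seed = 1L)
  nb <- nrow(ref_bundle$topology)
  expect_equal(noop$conformation[seq_len(nb), ],
               unclass(ref_bundle$conformation), tolerance = 1e-12,
               ignore_attr = TRUE)
  # spacing chosen so the measured outer width is the inserted-state value
  m <- generate_membrane_system(
    ref_bundle$topology, ref_bundle$conformation,
    membrane_params(compressed_spacing = 49.5 / 2 - 9.4), seed = 1L)
  dm <- bundle_dimensions(m$conformation, m$topology)
  expect_equal(dm$width, 49.5, tolerance = 0.01)
  # cavity must clear the bundle
  expect_error(generate_membrane_system(
    ref_bundle$topology, ref_bundle$conformation,
    membrane_params(compressed_spacing = 21, toroid_inner_radius = 20)),
    "overlap")
})

test_that("lipid bead count equals density times the cavity-corrected
           slab volume (Monte-Carlo volume oracle)", {
  mp <- membrane_params(compressed_spacing = 16, toroid_inner_radius = 30,
                        bilayer_thickness = 40, lipid_bead_density = 0.5)
  m <- generate_membrane_system(ref_bundle$topology,
                                ref_bundle$conformation, mp, seed = 2L)
  n_lip <- sum(m$topology$role == "lipid")
  box <- attr(m$conformation, "box")
  # Monte-Carlo estimate of the slab-minus-cylinder volume
  set.seed(99L)
  ns <- 2e5L
  px <- runif(ns, -box[1L] / 2, box[1L] / 2)
  py <- runif(ns, -box[2L] / 2, box[2L] / 2)
  frac <- mean(px^2 + py^2 >= 30^2)
  vol_mc <- frac * box[1L] * box[2L] * 40 / 1000
  expect_equal(n_lip, 0.5 * vol_mc, tolerance = 0.02)
  # exact volume: analytic slab minus cylinder
  vol <- (box[1L] * box[2L] - pi * 30^2) * 40 / 1000
  expect_equal(n_lip, round(0.5 * vol))
  # lipids stay out of the cavity and inside the slab
  lip <- m$conformation[m$topology$role == "lipid", ]
  expect_true(all(sqrt(lip[, 1L]^2 + lip[, 2L]^2) >= 30))
})

test_that("ion field realises bulk density and lumen enhancement", {
  ip <- ion_field_params(concentration = 0.3,
                         lumen_enhancement = c(Na = 0),
                         box = c(100, 100, 100), seed = 3L)
  f <- generate_ion_field(ip, n_frames = 40L, species = "Na")
  cyl <- f$lumen_cylinder
  bulk <- annulus_region(c(0, 0), cyl$radius + 10, 45, cyl$zmin,
                         cyl$zmax)
  dd <- region_density_difference(f, "Na", cyl, bulk)
  # no enhancement: lumen equals bulk within Poisson error
  expect_lt(abs(dd$difference), 0.03)
  expect_equal(dd$bulk_density, 0.3 * 0.60221408, tolerance = 0.05)
  # determinism
  f2 <- generate_ion_field(ip, n_frames = 2L, species = "Na")
  f3 <- generate_ion_field(ip, n_frames = 2L, species = "Na")
  expect_identical(f2$frames, f3$frames)
})

test_that("swap ledger realises Ohm's law with Poisson statistics", {
  # G = 0: expected net charge per slice is zero
  lp0 <- ledger_params(conductance_G = 0, v_jitter_sd = 0,
                       baseline_rate = 3, seed = 11L)
  led0 <- generate_swap_ledger(lp0)
  sl0 <- compute_slice_currents(led0)
  expect_lt(abs(mean(sl0$I_pA)), 5)
  # G = 1.2 nS at a held 100 mV: mean slice current is 120 pA
  lp <- ledger_params(conductance_G = 1.2,
                      voltage_schedule = data.frame(
                        dq = 4, V_mV = 100, n_replicas = 60L),
                      v_jitter_sd = 0, baseline_rate = 0, seed = 12L)
  sl <- compute_slice_currents(generate_swap_ledger(lp))
  # 300 slices, per-slice SD ~ sqrt(mu)/(2 dt) * 160.2 ~= 22 pA
  expect_equal(mean(sl$I_pA), 120, tolerance = 0.05)
  # species/charge consistency in the ledger rows
  led <- generate_swap_ledger(ledger_params(seed = 5L))
  expect_true(all(led$ledger$charge_e[led$ledger$species == "Na"] == 1))
  expect_true(all(led$ledger$charge_e[led$ledger$species == "Cl"] == -1))
  # event times stay inside their slice window
  with(led$ledger, expect_true(all(time_ns >= (slice - 1L) * 20 &
                                     time_ns <= slice * 20)))
})

test_that("Boltzmann inversion matches analytic forms", {
  # uniform distribution -> flat potential at zero
  u <- boltzmann_invert(data.frame(x = 1:5, count = rep(7, 5)), 300)
  expect_equal(u$U, rep(0, 5))
  # two-bin (3/4, 1/4): dU = kB T ln 3
  u2 <- boltzmann_invert(data.frame(x = c(0, 1), count = c(3, 1)), 300)
  expect_equal(u2$U[2L] - u2$U[1L], kB_kcal() * 300 * log(3))
  expect_equal(u2$U[1L], 0)
  # zero-count bins are undefined, empty histograms are an error
  u3 <- boltzmann_invert(data.frame(x = 1:3, count = c(1, 0, 1)), 300)
  expect_true(is.na(u3$U[2L]))
  expect_error(boltzmann_invert(data.frame(x = 1, count = 0)), "empty")
})

test_that("radius of gyration matches hand-computed cases", {
  two <- matrix(c(0, 0, 0, 10, 0, 0), 2L, 3L, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 5)
  expect_equal(radius_of_gyration(matrix(1, 4L, 3L)), 0)
  # regular tetrahedron with unit edge: Rg = circumradius = sqrt(3/8)
  tet <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                4L, 3L, byrow = TRUE) / sqrt(8)
  expect_equal(radius_of_gyration(tet), sqrt(3 / 8))
  # mass weighting pulls Rg toward the heavy bead
  expect_lt(radius_of_gyration(two, masses = c(9, 1)),
            radius_of_gyration(two))
  # identical conformers have zero Rg percentage difference
  rg <- radius_of_gyration(ref_bundle$conformation)
  cmp <- rg_percent_difference(rg, rg)
  expect_equal(cmp$pct_diff, 0)
  expect_true(cmp$within)
})
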
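# Electrophysiology module: slice currents, IV assembly, conductance
# fitting and conductance-state distributions.

test_that("slice current matches the hand-summed estimator", {
  # 10 Na+ A->B and 4 Cl- A->B in 20 ns: (10 - 4) / 40 e/ns = 24.03 pA
  rows <- data.frame(species = c(rep("Na", 10L), rep("Cl", 4L)),
                     charge_e = c(rep(1, 10L), rep(-1, 4L)),
                     direction = "A->B")
  expect_equal(slice_current(rows, 20), 0.15 * 160.2)
  # equal and opposite swaps cancel
  rows2 <- data.frame(species = c("Na", "Na"), charge_e = c(1, 1),
                      direction = c("A->B", "B->A"))
  expect_equal(slice_current(rows2, 20), 0)
  # empty slice carries no current; bad duration is an error
  expect_equal(slice_current(rows[0L, ], 20), 0)
  expect_error(slice_current(rows, 0), "> 0")
})

test_that("slice currents equal the oracle on random ledgers", {
  set.seed(17L)
  for (i in 1:20) {
    n <- sample(0:40, 1L)
    sp <- sample(c("Na", "Cl"), n, replace = TRUE)
    rows <- data.frame(species = sp,
                       charge_e = ifelse(sp == "Na", 1, -1),
                       direction = sample(c("A->B", "B->A"), n,
                                          replace = TRUE))
    dt <- sample(c(10, 20, 50), 1L)
    expect_equal(slice_current(rows, dt), oracle_slice_current(rows, dt))
  }
})

test_that("IV assembly applies the voltage filter with logged
           exclusions", {
  set.seed(23L)
  v <- c(-150, -80, -20, 0, 15, 60, 99, 100, 101, 150)
  sl <- data.frame(replica = 1L, slice = 1:10, V_mV = v,
                   I_pA = 1.2 * v, n_events = 5L)
  class(sl) <- c("hb_slices", "data.frame")
  iv <- assemble_iv(sl, v_max = 100)
  expect_equal(sort(iv$points$V_mV), sort(v[abs(v) <= 100]))
  expect_equal(sort(iv$excluded$V_mV), c(-150, 101, 150))
  expect_true(all(iv$excluded$reason == "voltage range"))
  # nothing excluded when all points are in range
  iv2 <- assemble_iv(sl[abs(v) <= 100, ], v_max = 100)
  expect_equal(nrow(iv2$excluded), 0L)
})

test_that("conductance fit is exact on exact lines and guarded", {
  iv <- structure(list(points = data.frame(replica = 1L, slice = 1:2,
                                           V_mV = c(50, 100),
                                           I_pA = c(60, 120)),
                       excluded = NULL, v_max = 100), class = "hb_iv")
  fit <- fit_conductance(iv, "through_origin", n_resamples = 200L,
                         seed = 1L)
  expect_equal(fit$G_nS, 1.2)
  # zero currents -> zero conductance
  iv0 <- iv; iv0$points$I_pA <- 0
  expect_equal(fit_conductance(iv0, n_resamples = 200L)$G_nS, 0)
  # identical voltages are degenerate
  ivd <- iv; ivd$points$V_mV <- c(50, 50)
  expect_error(fit_conductance(ivd), "identical")
  # free intercept recovers slope and offset of an affine relation
  ivf <- iv
  ivf$points <- data.frame(replica = 1L, slice = 1:4,
                           V_mV = c(-100, -50, 50, 100),
                           I_pA = 0.8 * c(-100, -50, 50, 100) + 7)
  ff <- fit_conductance(ivf, "free_intercept", n_resamples = 200L)
  expect_equal(ff$G_nS, 0.8)
  expect_equal(ff$intercept_pA, 7)
})

test_that("generator conductance is recovered and reversal-symmetric", {
  lp <- ledger_params(conductance_G = 1.19, seed = 3L)
  led <- generate_swap_ledger(lp)
  sl <- compute_slice_currents(led)
  iv <- assemble_iv(sl, v_max = 100)
  fit <- fit_conductance(iv, n_resamples = 500L, seed = 3L)
  expect_equal(fit$G_nS, 1.19, tolerance = 3 * fit$se_nS / 1.19)
  # negating voltages and directions leaves the slope unchanged
  led2 <- led$ledger
  led2$direction <- ifelse(led2$direction == "A->B", "B->A", "A->B")
  volts2 <- led$voltages
  volts2$V_mV <- -volts2$V_mV
  sl2 <- compute_slice_currents(led2, volts2, dt_ns = 20)
  fit2 <- fit_conductance(assemble_iv(sl2), n_resamples = 500L,
                          seed = 3L)
  expect_equal(fit2$G_nS, fit$G_nS, tolerance = 1e-9)
})

test_that("conductance distribution resolves sub-conductance states", {
  # single state: unimodal near the ground truth
  lp1 <- ledger_params(conductance_G = 1.2,
                       voltage_schedule = data.frame(
                         dq = 4, V_mV = 100, n_replicas = 40L),
                       seed = 6L)
  sl1 <- compute_slice_currents(generate_swap_ledger(lp1))
  gd1 <- conductance_distribution(sl1, min_abs_V = 50)
  m1 <- conductance_modes(gd1, n_modes = 1L)
  expect_equal(m1, 1.2, tolerance = 0.1)
  # the voltage floor removes near-zero-bias slices
  gd_all <- conductance_distribution(sl1, min_abs_V = 0)
  expect_gte(length(gd_all$G_nS), length(gd1$G_nS))
  expect_true(all(abs(sl1$V_mV[abs(sl1$V_mV) < 50]) < 50))
  # two-state generator: two modes near 1.5 and 0.5 nS
  lp2 <- ledger_params(conductance_G = c(1.5, 0.5),
                       state_probs = c(0.5, 0.5),
                       voltage_schedule = data.frame(
                         dq = 4, V_mV = 100, n_replicas = 40L),
                       seed = 7L)
  sl2 <- compute_slice_currents(generate_swap_ledger(lp2))
  gd2 <- conductance_distribution(sl2, min_abs_V = 50)
  modes <- sort(conductance_modes(gd2, n_modes = 2L))
  expect_equal(modes[1L], 0.5, tolerance = 0.3)
  expect_equal(modes[2L], 1.5, tolerance = 0.1)
})
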
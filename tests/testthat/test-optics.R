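test_that("Cherenkov threshold follows the refractive-index closed form", {
  expect_equal(cherenkov_threshold(2.2), 62.74, tolerance = 1e-3)
  expect_equal(cherenkov_threshold(2.15), 66.18, tolerance = 1e-3)
  expect_lt(cherenkov_threshold(1e6), 1e-6)   # n -> Inf: threshold -> 0
  expect_error(cherenkov_threshold(1), "exceed 1")
})

test_that("Cherenkov yield curve is calibrated, thresholded and superadditive", {
  cfg <- optical_config()
  expect_equal(cherenkov_mean_yield(511, cfg), 17, tolerance = 1e-6)
  expect_equal(cherenkov_mean_yield(50, cfg), 0)   # below ~63 keV threshold
  y <- cherenkov_mean_yield(seq(0, 511, 1), cfg)
  expect_true(all(diff(y) >= 0))                   # monotone non-decreasing
  # splitting a deposit strictly lowers the total yield (convexity):
  # the mechanism behind the InterCS prompt-photon deficit
  expect_lt(cherenkov_mean_yield(340.67, cfg) + cherenkov_mean_yield(170.33, cfg),
            cherenkov_mean_yield(511, cfg))
})

test_that("photon emission follows the configured Poisson statistics", {
  cfg <- optical_config()
  # no light below threshold when scintillation is off
  dark <- optical_config(scint_yield_per_keV = 0)
  s <- make_sites(1, 1, 50, z_mm = 5, t_ps = 20)
  expect_identical(nrow(emit_photons(s, dark, detect = FALSE)), 0L)
  # mean Cherenkov count at 511 keV ~ 17 over repeated draws
  set.seed(10)
  s511 <- make_sites(rep(1:2000, each = 1), 1, rep(511, 2000),
                     z_mm = 5, t_ps = 0)
  ph <- emit_photons(s511, dark, detect = FALSE)
  expect_lt(abs(nrow(ph) / 2000 - 17), 3 * sqrt(17 / 2000))
  # scintillation-only, untruncated: fraction emitted within 1 ns of the
  # vertex follows the exponential CDF at the 300 ns decay constant
  set.seed(11)
  so <- optical_config(cherenkov_yield_511 = 0, scint_yield_per_keV = 0.2,
                       scint_horizon_ps = 3e7)
  s500 <- make_sites(1:500, 1, rep(511, 500), z_mm = 5, t_ps = rep(0, 500))
  phs <- emit_photons(s500, so, detect = FALSE)
  frac <- mean(phs$t_emit_ps <= 1000)
  expect_lt(abs(frac - (1 - exp(-1 / 300))), 0.001)
})

test_that("photon transport reproduces straight-line transit arithmetic", {
  g <- detector_geometry()
  cfg <- optical_config(esr_reflectivity = 1, absorption_length_mm = 1e9,
                        sptr_sigma_ps = 0)
  # photons emitted at the detector face: earliest arrivals ~ emission time
  ph_face <- data.frame(event_id = 1:5000, crystal_id = 1L, x_mm = 1.25,
                        y_mm = 1.4, z_mm = 15, t_emit_ps = 0,
                        type = "cherenkov")
  det <- transport_photons(ph_face, g, cfg, detect = FALSE)
  expect_lt(min(det$t_ps), 0.5)
  # photons from the front face cannot beat the straight transit of 15 mm
  ph0 <- data.frame(event_id = 1:5000, crystal_id = 1L, x_mm = 1.25,
                    y_mm = 1.4, z_mm = 0, t_emit_ps = 0, type = "cherenkov")
  det0 <- transport_photons(ph0, g, cfg, detect = FALSE)
  transit <- 15 / (0.2998 / cfg$group_index)
  expect_true(all(det0$t_ps >= transit - 1e-9))
  expect_lt(min(det0$t_ps), transit * 1.02)  # the fastest are near-straight
})

test_that("detected fraction matches the downward-hemisphere argument", {
  # lossless crystal, PDE applied at generation: of the emitted photons,
  # those aimed at the detector (half) arrive directly; the reflected upward
  # half also survives when reflectivity is 1, so all photons arrive
  g <- detector_geometry()
  cfg <- optical_config(esr_reflectivity = 1, absorption_length_mm = 1e12,
                        sptr_sigma_ps = 0)
  set.seed(12)
  ph <- data.frame(event_id = 1:20000, crystal_id = 1L, x_mm = 1.25,
                   y_mm = 1.4, z_mm = 7.5, t_emit_ps = 0, type = "cherenkov")
  det <- transport_photons(ph, g, cfg, detect = FALSE)
  expect_gt(nrow(det) / 20000, 0.999)
  # with reflectivity 0 only reflection-free paths survive: downward photons
  # that cross no transverse wall, a small cone in this narrow pixel
  cfg0 <- optical_config(esr_reflectivity = 0, absorption_length_mm = 1e12)
  set.seed(13)
  det0 <- transport_photons(ph, g, cfg0, detect = FALSE)
  p <- nrow(det0) / 20000
  expect_lt(p, 0.5)
  expect_gt(p, 0.001)
  expect_true(all(det0$n_reflections == 0))
})

test_that("crystal timestamps equal the minimum over channel first photons", {
  cfg <- sim_config()
  sim <- simulate_detector(800, cfg, seed = 14)
  ro <- sim$readout
  expect_equal(ro$T1_ps, pmin(ro$T1A_ps, ro$T1B_ps, na.rm = TRUE),
               tolerance = 1e-12)
  # absent timestamp iff no detected photon in that crystal
  ph <- sim$photons
  has2 <- ro$event_id %in% ph$event_id[ph$crystal_id == 2]
  expect_identical(!is.na(ro$T2_ps), has2)
  # recompute channel firsts from the photon table
  m <- stats::aggregate(t_ps ~ event_id, data = ph[ph$crystal_id == 1, ], FUN = min)
  expect_equal(ro$T1_ps[match(m$event_id, ro$event_id)], m$t_ps)
})

test_that("energy smearing is honest: off means exact, on means sqrt(E) scaling", {
  cfg <- sim_config()
  sim <- simulate_detector(500, cfg, seed = 15, smear_energy = FALSE)
  expect_equal(sim$readout$E1_keV, sim$events$E1_true)
  set.seed(16)
  n <- 2e4
  ro <- build_readout(data.frame(event_id = 1:n, E1_true = 511, E2_true = 0),
                      data.frame(event_id = integer(0), crystal_id = integer(0),
                                 channel = character(0), t_ps = numeric(0),
                                 type = character(0)),
                      optical_config())
  expect_equal(sd(ro$E1_keV) * 2.3548 / 511, 0.15, tolerance = 0.02)
  expect_true(all(ro$E2_keV == 0))
})

test_that("reference timestamps carry the configured 83 ps FWHM jitter", {
  set.seed(17)
  n <- 1e5
  ro <- build_readout(data.frame(event_id = 1:n, E1_true = 511, E2_true = 0),
                      data.frame(event_id = integer(0), crystal_id = integer(0),
                                 channel = character(0), t_ps = numeric(0),
                                 type = character(0)),
                      optical_config())
  w <- fwhm_fwtm(ro$tref_ps, bin_width = 2)
  expect_lt(abs(w$fwhm - 83), 2)
})

test_that("mean detected photons increase with deposited energy", {
  cfg <- optical_config()
  g <- detector_geometry()
  set.seed(18)
  counts <- vapply(c(170, 340, 511), function(E) {
    s <- make_sites(1:3000, 1, rep(E, 3000), z_mm = 7.5, t_ps = 0)
    ph <- emit_photons(s, cfg, detect = TRUE)
    nrow(transport_photons(ph, g, cfg, detect = TRUE)) / 3000
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("disabling scintillation strictly reduces mean prompt counts", {
  cfg <- sim_config()
  cfg2 <- cfg
  cfg2$optics$scint_yield_per_keV <- 0
  sim1 <- simulate_detector(4000, cfg, seed = 19)
  sim2 <- simulate_detector(4000, cfg2, seed = 19)
  cl1 <- classify_events(sim1); cl2 <- classify_events(sim2)
  m1 <- mean(cl1$n_prompt[cl1$assigned_class == "FED"], na.rm = TRUE)
  m2 <- mean(cl2$n_prompt[cl2$assigned_class == "FED"], na.rm = TRUE)
  expect_gt(m1, m2)
})
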
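test_that("geometry constructor validates and locates points", {
  expect_error(detector_geometry(pixel_pitch_x = -1), "pixel_pitch_x")
  expect_error(detector_geometry(length_z = 0), "length_z")
  g <- detector_geometry()
  # crystal 1, gap, crystal 2, outside
  expect_identical(crystal_at(g, c(1.2, 2.52, 3.0, 6.0), 1.4, 7),
                   c(1L, 0L, 2L, -1L))
  expect_identical(crystal_at(g, 1.2, 1.4, 16), -1L)
  expect_identical(crystal_at(g, 1.2, 3.5, 7), -1L)
})

test_that("every history conserves energy exactly and orders site times", {
  g <- simulate_gamma_events(3000, seed = 6)
  ev <- g$events
  expect_lt(max(abs(ev$edep_total + ev$escaped_keV - 511)), 1e-9)
  expect_equal(ev$E1_true + ev$E2_true, ev$edep_total)
  # strictly increasing times within each history
  s <- g$sites
  by_ev <- split(s$t_ps, s$event_id)
  expect_true(all(vapply(by_ev, function(t) all(diff(t) > 0), logical(1))))
  # deposits lie inside a crystal and are positive
  expect_true(all(s$edep_keV > 0 & s$edep_keV <= 511))
  expect_true(all(crystal_at(g$geometry, s$x_mm, s$y_mm, s$z_mm) == s$crystal_id))
  # gamma flight: first site time equals distance from entry over c
  first <- s[s$site_index == 1, ]
  d <- sqrt((first$x_mm - ev$x0_mm[first$event_id])^2 +
            (first$y_mm - ev$y0_mm[first$event_id])^2 + first$z_mm^2)
  expect_equal(first$t_ps, d / 0.2998, tolerance = 1e-9)
})

test_that("interaction probability matches closed-form attenuation", {
  n <- 1e5
  g <- simulate_gamma_events(n, seed = 7)
  mu <- attenuation(511, g$material)$mu_total
  p_expect <- 1 - exp(-mu * 1.5)  # 15 mm of BGO along the beam
  p_obs <- mean(g$events$n_sites >= 1)
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(p_obs - p_expect), 4 * se)
})

test_that("truth labels follow their definitions on constructed events", {
  sites <- rbind(
    make_sites(1, 1, 511),                                   # PE
    make_sites(c(2, 2), c(1, 2), c(340.67, 170.33)),         # InterCS
    make_sites(c(3, 3), c(2, 2), c(300, 211)),               # IntraCS + Pene
    make_sites(4, 1, 100))                                   # below window
  ge <- make_gamma_events(sites, 4)
  lab <- truth_label(ge)
  expect_identical(lab$truth_class, c("PE", "InterCS", "IntraCS", "rejected"))
  expect_identical(lab$pene, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("collimated irradiation concentrates truth events in crystal 1", {
  g <- simulate_gamma_events(20000, seed = 8)
  lab <- truth_label(g)
  keep <- lab$truth_class %in% c("PE", "IntraCS")
  inter <- lab$truth_class == "InterCS"
  expect_gt(sum(keep), 5 * sum(inter))
  # PE + IntraCS dominate and sit in the irradiated crystal
  expect_true(all(g$events$E1_true[keep] > 425))
})

test_that("DOI separation fraction behaves at its threshold limits", {
  g <- simulate_gamma_events(30000, seed = 9)
  f0 <- delta_doi_fraction(g, threshold = 0)
  f2 <- delta_doi_fraction(g, threshold = 2)
  fbig <- delta_doi_fraction(g, threshold = 15)
  expect_equal(f0, 1)           # continuous depths: ties have measure zero
  expect_equal(fbig, 0)         # cannot exceed the crystal length
  expect_true(f2 > 0 && f2 < 0.5)
})
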
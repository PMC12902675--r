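# Closed-form Gaussian width constants
.g_fwhm <- 2 * sqrt(2 * log(2))
.g_fwtm <- 2 * sqrt(2 * log(10))

# Brute-force width oracle: evaluate an analytic density on a dense grid and
# find the half/tenth-maximum crossings by linear interpolation.
grid_width <- function(dens, frac, lim = c(-2000, 2000)) {
  x <- seq(lim[1], lim[2], by = 0.05)
  y <- dens(x)
  level <- frac * max(y)
  above <- which(y >= level)
  xl <- x[min(above)]; xr <- x[max(above)]
  xr - xl
}

test_that("FWHM/FWTM estimator matches Gaussian closed forms", {
  set.seed(26)
  x <- rnorm(1e5, 0, 100)
  w <- fwhm_fwtm(x, bin_width = 10)
  expect_lt(abs(w$fwhm - .g_fwhm * 100), 3)
  expect_lt(abs(w$fwtm - .g_fwtm * 100), 6)
  expect_gte(w$fwtm, w$fwhm)
})

test_that("estimator matches a dense-grid oracle on a two-Gaussian mixture", {
  dens <- function(x) 0.7 * dnorm(x, 0, 80) + 0.3 * dnorm(x, 0, 400)
  set.seed(27)
  comp <- runif(2e5) < 0.7
  x <- ifelse(comp, rnorm(2e5, 0, 80), rnorm(2e5, 0, 400))
  w <- fwhm_fwtm(x, bin_width = 10)
  expect_lt(abs(w$fwhm - grid_width(dens, 0.5)), 6)
  expect_lt(abs(w$fwtm - grid_width(dens, 0.1)), 20)
})

test_that("estimator is invariant under histogram origin shifts", {
  set.seed(28)
  x <- rnorm(5e4, 0, 100)
  w0 <- fwhm_fwtm(x, bin_width = 10)
  w1 <- fwhm_fwtm(x + 3.7, bin_width = 10)   # shifts the bin origin
  expect_lt(abs(w0$fwhm - w1$fwhm), 5)
  expect_error(fwhm_fwtm(rnorm(50)), "at least 100")
})

test_that("coincidence deltas subtract the reference and count skips", {
  cl <- data.frame(E1_keV = c(511, 500, 480), E2_keV = c(0, 10, 20),
                   T1_ps = c(100, NA, NA), T2_ps = c(200, 150, NA),
                   tref_ps = c(10, 20, 30))
  d <- coincidence_deltas(cl, "min")
  expect_equal(as.numeric(d), c(90, 130))
  expect_identical(attr(d, "n_skipped"), 1L)
  # energy strategy falls back to the present timestamp
  de <- coincidence_deltas(cl, "energy")
  expect_equal(as.numeric(de), c(90, 130))
})

test_that("the margin sweep is symmetric for exchangeable timestamps", {
  set.seed(29)
  n <- 30000
  # exchangeable pair: both crystals identically distributed
  T1 <- rnorm(n, 500, 120); T2 <- rnorm(n, 500, 120)
  cl <- data.frame(E1_keV = 255, E2_keV = 256, T1_ps = T1, T2_ps = T2,
                   tref_ps = rnorm(n, 0, 35))
  ks <- sweep_k(cl, k_grid = c(-400, -200, 0, 200, 400))
  expect_identical(ks$k_ps, c(-400, -200, 0, 200, 400))
  expect_lt(max(abs(ks$fwhm_ps - rev(ks$fwhm_ps))), 12)
  # k -> +Inf is the crystal-1-only estimator
  ks_inf <- sweep_k(cl, k_grid = 1e9)
  w1 <- fwhm_fwtm(T1 - cl$tref_ps)
  expect_equal(ks_inf$fwhm_ps, w1$fwhm)
  expect_error(sweep_k(cl[0, ]), "empty")
})

test_that("quadrant fractions sum to one and detect concordant toys", {
  # deterministic toy where timing order equals energy rank: no discordance
  cl <- data.frame(E1_keV = c(400, 100, 300), E2_keV = c(100, 400, 200),
                   T1_ps = c(10, 90, 20), T2_ps = c(50, 30, 60),
                   tref_ps = 0)
  q <- quadrant_fractions(cl)
  expect_equal(sum(q$fractions), 1)
  expect_equal(q$discordant, 0)
  # flipping one event's timestamps creates a discordant quadrant
  cl$T1_ps[1] <- 60; cl$T2_ps[1] <- 10
  expect_equal(quadrant_fractions(cl)$discordant, 1 / 3)
})

test_that("fwd/bwd fractions sum to one and honour constructed sets", {
  cl <- data.frame(E1_keV = c(300, 400), E2_keV = c(100, 50))
  f <- fwd_bwd_fractions(cl)
  expect_equal(sum(f), 1)
  expect_equal(unname(f["BWD"]), 1)  # all E1 > E2
})

test_that("travel-time order statistics are ordered in n and skip small events", {
  ph <- data.frame(event_id = c(1, 1, 1, 2, 2, 3),
                   t_ps = c(30, 10, 20, 5, 50, 40))
  ev <- data.frame(event_id = 1:3,
                   truth_class = c("PE", "PE", "IntraCS"))
  t1 <- travel_time_stats(ph, ev, order_n = 1)
  t2 <- travel_time_stats(ph, ev, order_n = 2)
  expect_equal(t1$mean_ps[t1$truth_class == "PE"], mean(c(10, 5)))
  expect_equal(t2$mean_ps[t2$truth_class == "PE"], mean(c(20, 50)))
  expect_identical(attr(t2, "n_skipped"), 1L)  # event 3 has one photon
  # n = 2 mean is never below n = 1 mean within a class
  expect_true(all(t2$mean_ps >= t1$mean_ps[match(t2$truth_class, t1$truth_class)]))
})

test_that("asymmetry binning flags under-populated bins", {
  set.seed(30)
  n <- 400
  cl <- data.frame(E1_keV = 255 + runif(n, -40, 40),
                   E2_keV = 255 + runif(n, -40, 40),
                   T1_ps = rnorm(n, 500, 80), T2_ps = rnorm(n, 500, 80),
                   tref_ps = rnorm(n, 0, 35),
                   n_prompt = rpois(n, 4))
  cl$A <- energy_asymmetry(cl$E1_keV, cl$E2_keV)
  ab <- asymmetry_binned_analysis(cl, breaks = seq(0, 1, 0.2), min_n = 100)
  expect_identical(nrow(ab), 5L)
  expect_true(all(!ab$reported[ab$n < 100]))
  expect_true(all(is.na(ab$ctr_fwhm_ps[!ab$reported])))
})

test_that("IntraCS prevalence grows with transverse pitch", {
  r <- aspect_ratio_study(pitches = c(1, 3, 15), n_events = 8000, seed = 31)
  expect_true(all(diff(r$frac_intracs) > 0))
  expect_lt(r$frac_intracs[1], 0.25)   # needle pixel: scatter escapes
  expect_error(aspect_ratio_study(pitches = c(-1)), "positive")
})
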
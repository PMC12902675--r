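# Independent oracle: solve Compton kinematics numerically from raw
# energy-momentum conservation instead of the closed-form wavelength shift.
brute_force_scattered <- function(E, theta) {
  me <- 511
  resid <- function(Ep) {
    pe2 <- E^2 + Ep^2 - 2 * E * Ep * cos(theta)  # electron momentum^2 (keV^2)
    (E + me - Ep) - sqrt(pe2 + me^2)             # energy conservation
  }
  stats::uniroot(resid, c(1e-9, E), tol = 1e-12)$root
}

test_that("Compton kinematics match the closed-form benchmark points", {
  k <- compton_kinematics(511, pi)
  expect_equal(k$scattered, 170.3333, tolerance = 1e-4)
  expect_equal(k$electron, 340.6667, tolerance = 1e-4)
  expect_equal(compton_kinematics(511, 0)$scattered, 511)
  expect_equal(compton_kinematics(511, 0)$electron, 0)
  expect_equal(compton_kinematics(511, pi / 2)$scattered, 255.5)
})

test_that("Compton formula agrees with a brute-force energy-momentum solver", {
  set.seed(3)
  E <- runif(100, 20, 511)
  th <- runif(100, 1e-3, pi - 1e-3)
  k <- compton_kinematics(E, th)
  oracle <- mapply(brute_force_scattered, E, th)
  expect_lt(max(abs(k$scattered - oracle)), 1e-6)
  # energy is conserved exactly
  expect_equal(k$scattered + k$electron, E)
})

test_that("Klein-Nishina sampler matches the analytic angular density", {
  set.seed(4)
  n <- 1e5
  th <- sample_klein_nishina_angle(511, n)
  expect_true(all(th >= 0 & th <= pi))
  # forward dominance at 511 keV
  expect_gt(mean(th < pi / 2), 0.5)
  # chi-squared against the numerically normalised analytic density
  breaks <- seq(0, pi, length.out = 21)
  obs <- table(cut(th, breaks))
  p <- vapply(seq_len(20), function(i)
    stats::integrate(klein_nishina_density, breaks[i], breaks[i + 1],
                     energy = 511)$value, numeric(1))
  chi <- stats::chisq.test(as.numeric(obs), p = p / sum(p))
  expect_gt(chi$p.value, 0.01)
})

test_that("the low-energy limit of the sampler is Thomson-symmetric", {
  set.seed(5)
  th <- sample_klein_nishina_angle(0.05, 4e4)
  # Thomson scattering is symmetric in cos(theta)
  ct <- cos(th)
  expect_lt(abs(mean(ct)), 3 * sd(ct) / sqrt(length(ct)))
  # and the analytic density integrates symmetrically too
  fwd <- stats::integrate(klein_nishina_density, 0, pi / 2, energy = 0.05)$value
  expect_equal(fwd, 0.5, tolerance = 1e-3)
})
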
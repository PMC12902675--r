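# Physical constants (keV / mm / ps unit system used throughout the package)
.const <- list(
  c_mm_ps  = 0.2998,        # speed of light in vacuum [mm/ps]
  mec2_keV = 511.0,         # electron rest energy [keV]
  re2_cm2  = 7.940787e-26,  # classical electron radius squared [cm^2]
  avogadro = 6.02214076e23
)

#' Total Klein-Nishina cross-section per electron
#'
#' Closed-form total cross-section for Compton scattering of a photon of the
#' given energy off a free electron.
#'
#' @param energy_keV photon energy in keV (vectorised).
#' @return cross-section in cm^2 per electron.
#' @export
klein_nishina_total_cs <- function(energy_keV) {
  stopifnot(all(energy_keV > 0))
  a <- energy_keV / .const$mec2_keV
  thomson <- 8 * pi / 3 * .const$re2_cm2
  out <- ifelse(
    a < 1e-4,
    thomson * (1 - 2 * a),  # low-energy expansion, avoids cancellation
    2 * pi * .const$re2_cm2 *
      ((1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
         log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2)
  )
  out
}

#' Construct a material attenuation model
#'
#' A material model is a lookup table of the total linear attenuation
#' coefficient and the photoelectric interaction fraction on an energy grid,
#' interpolated log-log by [attenuation()].  Only photoelectric absorption and
#' incoherent (Compton) scattering are modelled; Rayleigh scattering, Doppler
#' broadening and fluorescence escape are outside the transport model.
#'
#' @param table data.frame with columns `energy_keV`, `mu_total` (1/cm) and
#'   `f_photoelectric` (in \[0, 1\]).  `mu_total` must be positive and
#'   non-increasing with energy.
#' @param density material density in g/cm^3.
#' @param energy_cutoff tracking cutoff in keV; photons falling below it are
#'   absorbed locally.
#' @return an object of class `material_model`.
#' @seealso [bgo_material()] for the default BGO tables.
#' @export
material_model <- function(table, density, energy_cutoff = 10) {
  stopifnot(is.data.frame(table),
            all(c("energy_keV", "mu_total", "f_photoelectric") %in% names(table)))
  tb <- table[order(table$energy_keV), , drop = FALSE]
  if (any(tb$mu_total <= 0))
    stop("material_model: mu_total must be positive")
  if (any(tb$f_photoelectric < 0 | tb$f_photoelectric > 1))
    stop("material_model: f_photoelectric must lie in [0, 1]")
  if (any(diff(tb$mu_total) > 0))
    stop("material_model: mu_total must not increase with energy")
  if (density <= 0) stop("material_model: density must be positive")
  structure(list(table = tb, density = as.numeric(density),
                 energy_cutoff = as.numeric(energy_cutoff)),
            class = "material_model")
}

#' Default BGO cross-section model
#'
#' Builds the attenuation table for bismuth germanate (Bi4Ge3O12).  The
#' incoherent (Compton) component is computed from the analytic Klein-Nishina
#' total cross-section times the electron density of BGO; the photoelectric
#' component follows the textbook `tau ~ E^-3` law, anchored so that the
#' photoelectric fraction at 511 keV equals `photofraction_511`.  The table is
#' smooth (no absorption-edge structure) by construction, which keeps the
#' attenuation monotone in energy; edge effects and fluorescence escape are
#' second order for the quantities this package computes.
#'
#' @param density BGO density, g/cm^3.
#' @param photofraction_511 photoelectric fraction of the total interaction
#'   probability at 511 keV.
#' @param pe_exponent exponent of the photoelectric energy power law.
#' @param energy_cutoff tracking cutoff, keV (also the lower edge of the table).
#' @param n_grid number of logarithmically spaced grid energies.
#' @return a `material_model`.
#' @export
bgo_material <- function(density = 7.13, photofraction_511 = 0.42,
                         pe_exponent = 3, energy_cutoff = 10, n_grid = 72) {
  density <- as.numeric(density); photofraction_511 <- as.numeric(photofraction_511)
  pe_exponent <- as.numeric(pe_exponent); energy_cutoff <- as.numeric(energy_cutoff)
  n_grid <- as.integer(n_grid)
  z_over_a <- 0.42062  # electrons per amu for Bi4Ge3O12
  e_grid <- exp(seq(log(energy_cutoff), log(511), length.out = n_grid))
  n_e <- density * .const$avogadro * z_over_a          # electrons / cm^3
  mu_c <- n_e * klein_nishina_total_cs(e_grid)         # 1/cm
  mu_c_511 <- n_e * klein_nishina_total_cs(511)
  mu_pe_511 <- photofraction_511 / (1 - photofraction_511) * mu_c_511
  mu_pe <- mu_pe_511 * (511 / e_grid)^pe_exponent
  tb <- data.frame(energy_keV = e_grid,
                   mu_total = mu_c + mu_pe,
                   f_photoelectric = mu_pe / (mu_c + mu_pe))
  m <- material_model(tb, density = density, energy_cutoff = energy_cutoff)
  attr(m, "args") <- list(density = density,
                          photofraction_511 = photofraction_511,
                          pe_exponent = pe_exponent,
                          energy_cutoff = energy_cutoff, n_grid = n_grid)
  m
}

#' Interpolate attenuation coefficients
#'
#' Returns the total linear attenuation coefficient and photoelectric fraction
#' of a material at the requested energies.  `mu_total` is interpolated
#' log-log; `f_photoelectric` linearly in log-energy.
#'
#' @param energy photon energies in keV (vectorised); must lie within the
#'   material table's energy domain.
#' @param material a [material_model()].
#' @return list with numeric vectors `mu_total` (1/cm) and `f_pe`.
#' @export
attenuation <- function(energy, material = bgo_material()) {
  tb <- material$table
  lo <- min(tb$energy_keV); hi <- max(tb$energy_keV)
  if (any(energy < lo - 1e-9 | energy > hi + 1e-9))
    stop(sprintf("attenuation: energy outside table domain [%g, %g] keV", lo, hi))
  e <- pmin(pmax(energy, lo), hi)
  mu <- exp(stats::approx(log(tb$energy_keV), log(tb$mu_total), xout = log(e))$y)
  fpe <- stats::approx(log(tb$energy_keV), tb$f_photoelectric, xout = log(e))$y
  list(mu_total = mu, f_pe = fpe)
}

#' Sample exponential free paths
#'
#' Draws free-path lengths from the exponential attenuation law.
#'
#' @param mu linear attenuation coefficient(s) in 1/cm; must be positive.
#' @param n number of draws (defaults to `length(mu)`, recycling `mu`).
#' @return path lengths in mm.
#' @export
sample_free_path <- function(mu, n = length(mu)) {
  if (any(mu <= 0)) stop("sample_free_path: mu must be positive")
  10 * stats::rexp(n, rate = mu)  # mu is per cm; convert cm -> mm
}

#' @export
print.material_model <- function(x, ...) {
  cat("<material_model> density", x$density, "g/cm^3, cutoff",
      x$energy_cutoff, "keV,", nrow(x$table), "grid energies on [",
      round(min(x$table$energy_keV), 2), ",",
      round(max(x$table$energy_keV), 2), "] keV\n")
  invisible(x)
}
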
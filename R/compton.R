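#' Compton scattering kinematics
#'
#' Energy of the scattered photon and of the recoil electron for a photon of
#' the given energy scattering through the given polar angle, from
#' energy-momentum conservation on a free electron at rest.
#'
#' @param energy incident photon energy in keV (vectorised).
#' @param angle scattering angle in radians, in \[0, pi\] (vectorised).
#' @return list with numeric vectors `scattered` and `electron`, in keV.
#' @examples
#' compton_kinematics(511, pi)   # 180 degree backscatter: 170.3 / 340.7 keV
#' @export
compton_kinematics <- function(energy, angle) {
  stopifnot(all(energy > 0), all(angle >= 0 & angle <= pi))
  scattered <- energy / (1 + (energy / .const$mec2_keV) * (1 - cos(angle)))
  list(scattered = scattered, electron = energy - scattered)
}

#' Klein-Nishina angular density
#'
#' Probability density of the Compton scattering polar angle theta at a given
#' photon energy, i.e. `dsigma/dtheta` normalised to integrate to one on
#' \[0, pi\].  Normalisation is by numeric integration.
#'
#' @param theta polar angles in radians (vectorised).
#' @param energy photon energy in keV (scalar).
#' @return density values.
#' @export
klein_nishina_density <- function(theta, energy) {
  stopifnot(length(energy) == 1, energy > 0)
  f <- function(th) {
    ct <- cos(th)
    r <- 1 / (1 + (energy / .const$mec2_keV) * (1 - ct))
    r^2 * (r + 1 / r - (1 - ct^2)) * sin(th)
  }
  z <- stats::integrate(f, 0, pi, rel.tol = 1e-10)$value
  f(theta) / z
}

#' Sample Compton scattering angles from the Klein-Nishina distribution
#'
#' Rejection sampling of the polar scattering angle.  The unnormalised density
#' in `cos(theta)` is `r^2 (r + 1/r - sin^2 theta)` with
#' `r = E'/E <= 1`, which is bounded by its forward value 2, giving a simple
#' uniform envelope.
#'
#' @param energy photon energy in keV; scalar or a vector of length `n`.
#' @param n number of angles to draw.
#' @return polar angles in radians.
#' @export
sample_klein_nishina_angle <- function(energy, n = length(energy)) {
  stopifnot(all(energy > 0))
  alpha <- rep_len(energy / .const$mec2_keV, n)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    m <- length(todo)
    ct <- stats::runif(m, -1, 1)
    r <- 1 / (1 + alpha[todo] * (1 - ct))
    f <- r^2 * (r + 1 / r - (1 - ct^2))
    acc <- stats::runif(m) * 2 < f
    out[todo[acc]] <- acos(ct[acc])
    todo <- todo[!acc]
  }
  out
}
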
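#' Optical and readout model configuration
#'
#' Parameters of the optical photon generation, transport and SiPM detection
#' model.  Two refractive indices are kept: `n_cherenkov` (emission-weighted
#' phase index, sets the Cherenkov threshold and yield curve) and
#' `group_index` (group index at the Cherenkov-weighted wavelengths, sets the
#' optical propagation speed; BGO is strongly dispersive in the blue, so the
#' group index is appreciably larger than the phase index).
#'
#' @param n_phase BGO phase refractive index at the emission peak.
#' @param n_cherenkov effective emission-weighted index used for the Cherenkov
#'   threshold and yield calibration.
#' @param group_index group refractive index used for photon transport speed.
#' @param cherenkov_yield_511 mean Cherenkov photons produced by a 511 keV
#'   photoelectron (calibration point of the yield curve).
#' @param cherenkov_spread_ps uniform emission-time spread of Cherenkov
#'   photons, ps.
#' @param scint_yield_per_keV scintillation photons per keV.
#' @param scint_decay_ns scintillation decay constant, ns.
#' @param scint_rise_ps scintillation rise time, ps.
#' @param scint_horizon_ps importance truncation: scintillation photons
#'   emitted later than this after their vertex are not generated (only the
#'   first few ns matter for prompt timing).
#' @param esr_reflectivity survival probability per wall reflection.
#' @param absorption_length_mm bulk optical absorption length, mm.
#' @param pde SiPM photon detection efficiency.
#' @param detection_scale scalar calibration knob multiplying `pde`
#'   (see [calibrate_detection_scale()]).
#' @param sptr_sigma_ps single-photon time resolution (Gaussian sigma), ps.
#' @param energy_res_fwhm_511 relative energy resolution (FWHM) at 511 keV;
#'   the absolute FWHM scales as sqrt(E).
#' @param crosstalk_fraction fraction of detected photons reassigned to the
#'   neighbouring crystal's channels (optical crosstalk leakage; 0 disables).
#' @param ref_fwhm_ps timing jitter (FWHM) of the reference detector, ps.
#' @return an object of class `optical_config`.
#' @export
optical_config <- function(n_phase = 2.15, n_cherenkov = 2.2,
                           group_index = 2.55,
                           cherenkov_yield_511 = 17,
                           cherenkov_spread_ps = 1,
                           scint_yield_per_keV = 8.2,
                           scint_decay_ns = 300,
                           scint_rise_ps = 0,
                           scint_horizon_ps = 5000,
                           esr_reflectivity = 0.95,
                           absorption_length_mm = 400,
                           pde = 0.25,
                           detection_scale = 1,
                           sptr_sigma_ps = 40,
                           energy_res_fwhm_511 = 0.15,
                           crosstalk_fraction = 0,
                           ref_fwhm_ps = 83) {
  frac <- c(esr_reflectivity = esr_reflectivity, pde = pde,
            crosstalk_fraction = crosstalk_fraction)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad))
    stop("optical_config: ", paste(bad, collapse = ", "), " must lie in [0, 1]")
  if (n_phase <= 1 || n_cherenkov <= 1 || group_index <= 1)
    stop("optical_config: refractive indices must exceed 1")
  if (cherenkov_yield_511 < 0 || scint_yield_per_keV < 0)
    stop("optical_config: yields must be >= 0")
  if (detection_scale < 0) stop("optical_config: detection_scale must be >= 0")
  fields <- as.list(environment())[c(
    "n_phase", "n_cherenkov", "group_index", "cherenkov_yield_511",
    "cherenkov_spread_ps", "scint_yield_per_keV", "scint_decay_ns",
    "scint_rise_ps", "scint_horizon_ps", "esr_reflectivity",
    "absorption_length_mm", "pde", "detection_scale", "sptr_sigma_ps",
    "energy_res_fwhm_511", "crosstalk_fraction", "ref_fwhm_ps")]
  structure(lapply(fields, as.numeric), class = "optical_config")
}

#' Cherenkov emission threshold
#'
#' Electron kinetic energy above which Cherenkov light is emitted in a medium
#' of refractive index `n`: the electron must exceed the local phase velocity
#' of light, giving `T = 511 (1/sqrt(1 - 1/n^2) - 1)` keV.
#'
#' @param n refractive index (> 1).
#' @return threshold kinetic energy in keV.
#' @examples cherenkov_threshold(2.2)  # about 63 keV in BGO
#' @export
cherenkov_threshold <- function(n) {
  if (any(n <= 1)) stop("cherenkov_threshold: n must exceed 1 for Cherenkov emission")
  .const$mec2_keV * (1 / sqrt(1 - 1 / n^2) - 1)
}

# Cached cumulative Frank-Tamm-style yield curve N(T) for a given (n, yield)
.cherenkov_cache <- new.env(parent = emptyenv())

cherenkov_yield_curve <- function(n, yield_511) {
  key <- paste(format(n, digits = 12), format(yield_511, digits = 12))
  cur <- .cherenkov_cache[[key]]
  if (!is.null(cur)) return(cur)
  tg <- seq(0, .const$mec2_keV, by = 0.25)
  gam <- 1 + tg / .const$mec2_keV
  beta2 <- 1 - 1 / gam^2
  g <- pmax(0, 1 - 1 / (beta2 * n^2))
  g[1] <- 0
  cum <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * diff(tg)))
  cur <- list(T = tg, N = cum * yield_511 / cum[length(cum)])
  .cherenkov_cache[[key]] <- cur
  cur
}

#' Mean Cherenkov photon yield of a recoil electron
#'
#' Mean number of Cherenkov photons emitted while an electron of the given
#' kinetic energy slows down, from a Frank-Tamm-style integral
#' `N(T) = Y * integral_0^T max(0, 1 - 1/(beta^2 n^2)) dT'` with the constant
#' `Y` fixed so that `N(511 keV)` equals the configured yield.  Zero below the
#' Cherenkov threshold, monotone non-decreasing and convex above it (which is
#' why splitting a deposit across vertices lowers the total yield).
#'
#' @param electron_energy electron kinetic energies, keV (0 to 511).
#' @param cfg an [optical_config()].
#' @return mean photon counts.
#' @export
cherenkov_mean_yield <- function(electron_energy, cfg = optical_config()) {
  stopifnot(all(electron_energy >= 0), all(electron_energy <= .const$mec2_keV))
  cur <- cherenkov_yield_curve(cfg$n_cherenkov, cfg$cherenkov_yield_511)
  stats::approx(cur$T, cur$N, xout = electron_energy)$y
}

#' Generate optical photons at interaction vertices
#'
#' Draws Cherenkov and scintillation photon emissions for each ground-truth
#' interaction site.  Cherenkov counts are Poisson with mean given by
#' [cherenkov_mean_yield()] at the vertex's electron energy, emitted within
#' `cherenkov_spread_ps` of the vertex time; scintillation counts are Poisson
#' with mean `scint_yield_per_keV * edep` restricted to the emission horizon,
#' with exponential decay times.  When `detect = TRUE` the Poisson means are
#' pre-thinned by `pde * detection_scale` (detection thinning commutes with
#' the Poisson draw), so only potentially detectable photons are generated.
#'
#' @param sites site table from [simulate_gamma_events()].
#' @param cfg an [optical_config()].
#' @param detect logical; thin by PDE at generation (detected stream) or keep
#'   every emitted photon (face-arrival stream).
#' @return data.frame of emitted photons: `event_id`, `crystal_id`, position,
#'   `t_emit_ps`, `type` ("cherenkov"/"scintillation").
#' @export
emit_photons <- function(sites, cfg = optical_config(), detect = TRUE) {
  scale <- if (detect) cfg$pde * cfg$detection_scale else 1
  lam_c <- cherenkov_mean_yield(pmin(sites$edep_keV, .const$mec2_keV), cfg) * scale
  decay_ps <- cfg$scint_decay_ns * 1000
  p_horizon <- 1 - exp(-cfg$scint_horizon_ps / decay_ps)
  lam_s <- cfg$scint_yield_per_keV * sites$edep_keV * p_horizon * scale
  n_c <- stats::rpois(nrow(sites), lam_c)
  n_s <- stats::rpois(nrow(sites), lam_s)

  idx <- c(rep(seq_len(nrow(sites)), n_c), rep(seq_len(nrow(sites)), n_s))
  type <- c(rep("cherenkov", sum(n_c)), rep("scintillation", sum(n_s)))
  if (length(idx) == 0) {
    return(data.frame(event_id = integer(0), crystal_id = integer(0),
                      x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      t_emit_ps = numeric(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  delay <- numeric(length(idx))
  is_c <- type == "cherenkov"
  delay[is_c] <- stats::runif(sum(is_c), 0, cfg$cherenkov_spread_ps)
  if (any(!is_c)) {
    u <- stats::runif(sum(!is_c), 0, p_horizon)  # truncated exponential
    delay[!is_c] <- cfg$scint_rise_ps - decay_ps * log(1 - u)
  }
  data.frame(event_id = sites$event_id[idx],
             crystal_id = sites$crystal_id[idx],
             x_mm = sites$x_mm[idx], y_mm = sites$y_mm[idx],
             z_mm = sites$z_mm[idx],
             t_emit_ps = sites$t_ps[idx] + delay,
             type = type, stringsAsFactors = FALSE)
}

#' Transport optical photons to the photodetector face
#'
#' Each photon is assigned an isotropic direction and propagated along
#' straight segments at the group speed `c / group_index`, with specular
#' reflections at the crystal faces (survival `esr_reflectivity` per
#' reflection) until it exits into the SiPM at `z = length_z`.  In a
#' rectangular specular box the path to the detector plane is computed in
#' closed form by unfolding the reflections; transverse reflections do not
#' change the path length, only the reflection count and the folded exit
#' position, which assigns the readout channel (A/B split at the transverse
#' midline in y).  Bulk absorption is Beer-Lambert over the full path.  When
#' `detect = TRUE` Gaussian SPTR jitter is added to the arrival time and
#' optional optical crosstalk reassigns photons to the neighbouring crystal.
#'
#' @param photons photon table from [emit_photons()].
#' @param geometry a [detector_geometry()].
#' @param cfg an [optical_config()].
#' @param detect logical; apply the detection model (SPTR, crosstalk) or
#'   report bare arrivals at the face.
#' @return data.frame: `event_id`, `crystal_id`, `channel` ("A"/"B"),
#'   `t_ps` (detection or arrival time since gamma entry), `type`,
#'   `path_mm`, `n_reflections`.
#' @export
transport_photons <- function(photons, geometry = detector_geometry(),
                              cfg = optical_config(), detect = TRUE) {
  n <- nrow(photons)
  empty <- data.frame(event_id = integer(0), crystal_id = integer(0),
                      channel = character(0), t_ps = numeric(0),
                      type = character(0), path_mm = numeric(0),
                      n_reflections = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  L <- geometry$length_z
  dz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sq <- sqrt(pmax(0, 1 - dz^2))
  dx <- sq * cos(phi); dy <- sq * sin(phi)
  down <- dz > 0
  s <- ifelse(down, (L - photons$z_mm) / dz, (L + photons$z_mm) / pmax(-dz, 1e-12))
  cap <- 20 * cfg$absorption_length_mm
  alive <- is.finite(s) & s <= cap
  # transverse unfolding within the photon's own crystal
  lo <- crystal_x_lo(geometry)[photons$crystal_id]
  wx <- geometry$pixel_pitch_x; wy <- geometry$pixel_pitch_y
  ux1 <- (photons$x_mm - lo) + dx * s
  uy1 <- photons$y_mm + dy * s
  ncx <- abs(floor(ux1 / wx))
  ncy <- abs(floor(uy1 / wy))
  nrefl <- ncx + ncy + as.integer(!down)
  surv <- cfg$esr_reflectivity^nrefl * exp(-s / cfg$absorption_length_mm)
  keep <- alive & stats::runif(n) < surv
  if (!any(keep)) return(empty)

  px <- ux1[keep] %% (2 * wx); py <- uy1[keep] %% (2 * wy)
  yf <- ifelse(py < wy, py, 2 * wy - py)
  v <- .const$c_mm_ps / cfg$group_index
  t_arr <- photons$t_emit_ps[keep] + s[keep] / v
  crystal <- photons$crystal_id[keep]
  if (detect) {
    if (cfg$sptr_sigma_ps > 0)
      t_arr <- t_arr + stats::rnorm(sum(keep), 0, cfg$sptr_sigma_ps)
    if (cfg$crosstalk_fraction > 0 && geometry$n_pixels_x > 1) {
      flip <- stats::runif(sum(keep)) < cfg$crosstalk_fraction
      neighbour <- ifelse(crystal < geometry$n_pixels_x, crystal + 1L, crystal - 1L)
      crystal[flip] <- neighbour[flip]
    }
  }
  data.frame(event_id = photons$event_id[keep],
             crystal_id = as.integer(crystal),
             channel = ifelse(yf < wy / 2, "A", "B"),
             t_ps = t_arr,
             type = photons$type[keep],
             path_mm = s[keep],
             n_reflections = as.integer(nrefl[keep]),
             stringsAsFactors = FALSE)
}

#' Assemble the detector readout for each event
#'
#' Converts ground-truth events plus detected photons into what the
#' "experiment" records: smeared per-crystal energies (Gaussian, relative
#' FWHM scaling as `1/sqrt(E)` from the 511 keV anchor), per-channel first
#' photon timestamps, per-crystal timestamps `T1`/`T2` (minimum over the
#' crystal's two channels, `NA` when no photon was detected) and a reference
#' detector timestamp drawn as Gaussian jitter around zero.
#'
#' @param events event summary from [simulate_gamma_events()].
#' @param detected detected photon table from [transport_photons()].
#' @param cfg an [optical_config()].
#' @param smear_energy logical; disable to read out true energies.
#' @return data.frame, one row per event: `event_id`, `E1_keV`, `E2_keV`,
#'   channel timestamps `T1A_ps` ... `T2B_ps`, `T1_ps`, `T2_ps`, `tref_ps`.
#' @export
build_readout <- function(events, detected, cfg = optical_config(),
                          smear_energy = TRUE) {
  n <- nrow(events)
  smear <- function(E) {
    if (!smear_energy) return(E)
    sig <- cfg$energy_res_fwhm_511 / 2.3548 * sqrt(.const$mec2_keV * E)
    pmax(0, E + stats::rnorm(length(E), 0, sig))
  }
  out <- data.frame(event_id = events$event_id,
                    E1_keV = smear(events$E1_true),
                    E2_keV = smear(events$E2_true))
  event_id <- crystal_id <- channel <- t_ps <- NULL
  dt <- data.table::as.data.table(detected)
  firsts <- if (nrow(dt) > 0)
    dt[, list(t1 = min(t_ps)), by = list(event_id, crystal_id, channel)]
  else data.table::data.table(event_id = integer(0), crystal_id = integer(0),
                              channel = character(0), t1 = numeric(0))
  for (cr in 1:2) for (ch in c("A", "B")) {
    cname <- sprintf("T%d%s_ps", cr, ch)
    m <- firsts[firsts$crystal_id == cr & firsts$channel == ch, ]
    v <- rep(NA_real_, n)
    v[match(m$event_id, events$event_id)] <- m$t1
    out[[cname]] <- v
  }
  out$T1_ps <- pmin(out$T1A_ps, out$T1B_ps, na.rm = TRUE)
  out$T2_ps <- pmin(out$T2A_ps, out$T2B_ps, na.rm = TRUE)
  out$T1_ps[is.na(out$T1A_ps) & is.na(out$T1B_ps)] <- NA_real_
  out$T2_ps[is.na(out$T2A_ps) & is.na(out$T2B_ps)] <- NA_real_
  out$tref_ps <- stats::rnorm(n, 0, cfg$ref_fwhm_ps / 2.3548)
  out
}

#' Full-chain detector simulation
#'
#' Convenience wrapper: gamma transport, truth labelling, optical photon
#' generation and transport, and readout assembly for `n_events` histories.
#'
#' @param n_events number of gamma histories.
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to the config's seed.
#' @param mode `"detected"` for the full detection model, `"face"` for bare
#'   photon arrivals at the detector face (no PDE, no SPTR).
#' @param smear_energy logical, passed to [build_readout()].
#' @return an object of class `bgo_sim`: list with `sites`, `events` (with
#'   truth labels merged), `photons`, `readout`, and the `config`.
#' @export
simulate_detector <- function(n_events, config = sim_config(),
                              seed = config$seed, mode = c("detected", "face"),
                              smear_energy = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_gamma_events(n_events, config$geometry, config$material,
                             config$source, seed = NULL)
  lab <- truth_label(g, config$partition$photopeak_window)
  ev <- merge(g$events, lab, by = "event_id")
  ev <- ev[order(ev$event_id), ]
  detect <- mode == "detected"
  ph <- emit_photons(g$sites, config$optics, detect = detect)
  det <- transport_photons(ph, config$geometry, config$optics, detect = detect)
  ro <- build_readout(ev, det, config$optics, smear_energy = smear_energy)
  structure(list(sites = g$sites, events = ev, photons = det, readout = ro,
                 config = config, mode = mode),
            class = "bgo_sim")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> n_cherenkov %.2f (threshold %.1f keV), group index %.2f, %g Cherenkov ph @511 keV, pde*scale %.3f\n",
              x$n_cherenkov, cherenkov_threshold(x$n_cherenkov),
              x$group_index, x$cherenkov_yield_511, x$pde * x$detection_scale))
  invisible(x)
}

#' @export
print.bgo_sim <- function(x, ...) {
  cat(sprintf("<bgo_sim> %d events (%s mode), %d detected photons\n",
              nrow(x$events), x$mode, nrow(x$photons)))
  invisible(x)
}
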
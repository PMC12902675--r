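#' FWHM and FWTM of a sample by histogram interpolation
#'
#' Bins the sample at fixed width, takes the highest bin as the peak, and
#' finds the half- and tenth-maximum crossings on each side of the peak by
#' linear interpolation between bin centres.  Interpolation (rather than a
#' Gaussian fit) is used because coincidence timing distributions here are
#' heavy-tailed.  The histogram is padded with an empty bin on each side so
#' the crossings always exist.
#'
#' @param x numeric sample (at least 100 values).
#' @param bin_width histogram bin width in the sample's units (default 10 ps).
#' @return object of class `resolution_result`: list with `fwhm`, `fwtm`,
#'   `peak` (mode position), `n`, `bin_width`.
#' @export
fwhm_fwtm <- function(x, bin_width = 10) {
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("fwhm_fwtm: need at least 100 samples")
  lo <- floor(min(x) / bin_width) * bin_width
  breaks <- seq(lo, max(x) + bin_width, by = bin_width)
  cnt <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  cnt <- c(0, cnt, 0)
  centers <- seq(lo - bin_width / 2, by = bin_width, length.out = length(cnt))
  pk <- which.max(cnt)
  if (max(cnt) == min(cnt)) stop("fwhm_fwtm: flat histogram, ambiguous peak")
  width_at <- function(frac) {
    level <- frac * cnt[pk]
    i <- pk
    while (i > 1 && cnt[i - 1] >= level) i <- i - 1
    xl <- if (cnt[i] == cnt[i - 1]) centers[i - 1] else
      centers[i - 1] + (level - cnt[i - 1]) / (cnt[i] - cnt[i - 1]) * bin_width
    j <- pk
    while (j < length(cnt) && cnt[j + 1] >= level) j <- j + 1
    xr <- if (cnt[j] == cnt[j + 1]) centers[j + 1] else
      centers[j] + (cnt[j] - level) / (cnt[j] - cnt[j + 1]) * bin_width
    xr - xl
  }
  structure(list(fwhm = width_at(0.5), fwtm = width_at(0.1),
                 peak = centers[pk], n = length(x), bin_width = bin_width),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("FWHM %.1f / FWTM %.1f (peak %.1f, n = %d, bin %g)\n",
              x$fwhm, x$fwtm, x$peak, x$n, x$bin_width))
  invisible(x)
}

#' Coincidence time differences against the reference detector
#'
#' `delta = T_selected - t_ref` per event, for the chosen timestamp strategy.
#' Events without the needed timestamps are skipped; their number is attached
#' as attribute `n_skipped`.
#'
#' @param classified output of [classify_events()].
#' @param strategy `"min"`, `"adaptive"`, or `"energy"`.
#' @param k margin (ps) when `strategy = "adaptive"`.
#' @return numeric vector of time differences, ps.
#' @export
coincidence_deltas <- function(classified, strategy = c("min", "adaptive", "energy"),
                               k = 0) {
  strategy <- match.arg(strategy)
  has <- !(is.na(classified$T1_ps) & is.na(classified$T2_ps))
  d <- classified[has, ]
  sel <- switch(strategy,
    min = select_timestamp_min(d$T1_ps, d$T2_ps),
    adaptive = select_timestamp_adaptive(d$T1_ps, d$T2_ps, k),
    energy = select_timestamp_energy(d$T1_ps, d$T2_ps, d$E1_keV, d$E2_keV))
  out <- sel - d$tref_ps
  attr(out, "n_skipped") <- sum(!has)
  out
}

#' Sweep the adaptive margin parameter
#'
#' CTR FWHM/FWTM of the adaptive timestamp strategy as a function of the
#' margin `k`, over the supplied (typically InterCS) events.
#'
#' @param classified output of [classify_events()], usually filtered to
#'   InterCS events.
#' @param k_grid margins to evaluate, ps; should cover 0.
#' @param bin_width histogram bin width for the width estimator, ps.
#' @return data.frame with `k_ps`, `fwhm_ps`, `fwtm_ps`, `n`.
#' @export
sweep_k <- function(classified, k_grid = seq(-1000, 1000, by = 50),
                    bin_width = 10) {
  if (nrow(classified) == 0) stop("sweep_k: empty event set")
  res <- lapply(k_grid, function(k) {
    d <- coincidence_deltas(classified, "adaptive", k)
    w <- fwhm_fwtm(d, bin_width)
    data.frame(k_ps = k, fwhm_ps = w$fwhm, fwtm_ps = w$fwtm, n = length(d))
  })
  do.call(rbind, res)
}

#' Timing and prompt statistics binned by energy asymmetry
#'
#' Bins (typically InterCS) events by the continuous energy asymmetry `A` and
#' reports per bin the CTR FWHM of the earliest-timestamp strategy, the mean
#' prompt count from the earlier-timestamp crystal, and the fraction of
#' events where crystal 1 produced the earlier timestamp.  Bins with fewer
#' than `min_n` events are flagged (`reported = FALSE`) and their statistics
#' set to `NA`.
#'
#' @param classified output of [classify_events()], usually InterCS only.
#' @param breaks bin edges on `A` in \[0, 1\].
#' @param min_n minimum events for a bin to be reported.
#' @param bin_width histogram bin width for the CTR estimate, ps.
#' @return data.frame with one row per bin.
#' @export
asymmetry_binned_analysis <- function(classified, breaks = seq(0, 1, by = 0.2),
                                      min_n = 100, bin_width = 10) {
  b <- cut(classified$A, breaks, include.lowest = TRUE)
  out <- lapply(levels(b), function(lv) {
    d <- classified[!is.na(b) & b == lv, ]
    n <- nrow(d)
    if (n < min_n)
      return(data.frame(bin = lv, n = n, ctr_fwhm_ps = NA_real_,
                        mean_prompt = NA_real_, frac_t1_earlier = NA_real_,
                        reported = FALSE))
    dd <- coincidence_deltas(d, "min")
    fw <- if (length(dd) >= 100 && stats::sd(dd) > 0)
      fwhm_fwtm(dd, bin_width)$fwhm else NA_real_
    both <- !is.na(d$T1_ps) & !is.na(d$T2_ps)
    data.frame(bin = lv, n = n, ctr_fwhm_ps = fw,
               mean_prompt = mean(d$n_prompt, na.rm = TRUE),
               frac_t1_earlier = mean(d$T1_ps[both] < d$T2_ps[both]),
               reported = TRUE)
  })
  out <- do.call(rbind, out)
  out$a_mid <- (breaks[-length(breaks)] + breaks[-1]) / 2
  out
}

#' Forward/backward scatter fractions
#'
#' @param classified InterCS events from [classify_events()].
#' @return named numeric vector `c(FWD = ..., BWD = ...)`, summing to 1.
#' @export
fwd_bwd_fractions <- function(classified) {
  if (nrow(classified) == 0) stop("fwd_bwd_fractions: no events")
  dir <- scatter_direction(classified$E1_keV, classified$E2_keV)
  c(FWD = mean(dir == "FWD"), BWD = mean(dir == "BWD"))
}

#' Quadrant fractions of energy dominance versus timestamp order
#'
#' Fractions of events in the four quadrants of (`E1 > E2`) x (`T1 < T2`),
#' over events where both timestamps are present.  The discordant fraction
#' (higher-energy crystal not the earlier one) measures the decoupling of
#' energy dominance from signal arrival order.
#'
#' @param classified InterCS events from [classify_events()].
#' @return list with the 2x2 `fractions` table (rows: E1>E2 TRUE/FALSE;
#'   columns: T1<T2 TRUE/FALSE), `discordant`, and `n`.
#' @export
quadrant_fractions <- function(classified) {
  d <- classified[!is.na(classified$T1_ps) & !is.na(classified$T2_ps), ]
  if (nrow(d) == 0) stop("quadrant_fractions: no events with both timestamps")
  e1_dom <- factor(d$E1_keV > d$E2_keV, levels = c(TRUE, FALSE))
  t1_first <- factor(d$T1_ps < d$T2_ps, levels = c(TRUE, FALSE))
  tab <- table(e1_dom, t1_first) / nrow(d)
  disc <- tab["TRUE", "FALSE"] + tab["FALSE", "TRUE"]
  list(fractions = tab, discordant = as.numeric(disc), n = nrow(d))
}

#' Travel-time order statistics per truth class
#'
#' Mean and standard deviation of the n-th earliest photon time per event
#' (time measured from the gamma's entry into the crystal), grouped by truth
#' class.  Operates on a photon stream: either bare face arrivals
#' (`mode = "face"` simulation, closest to a pure transport definition) or
#' the detected stream.  Events with fewer than `order_n` photons are skipped
#' and counted.
#'
#' @param photons detected/arrival photon table of a `bgo_sim`.
#' @param events event table with `truth_class` (e.g. `sim$events`).
#' @param order_n which order statistic (1 = first photon).
#' @return data.frame per class: `truth_class`, `n_events`, `mean_ps`,
#'   `sd_ps`; attribute `n_skipped` counts events with too few photons.
#' @export
travel_time_stats <- function(photons, events, order_n = 1) {
  event_id <- t_ps <- NULL
  dt <- data.table::as.data.table(photons)
  per <- dt[, list(tn = if (.N >= order_n) sort(t_ps, partial = order_n)[order_n]
                   else NA_real_), by = event_id]
  per$truth_class <- events$truth_class[match(per$event_id, events$event_id)]
  skipped <- sum(is.na(per$tn)) +
    sum(!(events$event_id %in% per$event_id))
  per <- per[!is.na(per$tn) & !is.na(per$truth_class), ]
  tn <- truth_class <- NULL
  out <- per[, list(n_events = .N, mean_ps = mean(tn), sd_ps = stats::sd(tn)),
             by = truth_class]
  out <- data.table::setDF(out)
  attr(out, "n_skipped") <- skipped
  out
}

#' Intra-crystal scatter prevalence versus crystal pitch
#'
#' For each transverse pitch, runs a single-crystal gamma Monte Carlo
#' (square pitch x pitch cross-section, fixed length) with a collimated beam
#' on the crystal centre and reports the fraction of photopeak-window events
#' with two or more deposition vertices, i.e. the IntraCS fraction.
#'
#' @param pitches transverse pitches to simulate, mm.
#' @param n_events histories per pitch.
#' @param length_z crystal length, mm.
#' @param material a [material_model()].
#' @param beam_width collimator aperture, mm (capped at the pitch).
#' @param photopeak_window accepted total deposit range, keV.
#' @param seed integer seed.
#' @return data.frame: `pitch_mm`, `frac_intracs`, `n_photopeak`.
#' @export
aspect_ratio_study <- function(pitches = c(1, 2, 3, 5, 10, 15),
                               n_events = 20000, length_z = 15,
                               material = bgo_material(), beam_width = 0.5,
                               photopeak_window = c(425, 600), seed = NULL) {
  if (any(pitches <= 0)) stop("aspect_ratio_study: pitches must be positive")
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(pitches, function(p) {
    geom <- detector_geometry(pixel_pitch_x = p, pixel_pitch_y = p,
                              length_z = length_z, n_pixels_x = 1,
                              reflector_gap = 0)
    src <- beam_source(beam_width = min(beam_width, p / 2), crystal = 1)
    g <- simulate_gamma_events(n_events, geom, material, src, seed = NULL)
    lab <- truth_label(g, photopeak_window)
    keep <- lab$truth_class != "rejected"
    data.frame(pitch_mm = p,
               frac_intracs = mean(g$events$n_sites[keep] >= 2),
               n_photopeak = sum(keep))
  })
  do.call(rbind, res)
}

#' IntraCS contamination of FED-classified events
#'
#' Runs the dual-pixel gamma Monte Carlo, applies the measured-energy model
#' (Gaussian smearing) and the energy-weighted-position classification, and
#' returns the fraction of FED-classified events whose ground truth contains
#' two or more deposition vertices in the irradiated crystal.
#'
#' @param n_events number of gamma histories.
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to the config seed.
#' @param smear_energy logical; apply the energy resolution model.
#' @return list: `contamination` (fraction), `n_fed`, `n_photopeak`.
#' @export
intracs_contamination <- function(n_events, config = sim_config(),
                                  seed = config$seed, smear_energy = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_gamma_events(n_events, config$geometry, config$material,
                             config$source, seed = NULL)
  ev <- g$events
  if (smear_energy) {
    sig <- function(E) config$optics$energy_res_fwhm_511 / 2.3548 *
      sqrt(.const$mec2_keV * E)
    E1 <- pmax(0, ev$E1_true + stats::rnorm(nrow(ev), 0, sig(ev$E1_true)))
    E2 <- pmax(0, ev$E2_true + stats::rnorm(nrow(ev), 0, sig(ev$E2_true)))
  } else {
    E1 <- ev$E1_true; E2 <- ev$E2_true
  }
  cls <- classify_event(E1, E2, config$partition)
  fed <- cls == "FED"
  list(contamination = mean(ev$n_sites_irr[fed] >= 2),
       n_fed = sum(fed), n_photopeak = sum(cls != "rejected"))
}

#' Calibrate the detection-efficiency knob to a prompt-count target
#'
#' Adjusts `detection_scale` of the optical model by fixed-point iteration
#' (common random numbers across iterations) until FED-classified events
#' average `target` prompt photons in the integration window.
#'
#' @param config a [sim_config()].
#' @param target target mean FED prompt count.
#' @param n_events histories per iteration.
#' @param seed integer seed reused across iterations.
#' @param max_iter,tol iteration cap and relative tolerance.
#' @return the config with calibrated `optics$detection_scale`; attributes
#'   `achieved` (mean FED prompt at the final scale) and `iterations`.
#' @export
calibrate_detection_scale <- function(config = sim_config(), target = 5.76,
                                      n_events = 20000, seed = config$seed,
                                      max_iter = 8, tol = 0.01) {
  s <- config$optics$detection_scale
  achieved <- NA_real_
  for (it in seq_len(max_iter)) {
    cfg <- config
    cfg$optics$detection_scale <- s
    sim <- simulate_detector(n_events, cfg, seed = seed)
    cl <- classify_events(sim)
    m <- mean(cl$n_prompt[cl$assigned_class == "FED"], na.rm = TRUE)
    achieved <- m
    if (abs(m - target) <= tol * target) break
    s <- s * target / m
  }
  config$optics$detection_scale <- s
  attr(config, "achieved") <- achieved
  attr(config, "iterations") <- it
  config
}
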
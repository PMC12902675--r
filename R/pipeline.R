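#' Classification partition
#'
#' Thresholds on the energy-weighted position `P` and the photopeak window on
#' the summed energy that partition readouts into FED / InterCS / Pene /
#' rejected.
#'
#' @param fed_upper events with `P <= fed_upper` are FED.
#' @param pene_lower events with `P >= pene_lower` are Pene.
#' @param photopeak_window accepted range of `E1 + E2`, keV.
#' @return object of class `class_partition`.
#' @export
class_partition <- function(fed_upper = -0.8, pene_lower = 0.8,
                            photopeak_window = c(425, 600)) {
  if (!(fed_upper >= -1 && fed_upper < pene_lower && pene_lower <= 1))
    stop("class_partition: need -1 <= fed_upper < pene_lower <= 1")
  if (length(photopeak_window) != 2 || photopeak_window[1] >= photopeak_window[2])
    stop("class_partition: photopeak_window must be an increasing (lo, hi) pair")
  structure(list(fed_upper = as.numeric(fed_upper),
                 pene_lower = as.numeric(pene_lower),
                 photopeak_window = as.numeric(photopeak_window)),
            class = "class_partition")
}

#' Energy-weighted interaction position
#'
#' Normalised energy difference `P = (E2 - E1) / (E2 + E1)` between the two
#' crystals, the one-dimensional Anger-logic position used for event
#' classification.  Antisymmetric under swapping the crystals; -1 when all
#' energy is in crystal 1, +1 when all is in crystal 2.
#'
#' @param E1,E2 per-crystal energies, keV (vectorised); `E1 + E2` must be
#'   positive.
#' @return positions in \[-1, 1\].
#' @export
energy_weighted_position <- function(E1, E2) {
  if (any(E1 + E2 <= 0))
    stop("energy_weighted_position: undefined for E1 + E2 <= 0")
  (E2 - E1) / (E2 + E1)
}

#' Continuous energy asymmetry
#'
#' `A = |E1 - E2| / (E1 + E2)`, i.e. the magnitude of the energy-weighted
#' position: 0 for an even split, 1 when one crystal takes everything.
#'
#' @inheritParams energy_weighted_position
#' @return asymmetries in \[0, 1\].
#' @export
energy_asymmetry <- function(E1, E2) abs(energy_weighted_position(E1, E2))

#' Scatter direction of an inter-crystal scatter event
#'
#' Forward (FWD) when the irradiated crystal received no more energy than its
#' neighbour (`E1 <= E2`), backward (BWD) otherwise.
#'
#' @inheritParams energy_weighted_position
#' @return character vector, "FWD" or "BWD".
#' @export
scatter_direction <- function(E1, E2) ifelse(E1 <= E2, "FWD", "BWD")

#' Classify readouts by energy-weighted position
#'
#' `rejected` when the summed energy falls outside the photopeak window (or
#' is zero); otherwise FED, Pene, or InterCS according to where the
#' energy-weighted position falls relative to the partition thresholds.
#'
#' @param E1,E2 per-crystal measured energies, keV (vectorised).
#' @param partition a [class_partition()].
#' @return character vector in {"FED", "InterCS", "Pene", "rejected"}.
#' @export
classify_event <- function(E1, E2, partition = class_partition()) {
  tot <- E1 + E2
  ok <- tot >= partition$photopeak_window[1] & tot <= partition$photopeak_window[2]
  P <- rep(NA_real_, length(tot))
  pos <- tot > 0
  P[pos] <- energy_weighted_position(E1[pos], E2[pos])
  out <- rep("rejected", length(tot))
  out[ok & P <= partition$fed_upper] <- "FED"
  out[ok & P >= partition$pene_lower] <- "Pene"
  out[ok & P > partition$fed_upper & P < partition$pene_lower] <- "InterCS"
  out
}

#' Earliest-timestamp selection
#'
#' Returns the earlier of the two crystal timestamps; a single present
#' timestamp is returned as-is.  Equivalent to the adaptive rule with margin
#' `k = 0`.  Ties return `T1`.
#'
#' @param T1,T2 crystal timestamps, ps; `NA` marks an absent timestamp.
#' @return selected timestamps.
#' @export
select_timestamp_min <- function(T1, T2) {
  if (any(is.na(T1) & is.na(T2)))
    stop("select_timestamp_min: event with no timestamp in either crystal")
  out <- pmin(T1, T2, na.rm = TRUE)
  out
}

#' Adaptive margin timestamp selection
#'
#' Selects `T1` if `T1 < T2 + k`, otherwise `T2`.  The margin `k` (ps, may be
#' negative) biases the choice toward crystal 1 as `k` grows.  Falls back to
#' the present timestamp when the other is absent.
#'
#' @param T1,T2 crystal timestamps, ps.
#' @param k margin, ps.
#' @return selected timestamps.
#' @export
select_timestamp_adaptive <- function(T1, T2, k = 0) {
  if (any(is.na(T1) & is.na(T2)))
    stop("select_timestamp_adaptive: event with no timestamp in either crystal")
  out <- ifelse(T1 < T2 + k, T1, T2)
  out[is.na(T2)] <- T1[is.na(T2)]
  out[is.na(T1)] <- T2[is.na(T1)]
  out
}

#' Energy-based timestamp selection
#'
#' Takes the timestamp of the crystal with the larger energy deposit:
#' `T1` when `E1 > E2` (BWD scattering), `T2` when `E1 <= E2` (FWD,
#' including the tie).  Falls back to the present timestamp when the other is
#' absent.
#'
#' @param T1,T2 crystal timestamps, ps.
#' @param E1,E2 per-crystal energies, keV.
#' @return selected timestamps.
#' @export
select_timestamp_energy <- function(T1, T2, E1, E2) {
  if (any(is.na(T1) & is.na(T2)))
    stop("select_timestamp_energy: event with no timestamp in either crystal")
  out <- ifelse(E1 > E2, T1, T2)
  out[is.na(T2)] <- T1[is.na(T2)]
  out[is.na(T1)] <- T2[is.na(T1)]
  out
}

#' Prompt photon count of one crystal
#'
#' Photon-counting analogue of integrating the first nanosecond of each SiPM
#' channel's waveform: each channel counts its photons within `window` of its
#' own first photon; if the two channels' first photons differ by more than
#' `tolerance`, the later channel is considered uncorrelated and its count is
#' zeroed; the two channel counts are then summed.
#'
#' @param tA,tB sorted (or unsorted) photon detection times of channels A and
#'   B, ps; an empty vector marks a silent channel.
#' @param window integration window, ps.
#' @param tolerance inter-channel coincidence tolerance, ps.
#' @return integer prompt count for the crystal.
#' @export
prompt_photon_count <- function(tA, tB, window = 1000, tolerance = 300) {
  nA <- if (length(tA)) sum(tA <= min(tA) + window) else 0L
  nB <- if (length(tB)) sum(tB <= min(tB) + window) else 0L
  if (length(tA) && length(tB)) {
    d <- min(tA) - min(tB)
    if (abs(d) > tolerance) {
      if (d > 0) nA <- 0L else nB <- 0L
    }
  }
  as.integer(nA + nB)
}

#' Prompt count of an inter-crystal scatter event
#'
#' The prompt photon count of the crystal that produced the earlier
#' timestamp (an absent timestamp loses); ties go to crystal 1.
#'
#' @param T1,T2 crystal timestamps, ps (`NA` = absent).
#' @param N1,N2 per-crystal prompt counts.
#' @return selected prompt counts.
#' @export
intercs_prompt_count <- function(T1, T2, N1, N2) {
  if (any(is.na(T1) & is.na(T2)))
    stop("intercs_prompt_count: event with no timestamp in either crystal")
  out <- ifelse(T1 <= T2, N1, N2)
  out[is.na(T1)] <- N2[is.na(T1)]
  out[is.na(T2)] <- N1[is.na(T2)]
  out
}

# Vectorised per-crystal prompt counts from the detected photon table.
crystal_prompt_counts <- function(detected, window = 1000, tolerance = 300) {
  event_id <- crystal_id <- channel <- t_ps <- t1 <- nwin <- NULL
  dt <- data.table::as.data.table(detected)
  if (nrow(dt) == 0)
    return(data.table::data.table(event_id = integer(0), crystal_id = integer(0),
                                  N = integer(0)))
  ch <- dt[, list(t1 = min(t_ps), nwin = sum(t_ps <= min(t_ps) + window)),
           by = list(event_id, crystal_id, channel)]
  per <- ch[, {
    if (.N == 2L) {
      d <- t1[1] - t1[2]
      n <- nwin
      if (abs(d) > tolerance) n[if (d > 0) 1L else 2L] <- 0L
      list(N = sum(n))
    } else list(N = sum(nwin))
  }, by = list(event_id, crystal_id)]
  per
}

#' Run the event-processing pipeline on a simulation
#'
#' Applies energy-weighted classification, the three timestamp-selection
#' strategies, scatter direction, energy asymmetry, and prompt-photon
#' quantification to the readout of a [simulate_detector()] result.
#'
#' @param sim a `bgo_sim` object (detected mode).
#' @param partition a [class_partition()]; defaults to the one in the
#'   simulation's config.
#' @param k adaptive margin used for the `t_adap_ps` column, ps.
#' @param window,tolerance prompt-count parameters, ps.
#' @return data.frame, one row per event, with measured energies, truth
#'   labels, position `P`, `assigned_class`, `direction`, asymmetry `A`,
#'   prompt counts `N1`/`N2`, the selected timestamps `t_min_ps`,
#'   `t_adap_ps`, `t_energy_ps`, the per-event prompt count `n_prompt`
#'   (crystal 1 for FED, crystal 2 for Pene, earlier-timestamp crystal for
#'   InterCS) and `tref_ps`.
#' @export
classify_events <- function(sim, partition = NULL, k = 0,
                            window = 1000, tolerance = 300) {
  stopifnot(inherits(sim, "bgo_sim"))
  if (is.null(partition)) partition <- sim$config$partition
  ro <- sim$readout
  out <- data.frame(event_id = ro$event_id,
                    E1_keV = ro$E1_keV, E2_keV = ro$E2_keV,
                    T1_ps = ro$T1_ps, T2_ps = ro$T2_ps,
                    tref_ps = ro$tref_ps)
  out$truth_class <- sim$events$truth_class[match(out$event_id, sim$events$event_id)]
  out$pene <- sim$events$pene[match(out$event_id, sim$events$event_id)]
  out$multi_irr <- sim$events$n_sites_irr[match(out$event_id, sim$events$event_id)] >= 2
  tot <- out$E1_keV + out$E2_keV
  out$P <- ifelse(tot > 0, (out$E2_keV - out$E1_keV) / tot, NA_real_)
  out$assigned_class <- classify_event(out$E1_keV, out$E2_keV, partition)
  out$A <- abs(out$P)
  out$direction <- ifelse(out$assigned_class == "InterCS",
                          scatter_direction(out$E1_keV, out$E2_keV), NA_character_)

  pc <- crystal_prompt_counts(sim$photons, window, tolerance)
  pc1 <- pc[pc$crystal_id == 1L, ]
  pc2 <- pc[pc$crystal_id == 2L, ]
  out$N1 <- pc1$N[match(out$event_id, pc1$event_id)]
  out$N2 <- pc2$N[match(out$event_id, pc2$event_id)]
  out$N1[is.na(out$N1)] <- 0L
  out$N2[is.na(out$N2)] <- 0L

  has_t <- !(is.na(out$T1_ps) & is.na(out$T2_ps))
  out$t_min_ps <- out$t_adap_ps <- out$t_energy_ps <- rep(NA_real_, nrow(out))
  if (any(has_t)) {
    out$t_min_ps[has_t] <- select_timestamp_min(out$T1_ps[has_t], out$T2_ps[has_t])
    out$t_adap_ps[has_t] <- select_timestamp_adaptive(out$T1_ps[has_t],
                                                      out$T2_ps[has_t], k)
    out$t_energy_ps[has_t] <- select_timestamp_energy(out$T1_ps[has_t],
                                                      out$T2_ps[has_t],
                                                      out$E1_keV[has_t],
                                                      out$E2_keV[has_t])
  }
  out$n_prompt <- rep(NA_integer_, nrow(out))
  fed <- out$assigned_class == "FED"
  pen <- out$assigned_class == "Pene"
  ics <- out$assigned_class == "InterCS" & has_t
  out$n_prompt[fed] <- out$N1[fed]
  out$n_prompt[pen] <- out$N2[pen]
  if (any(ics))
    out$n_prompt[ics] <- intercs_prompt_count(out$T1_ps[ics], out$T2_ps[ics],
                                              out$N1[ics], out$N2[ics])
  attr(out, "partition") <- partition
  attr(out, "k") <- k
  out
}

#' Fit classification thresholds from the position histogram
#'
#' Locates the valleys of the energy-weighted-position distribution between
#' the FED cluster (near -1) and the central InterCS cluster, and between the
#' centre and the Pene cluster (near +1), by finding the minimum of a kernel
#' density estimate in each search interval.
#'
#' @param P energy-weighted positions of photopeak events.
#' @param search half-open search intervals, as `c(inner_lo, inner_hi)`:
#'   valleys are sought on (-1, inner_lo) and (inner_hi, 1).
#' @return a [class_partition()] with fitted thresholds.
#' @export
fit_class_partition <- function(P, search = c(-0.2, 0.2)) {
  P <- P[is.finite(P)]
  if (length(P) < 100) stop("fit_class_partition: need at least 100 positions")
  d <- stats::density(P, from = -1, to = 1, n = 512, bw = 0.02)
  left <- d$x < search[1] & d$x > -0.99
  right <- d$x > search[2] & d$x < 0.99
  fed_upper <- d$x[left][which.min(d$y[left])]
  pene_lower <- d$x[right][which.min(d$y[right])]
  class_partition(fed_upper = fed_upper, pene_lower = pene_lower)
}
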
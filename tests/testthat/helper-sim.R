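# Shared fixtures: small, fast configurations built in code.

fast_config <- function(...) {
  cfg <- sim_config(...)
  cfg
}

# A minimal gamma_events object built by hand, for label/bookkeeping tests.
make_gamma_events <- function(sites, n_events, escaped = NULL,
                              geometry = detector_geometry(),
                              source = beam_source()) {
  if (is.null(escaped))
    escaped <- vapply(seq_len(n_events), function(i)
      511 - sum(sites$edep_keV[sites$event_id == i]), numeric(1))
  ev <- data.frame(event_id = seq_len(n_events))
  ev$edep_total <- vapply(ev$event_id, function(i)
    sum(sites$edep_keV[sites$event_id == i]), numeric(1))
  ev$E1_true <- vapply(ev$event_id, function(i)
    sum(sites$edep_keV[sites$event_id == i & sites$crystal_id == source$crystal]),
    numeric(1))
  ev$E2_true <- ev$edep_total - ev$E1_true
  ev$n_sites <- vapply(ev$event_id, function(i)
    sum(sites$event_id == i), integer(1))
  ev$n_sites_irr <- vapply(ev$event_id, function(i)
    sum(sites$event_id == i & sites$crystal_id == source$crystal), integer(1))
  ev$n_crystals <- vapply(ev$event_id, function(i)
    length(unique(sites$crystal_id[sites$event_id == i])), integer(1))
  ev$escaped_keV <- escaped
  structure(list(sites = sites, events = ev, geometry = geometry,
                 material = bgo_material(), source = source),
            class = "gamma_events")
}

make_sites <- function(event_id, crystal_id, edep_keV,
                       z_mm = seq_along(event_id), t_ps = seq_along(event_id)) {
  data.frame(event_id = event_id, site_index = seq_along(event_id),
             crystal_id = crystal_id, x_mm = 1.25, y_mm = 1.4, z_mm = z_mm,
             edep_keV = edep_keV, t_ps = t_ps, kind = "photoelectric",
             stringsAsFactors = FALSE)
}
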
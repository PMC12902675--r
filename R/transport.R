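#' Monte Carlo gamma transport through the pixelated module
#'
#' Tracks collimated annihilation photons through the crystal geometry by
#' alternating exponential free-path sampling with photoelectric or Compton
#' interactions (Klein-Nishina angular sampling) until absorption, escape from
#' the module, or fall below the tracking cutoff (the residual photon is then
#' absorbed locally).  Electron transport is not modelled: every energy
#' deposit is local to its interaction vertex, which is a good approximation
#' at pixel-pitch scales.  Gamma flight time accrues at the vacuum speed of
#' light; reflector gaps are inert (no deposits).
#'
#' @param n_events number of gamma histories.
#' @param geometry a [detector_geometry()].
#' @param material a [material_model()].
#' @param source a [beam_source()].
#' @param seed optional integer seed (set once before sampling).
#' @param max_iter safety cap on transport iterations.
#' @return an object of class `gamma_events`: a list with
#'   \describe{
#'     \item{sites}{data.frame of interaction vertices: `event_id`,
#'       `site_index`, `crystal_id`, `x_mm`, `y_mm`, `z_mm`, `edep_keV`,
#'       `t_ps`, `kind` ("photoelectric" or "compton").}
#'     \item{events}{per-event summary: entry point, per-crystal true energies
#'       `E1_true`/`E2_true` (irradiated crystal vs all others), total
#'       deposit, escaped energy, vertex counts.}
#'     \item{geometry, material, source}{the configuration used.}
#'   }
#' @export
simulate_gamma_events <- function(n_events,
                                  geometry = detector_geometry(),
                                  material = bgo_material(),
                                  source = beam_source(),
                                  seed = NULL, max_iter = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  n_events <- as.integer(n_events)
  stopifnot(n_events >= 0)

  escaped <- numeric(n_events)
  chunks <- list()
  if (n_events > 0) {
    entry <- source_entry_points(source, geometry, n_events)
    st <- list(id = seq_len(n_events),
               E = rep(source$energy, n_events),
               x = entry[, 1], y = entry[, 2], z = rep(0, n_events),
               dx = rep(0, n_events), dy = rep(0, n_events),
               dz = rep(1, n_events),
               t = rep(0, n_events))
    iter <- 0L
    while (length(st$id) > 0) {
      iter <- iter + 1L
      if (iter > max_iter) {
        warning("simulate_gamma_events: max_iter reached; remaining photons treated as escaped")
        escaped[st$id] <- escaped[st$id] + st$E
        break
      }
      att <- attenuation(st$E, material)
      step <- sample_free_path(att$mu_total, length(st$id))
      x <- st$x + step * st$dx
      y <- st$y + step * st$dy
      z <- st$z + step * st$dz
      t <- st$t + step / .const$c_mm_ps
      loc <- crystal_at(geometry, x, y, z)

      esc <- loc == -1L
      escaped[st$id[esc]] <- escaped[st$id[esc]] + st$E[esc]

      act <- !esc
      inter <- act & loc >= 1L   # in a crystal: interact
      # in-gap photons (loc == 0) simply continue from the sampled point

      pe <- inter & (stats::runif(length(st$id)) < att$f_pe)
      co <- inter & !pe

      dep_id <- integer(0); dep_cr <- integer(0)
      dep_x <- dep_y <- dep_z <- dep_e <- dep_t <- numeric(0)
      dep_kind <- character(0)
      if (any(pe)) {
        dep_id <- c(dep_id, st$id[pe]); dep_cr <- c(dep_cr, loc[pe])
        dep_x <- c(dep_x, x[pe]); dep_y <- c(dep_y, y[pe])
        dep_z <- c(dep_z, z[pe]); dep_e <- c(dep_e, st$E[pe])
        dep_t <- c(dep_t, t[pe])
        dep_kind <- c(dep_kind, rep("photoelectric", sum(pe)))
      }
      if (any(co)) {
        theta <- sample_klein_nishina_angle(st$E[co])
        kin <- compton_kinematics(st$E[co], theta)
        below <- kin$scattered < material$energy_cutoff
        # sub-cutoff scattered photons are absorbed at the vertex
        edep <- ifelse(below, st$E[co], kin$electron)
        keep_e <- edep > 0
        dep_id <- c(dep_id, st$id[co][keep_e]); dep_cr <- c(dep_cr, loc[co][keep_e])
        dep_x <- c(dep_x, x[co][keep_e]); dep_y <- c(dep_y, y[co][keep_e])
        dep_z <- c(dep_z, z[co][keep_e]); dep_e <- c(dep_e, edep[keep_e])
        dep_t <- c(dep_t, t[co][keep_e])
        dep_kind <- c(dep_kind, rep("compton", sum(keep_e)))
      }
      if (length(dep_id) > 0) {
        chunks[[length(chunks) + 1L]] <- data.frame(
          event_id = dep_id, crystal_id = dep_cr,
          x_mm = dep_x, y_mm = dep_y, z_mm = dep_z,
          edep_keV = dep_e, t_ps = dep_t, kind = dep_kind,
          stringsAsFactors = FALSE)
      }

      # survivors: in-gap photons and Compton-scattered photons above cutoff
      surv <- act & !pe
      if (any(co)) {
        co_idx <- which(co)
        absorbed <- logical(length(st$id))
        absorbed[co_idx] <- below  # sub-cutoff scattered photon: history ends
        surv <- surv & !absorbed
        theta_all <- numeric(length(st$id))
        theta_all[co_idx] <- theta
        phi_all <- stats::runif(length(st$id), 0, 2 * pi)
        nd <- rotate_direction(cbind(st$dx, st$dy, st$dz), theta_all, phi_all)
        keep_dir <- co & surv
        st$dx[keep_dir] <- nd[keep_dir, 1]
        st$dy[keep_dir] <- nd[keep_dir, 2]
        st$dz[keep_dir] <- nd[keep_dir, 3]
        st$E[co_idx] <- kin$scattered
      }
      st <- list(id = st$id[surv], E = st$E[surv],
                 x = x[surv], y = y[surv], z = z[surv],
                 dx = st$dx[surv], dy = st$dy[surv], dz = st$dz[surv],
                 t = t[surv])
    }
  }

  sites <- if (length(chunks) > 0) do.call(rbind, chunks) else
    data.frame(event_id = integer(0), crystal_id = integer(0),
               x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
               edep_keV = numeric(0), t_ps = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
  sites <- sites[order(sites$event_id, sites$t_ps), , drop = FALSE]
  rownames(sites) <- NULL
  if (nrow(sites) > 0) {
    sites$site_index <- stats::ave(sites$event_id, sites$event_id,
                                   FUN = seq_along)
  } else sites$site_index <- integer(0)
  sites <- sites[, c("event_id", "site_index", "crystal_id", "x_mm", "y_mm",
                     "z_mm", "edep_keV", "t_ps", "kind")]

  events <- summarise_events(sites, n_events, escaped, source)
  if (n_events > 0) {
    events$x0_mm <- entry[, 1]; events$y0_mm <- entry[, 2]
  } else {
    events$x0_mm <- numeric(0); events$y0_mm <- numeric(0)
  }
  structure(list(sites = sites, events = events, geometry = geometry,
                 material = material, source = source),
            class = "gamma_events")
}

# Per-event summary table from the site list
summarise_events <- function(sites, n_events, escaped, source) {
  event_id <- crystal_id <- edep_keV <- NULL  # data.table NSE
  base <- data.table::data.table(event_id = seq_len(n_events))
  if (nrow(sites) > 0) {
    dt <- data.table::as.data.table(sites)
    agg <- dt[, list(
      edep_total = sum(edep_keV),
      E1_true = sum(edep_keV[crystal_id == source$crystal]),
      E2_true = sum(edep_keV[crystal_id != source$crystal]),
      n_sites = .N,
      n_sites_irr = sum(crystal_id == source$crystal),
      n_crystals = length(unique(crystal_id))
    ), by = event_id]
    out <- merge(base, agg, by = "event_id", all.x = TRUE)
    for (cc in c("edep_total", "E1_true", "E2_true"))
      out[[cc]][is.na(out[[cc]])] <- 0
    for (cc in c("n_sites", "n_sites_irr", "n_crystals"))
      out[[cc]][is.na(out[[cc]])] <- 0L
  } else {
    out <- base
    out$edep_total <- out$E1_true <- out$E2_true <- rep(0, n_events)
    out$n_sites <- out$n_sites_irr <- out$n_crystals <- rep(0L, n_events)
  }
  out$escaped_keV <- escaped
  data.table::setDF(out)
  out
}

# Rotate unit vectors d (n x 3) by polar angle theta about themselves with
# azimuth phi, via an orthonormal frame built per vector.
rotate_direction <- function(d, theta, phi) {
  n <- nrow(d)
  # pick a helper axis not parallel to d
  hx <- ifelse(abs(d[, 3]) < 0.99, 0, 1)
  hz <- 1 - hx
  # u = normalize(h x d), v = d x u
  ux <- hx * 0 + hz * 0 - d[, 2] * hz
  uy <- hz * d[, 1] - hx * d[, 3]
  uz <- hx * d[, 2]
  un <- sqrt(ux^2 + uy^2 + uz^2)
  un[un == 0] <- 1
  ux <- ux / un; uy <- uy / un; uz <- uz / un
  vx <- d[, 2] * uz - d[, 3] * uy
  vy <- d[, 3] * ux - d[, 1] * uz
  vz <- d[, 1] * uy - d[, 2] * ux
  st <- sin(theta); ct <- cos(theta)
  cp <- cos(phi); sp <- sin(phi)
  cbind(d[, 1] * ct + st * (ux * cp + vx * sp),
        d[, 2] * ct + st * (uy * cp + vy * sp),
        d[, 3] * ct + st * (uz * cp + vz * sp))
}

#' Truth-level event classification
#'
#' Labels each simulated gamma history from its ground-truth vertices:
#' `rejected` if the total deposit lies outside the photopeak window;
#' `InterCS` if deposits occur in two or more crystals; `IntraCS` if two or
#' more vertices lie in a single crystal; `PE` for a single vertex.  A
#' separate `pene` flag marks events whose deposits all lie outside the
#' irradiated crystal (penetration), which can co-occur with PE/IntraCS.
#'
#' @param x a `gamma_events` object.
#' @param photopeak_window accepted range of the total deposit, keV.
#' @return data.frame with `event_id`, `truth_class` and logical `pene`.
#' @export
truth_label <- function(x, photopeak_window = c(425, 600)) {
  ev <- x$events
  in_window <- ev$edep_total >= photopeak_window[1] &
    ev$edep_total <= photopeak_window[2]
  cls <- ifelse(!in_window, "rejected",
         ifelse(ev$n_crystals >= 2, "InterCS",
         ifelse(ev$n_sites >= 2, "IntraCS", "PE")))
  pene <- in_window & ev$n_sites > 0 & ev$n_sites_irr == 0
  data.frame(event_id = ev$event_id, truth_class = cls, pene = pene,
             stringsAsFactors = FALSE)
}

#' Fraction of intra-crystal-scatter events with large depth separation
#'
#' Among truth IntraCS events (at least two vertices in one crystal, ending in
#' photoelectric absorption), the fraction whose depth-of-interaction
#' separation between the first Compton vertex and the final photoelectric
#' vertex exceeds `threshold`.
#'
#' @param x a `gamma_events` object.
#' @param threshold DOI separation threshold, mm.
#' @param photopeak_window photopeak acceptance for the event total, keV.
#' @return fraction in \[0, 1\]; `NA` if no qualifying events.
#' @export
delta_doi_fraction <- function(x, threshold = 2, photopeak_window = c(425, 600)) {
  lab <- truth_label(x, photopeak_window)
  ids <- lab$event_id[lab$truth_class == "IntraCS"]
  if (length(ids) == 0) return(NA_real_)
  s <- x$sites[x$sites$event_id %in% ids, ]
  dt <- data.table::as.data.table(s)
  event_id <- kind <- z_mm <- t_ps <- NULL
  per <- dt[order(t_ps),
            list(z_c = z_mm[kind == "compton"][1],
                 z_pe = {zz <- z_mm[kind == "photoelectric"]
                         if (length(zz)) zz[length(zz)] else NA_real_}),
            by = event_id]
  per <- per[!is.na(per$z_c) & !is.na(per$z_pe), ]
  if (nrow(per) == 0) return(NA_real_)
  mean(abs(per$z_c - per$z_pe) > threshold)
}

#' @export
print.gamma_events <- function(x, ...) {
  cat(sprintf("<gamma_events> %d histories, %d interaction vertices\n",
              nrow(x$events), nrow(x$sites)))
  invisible(x)
}
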
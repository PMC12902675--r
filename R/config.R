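#' Simulation configuration
#'
#' Bundles geometry, material, source, optics, classification partition and
#' analysis parameters together with the RNG seed and the number of events.
#' The defaults reproduce the dual-pixel 2.5 x 2.8 x 15 mm BGO module with a
#' collimated 511 keV beam on the centre of crystal 1 and an 83 ps FWHM
#' reference detector.
#'
#' @param geometry a [detector_geometry()].
#' @param material a [material_model()].
#' @param source a [beam_source()].
#' @param optics an [optical_config()].
#' @param partition a [class_partition()].
#' @param analysis list of analysis parameters: `k_grid_ps`, `asym_breaks`,
#'   `prompt_window_ps`, `prompt_tolerance_ps`, `bin_width_ps`.
#' @param n_events default number of histories for [run_experiment()].
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(geometry = detector_geometry(),
                       material = bgo_material(),
                       source = beam_source(),
                       optics = optical_config(),
                       partition = class_partition(),
                       analysis = list(k_grid_ps = seq(-1000, 1000, by = 50),
                                       asym_breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                       prompt_window_ps = 1000,
                                       prompt_tolerance_ps = 300,
                                       bin_width_ps = 10),
                       n_events = 10000, seed = 1) {
  stopifnot(inherits(geometry, "detector_geometry"),
            inherits(material, "material_model"),
            inherits(source, "beam_source"),
            inherits(optics, "optical_config"),
            inherits(partition, "class_partition"))
  if (n_events < 0) stop("sim_config: n_events must be >= 0")
  analysis <- lapply(analysis, as.numeric)
  structure(list(geometry = geometry, material = material, source = source,
                 optics = optics, partition = partition, analysis = analysis,
                 n_events = as.integer(n_events), seed = as.integer(seed)),
            class = "sim_config")
}

# Keys allowed in each config file section (constructor argument names)
.config_keys <- function() list(
  geometry = names(formals(detector_geometry)),
  source = names(formals(beam_source)),
  optics = names(formals(optical_config)),
  partition = names(formals(class_partition)),
  material = c("density", "photofraction_511", "pe_exponent",
               "energy_cutoff", "n_grid"),
  analysis = c("k_grid_ps", "asym_breaks", "prompt_window_ps",
               "prompt_tolerance_ps", "bin_width_ps"),
  run = c("n_events", "seed")
)

#' Load a simulation configuration from a YAML file
#'
#' Reads a sectioned YAML file (`geometry:`, `material:`, `source:`,
#' `optics:`, `partition:`, `analysis:`, `run:`), fills every omitted key
#' with the package default, and validates.  Unknown sections or keys are a
#' hard error, naming the offending key.  An empty file yields the full
#' default configuration.
#'
#' @param path path to the YAML file.
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- .config_keys()
  bad_sec <- setdiff(names(raw), names(allowed))
  if (length(bad_sec))
    stop("load_config: unknown section(s): ", paste(bad_sec, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), allowed[[sec]])
    if (length(bad))
      stop("load_config: unknown key(s): ",
           paste(paste0(sec, ".", bad), collapse = ", "))
  }
  build <- function(fun, args) {
    tryCatch(do.call(fun, args), error = function(e)
      stop("load_config: ", conditionMessage(e), call. = FALSE))
  }
  geometry <- build(detector_geometry, raw$geometry %||% list())
  material <- build(bgo_material, raw$material %||% list())
  source <- build(beam_source, raw$source %||% list())
  optics <- build(optical_config, raw$optics %||% list())
  partition <- if (!is.null(raw$partition)) {
    pw <- raw$partition$photopeak_window
    args <- raw$partition
    if (!is.null(pw)) args$photopeak_window <- as.numeric(unlist(pw))
    build(class_partition, args)
  } else class_partition()
  defaults <- formals(sim_config)$analysis
  analysis <- utils::modifyList(eval(defaults), raw$analysis %||% list())
  run <- raw$run %||% list()
  sim_config(geometry = geometry, material = material, source = source,
             optics = optics, partition = partition, analysis = analysis,
             n_events = run$n_events %||% 10000, seed = run$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a simulation configuration to YAML
#'
#' Writes every parameter (including defaults) so that
#' `load_config(save_config(cfg, f))` round-trips exactly.
#'
#' @param config a [sim_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  g <- config$geometry; m <- config$material; o <- config$optics
  s <- config$source; p <- config$partition
  mat_args <- attr(m, "args") %||% list(density = m$density,
                                        energy_cutoff = m$energy_cutoff)
  out <- list(
    geometry = unclass(g),
    material = mat_args,
    source = unclass(s),
    optics = unclass(o),
    partition = unclass(p),
    analysis = config$analysis,
    run = list(n_events = config$n_events, seed = config$seed)
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Short content hash of a configuration
#'
#' FNV-1a hash over the serialised configuration, for tagging output tables
#' with the exact parameter set that produced them.
#'
#' @param config a [sim_config()].
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config, control = c("all", "hexNumeric")),
               collapse = "\n")
  b <- utf8ToInt(txt)
  h <- 17
  for (i in seq_along(b)) h <- (h * 131 + b[i]) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full simulation-plus-analysis experiment
#'
#' Orchestrates the chain end to end for a configuration: gamma transport,
#' optical simulation, readout, classification, and the standard analysis
#' tables (per-class CTR, margin sweep, asymmetry binning), writing
#' everything as CSV files under `outdir`.  Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param verbose logical; log per-stage event counts to stderr.
#' @return the run manifest (list): config hash, seed, package version and
#'   per-stage event counts; also written as `manifest.yaml`.
#' @export
run_experiment <- function(config = sim_config(), outdir = ".",
                           verbose = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("run_experiment: stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  sim <- stage("simulate", simulate_detector(config$n_events, config,
                                             seed = config$seed))
  say("simulate: %d histories, %d detected photons",
      nrow(sim$events), nrow(sim$photons))
  cl <- stage("classify", classify_events(
    sim, window = config$analysis$prompt_window_ps,
    tolerance = config$analysis$prompt_tolerance_ps))
  counts <- table(factor(cl$assigned_class,
                         levels = c("FED", "InterCS", "Pene", "rejected")))
  say("classify: FED %d, InterCS %d, Pene %d, rejected %d",
      counts["FED"], counts["InterCS"], counts["Pene"], counts["rejected"])

  write_events_csv(sim$sites, file.path(outdir, "truth_sites.csv"))
  write_events_csv(sim$readout, file.path(outdir, "readout.csv"))
  write_events_csv(cl, file.path(outdir, "classified.csv"))

  bw <- config$analysis$bin_width_ps
  ctr_rows <- list()
  for (cls in c("FED", "InterCS")) {
    d <- cl[cl$assigned_class == cls, ]
    strategies <- if (cls == "InterCS") c("min", "energy") else "min"
    for (st in strategies) {
      dd <- try(coincidence_deltas(d, st), silent = TRUE)
      if (!inherits(dd, "try-error") && length(dd) >= 100) {
        w <- fwhm_fwtm(dd, bw)
        ctr_rows[[length(ctr_rows) + 1L]] <-
          data.frame(class = cls, strategy = st, fwhm_ps = w$fwhm,
                     fwtm_ps = w$fwtm, n = length(dd))
      }
    }
  }
  if (length(ctr_rows))
    write_events_csv(do.call(rbind, ctr_rows), file.path(outdir, "ctr.csv"))

  ics <- cl[cl$assigned_class == "InterCS", ]
  if (nrow(ics) >= 200) {
    ks <- sweep_k(ics, config$analysis$k_grid_ps, bw)
    write_events_csv(ks, file.path(outdir, "sweep_k.csv"))
    ab <- asymmetry_binned_analysis(ics, config$analysis$asym_breaks,
                                    bin_width = bw)
    write_events_csv(ab, file.path(outdir, "asymmetry.csv"))
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("bgotof")),
    n_generated = nrow(sim$events),
    n_accepted = as.integer(sum(counts[c("FED", "InterCS", "Pene")])),
    class_counts = as.list(stats::setNames(as.integer(counts), names(counts)))
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  save_config(config, file.path(outdir, "config.yaml"))
  manifest
}

#' Write / read an event table as CSV
#'
#' Thin wrappers over [data.table::fwrite()] / [data.table::fread()]; numeric
#' columns are written with full round-trip precision.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_events_csv <- function(x, path) {
  data.table::fwrite(x, path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("read_events_csv: file not found: ", path)
  data.table::setDF(data.table::fread(path))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", config_hash(x), "seed", x$seed, "n_events", x$n_events, "\n")
  print(x$geometry); print(x$optics)
  invisible(x)
}
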
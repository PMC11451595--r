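# Orchestration: validated run configuration and a consolidated run report
# tying generator parameters to analysis outputs.

#' Validated run configuration
#'
#' Bundles everything a reproducible run needs: generator parameters, the
#' scaffold, analysis options and the output directory.  Validation errors
#' name the offending field.  Outputs are never overwritten unless
#' `overwrite = TRUE`.
#'
#' @param output_dir Directory for outputs (created if absent).
#' @param params A `generator_params`.
#' @param scaffold A `scaffold`; default [make_scaffold()].
#' @param contact_cutoff Ligand-contact cutoff (Angstrom).
#' @param density_bin Axial density bin width (Angstrom).
#' @param bulk_mM Bulk concentration for density normalization (mM).
#' @param reload_window_ns Follow-up window for the S4 reload diagnostic (ns).
#' @param emit_frames Also emit noisy 3D coordinates (needed for density,
#'   radial and contact statistics).
#' @param write_xyz Write the emitted frames as multi-frame XYZ.
#' @param overwrite Allow overwriting existing outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir, params, scaffold = make_scaffold(),
                       contact_cutoff = 4.5, density_bin = 0.5,
                       bulk_mM = 300, reload_window_ns = 100,
                       emit_frames = TRUE, write_xyz = FALSE,
                       overwrite = FALSE) {
  if (!is.character(output_dir) || length(output_dir) != 1L)
    stop_config("field 'output_dir' must be a single path")
  if (!inherits(params, "generator_params"))
    stop_config("field 'params' must be a generator_params object")
  validate_generator_params(params)
  validate_scaffold(scaffold)
  if (!is_scalar_num(contact_cutoff) || contact_cutoff <= 0)
    stop_config("field 'contact_cutoff' must be positive")
  if (!is_scalar_num(density_bin) || density_bin <= 0)
    stop_config("field 'density_bin' must be positive")
  if (!is_scalar_num(bulk_mM) || bulk_mM <= 0)
    stop_config("field 'bulk_mM' must be positive")
  if (!is_scalar_num(reload_window_ns) || reload_window_ns <= 0)
    stop_config("field 'reload_window_ns' must be positive")
  structure(list(output_dir = output_dir, params = params,
                 scaffold = scaffold, contact_cutoff = contact_cutoff,
                 density_bin = density_bin, bulk_mM = bulk_mM,
                 reload_window_ns = reload_window_ns,
                 emit_frames = isTRUE(emit_frames),
                 write_xyz = isTRUE(write_xyz),
                 overwrite = isTRUE(overwrite)),
            class = "run_config")
}

#' Generate, analyze and report one synthetic run
#'
#' Runs the knock-on generator under the configured parameters, writes the
#' scaffold (PDB), pore model (JSON), event log, detected events, occupancy
#' and (optionally) trajectory frames to the output directory, and returns a
#' consolidated report: package version, configuration echo, output
#' checksums, event counts, conductance, mean permeation interval, modal
#' filter occupancy, knock-on cycle count, and mode-specific statistics
#' (TEA radial 95th percentile; RY785 contact distribution).
#'
#' @param config A `run_config`.
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_report <- function(config) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$output_dir,
                     c(scaffold = "scaffold.pdb", model = "pore_model.json",
                       events = "event_log.tsv", perm = "permeation_events.tsv",
                       occ = "occupancy.tsv", report = "report.json",
                       xyz = "frames.xyz"))
  names(paths) <- c("scaffold", "model", "events", "perm", "occ", "report", "xyz")
  if (!config$overwrite && any(file.exists(paths)))
    stop_config("output files exist; set overwrite = TRUE to replace them")

  model <- build_pore_model(config$scaffold)
  write_scaffold_pdb(config$scaffold, paths[["scaffold"]])
  write_pore_model(model, paths[["model"]])

  log <- simulate_knockon(config$params)
  write_event_log(log, paths[["events"]])
  series <- site_series_from_log(log)
  events <- detect_permeation_events(series)
  utils::write.table(events, paths[["perm"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  occ <- filter_occupancy(series)
  utils::write.table(
    data.frame(time_ns = series$times, occupancy = occ$occupancy),
    paths[["occ"]], sep = "\t", quote = FALSE, row.names = FALSE)
  cycles <- detect_knockon_cycles(series)

  n_out <- sum(events$direction == "outward")
  dur_us <- log$duration_ns / 1000
  report <- list(
    package = "kvperm",
    version = as.character(utils::packageVersion("kvperm")),
    config = list(mode = config$params$mode,
                  duration_us = dur_us,
                  voltage_mV = config$params$voltage_mV,
                  seed = config$params$seed,
                  frame_interval_ns = config$params$frame_interval_ns),
    n_events_outward = n_out,
    n_events_inward = sum(events$direction == "inward"),
    eject_count = log$counts$eject_out,
    conductance_pS = if (config$params$voltage_mV != 0)
      conductance(n_out, dur_us, config$params$voltage_mV) else NA,
    mean_interval_us = mean_interval(n_out, dur_us),
    modal_filter_occupancy = occ$modal,
    n_knockon_cycles = nrow(cycles)
  )

  if (config$emit_frames) {
    frames <- emit_coordinates(log, model)
    if (config$params$mode == "TEA")
      report$tea_radial_p95_A <-
        radial_percentile(frames, "ligand_N", model, 0.95)
    if (config$params$mode == "RY785") {
      ct <- find_contacts(frames, config$scaffold, config$contact_cutoff)
      cd <- contact_distribution(ct)
      report$contact_modal_subunits <- as.list(cd$modal)
    }
    if (config$write_xyz) write_frames_xyz(frames, paths[["xyz"]])
  }

  report$checksums <- as.list(tools::md5sum(
    paths[file.exists(paths) & names(paths) != "report"]))
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
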
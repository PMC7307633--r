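# Reproducible pipeline runs: one entry point dispatching subcommands,
# writing outputs atomically together with a manifest (package version,
# parameters, seeds, input checksums). One run seed governs all
# stochastic stages, split deterministically per stage.

#' Run an analysis pipeline subcommand
#'
#' Subcommands and their outputs (all CSV unless noted):
#' * `"morpho"` — summarise a directory of SWC files (plus optional layer
#'   geometry CSV) into a cohort table (`cohort.csv`, `association.csv`).
#' * `"ca-events"` — detect events on per-ROI traces (`traces` CSV) and
#'   compute coactivity (`events.csv`, `coactivity.csv`).
#' * `"ephys"` — extract intrinsic and EPSP features from sweeps written
#'   by [write_ephys_sweeps()] (`cells.csv`).
#' * `"model-census"` / `"model-curve"` — census constants
#'   (`census.csv`) / response-probability curves (`curve.csv`).
#' * `"simulate-morpho"`, `"simulate-ca"`, `"simulate-ephys"` — write
#'   synthetic datasets with ground truth.
#'
#' Outputs are staged and moved into place only on success; a
#' `manifest.json` records the package version, R version, subcommand,
#' seed, parameters and MD5 checksums of the inputs.
#'
#' @param config named list (or path to a YAML/JSON file) with
#'   `subcommand`, `out` (output directory), optional `seed` (default 1)
#'   and subcommand-specific fields: `swc_dir`, `layers`, `traces`,
#'   `sampling_rate`, `sweep_dir`, `params` (overrides for
#'   [integration_params()] / spec constructors), `bl_grid`, `s_values`,
#'   `mode`, `variant`, `n_cells`.
#' @return Invisibly, the manifest list (with `status = "ok"`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- .read_config(config)
  stopifnot(is.list(config))
  sub <- config$subcommand %||% stop("config needs a `subcommand`",
                                     call. = FALSE)
  out <- config$out %||% stop("config needs an `out` directory",
                              call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  known <- c("morpho", "ca-events", "ephys", "model-census", "model-curve",
             "simulate-morpho", "simulate-ca", "simulate-ephys")
  if (!sub %in% known)
    stop("unknown subcommand '", sub, "'; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)

  staging <- tempfile("apcdend_run_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  inputs <- switch(sub,
    "morpho" = c(list.files(config$swc_dir, "\\.swc$", full.names = TRUE),
                 config$layers),
    "ca-events" = config$traces,
    "ephys" = file.path(config$sweep_dir, "sweeps.yaml"),
    character(0))
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]

  handler <- switch(sub,
    "morpho" = .run_morpho, "ca-events" = .run_ca_events,
    "ephys" = .run_ephys, "model-census" = .run_model_census,
    "model-curve" = .run_model_curve,
    "simulate-morpho" = .run_sim_morpho, "simulate-ca" = .run_sim_ca,
    "simulate-ephys" = .run_sim_ephys)
  params_used <- handler(config, seed, staging)

  manifest <- list(
    package = "apcdend",
    version = as.character(utils::packageVersion("apcdend")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    subcommand = sub, seed = seed, parameters = params_used,
    inputs = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list(),
    status = "ok")
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # atomic publish: move staged files into `out` only after success
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging, recursive = TRUE)) {
    dest <- file.path(out, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(staging, f), dest, overwrite = TRUE)
  }
  invisible(manifest)
}

.read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.run_morpho <- function(config, seed, staging) {
  files <- sort(list.files(config$swc_dir, "\\.swc$", full.names = TRUE))
  if (!length(files)) stop("no SWC files in ", config$swc_dir, call. = FALSE)
  g <- if (!is.null(config$layers)) read_layer_geometry(config$layers)
  summaries <- lapply(files, function(f) {
    m <- read_swc(f)
    if (!is.null(g)) {
      nd <- suppressWarnings(normalized_depth(m$soma_centroid[1:2], g))
      m$metadata$depth_norm <- nd$depth_norm
      m$metadata$cell_class <- nd$cell_class
    }
    morphometry_summary(m, geometry = g)
  })
  tab <- cohort_table(summaries)
  utils::write.csv(as.data.frame(tab), file.path(staging, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(tab, "association"),
                   file.path(staging, "association.csv"), row.names = FALSE)
  list(n_cells = length(files), layers = !is.null(config$layers))
}

.run_ca_events <- function(config, seed, staging) {
  rate <- config$sampling_rate %||% stop("ca-events needs `sampling_rate`",
                                         call. = FALSE)
  rois <- filter_rois(read_roi_traces_csv(config$traces, rate))
  thr <- config$threshold_sd %||% 2.5
  sdm <- config$sd_method %||% "mad"
  events <- detect_fov_events(rois, threshold_sd = thr, sd_method = sdm)
  utils::write.csv(events, file.path(staging, "events.csv"),
                   row.names = FALSE)
  if (nrow(events)) {
    co <- coactivity(events, rois)
    utils::write.csv(co$records, file.path(staging, "coactivity.csv"),
                     row.names = FALSE)
  }
  list(threshold_sd = thr, sd_method = sdm, min_pixels = 70,
       sampling_rate = rate)
}

.run_ephys <- function(config, seed, staging) {
  meta <- yaml::read_yaml(file.path(config$sweep_dir, "sweeps.yaml"))
  files <- vapply(meta$sweeps, `[[`, "", "file")
  ss <- read_sweeps(file.path(config$sweep_dir, files),
                    file.path(config$sweep_dir, "sweeps.yaml"))
  amp <- vapply(ss$sweeps, function(s)
    (s$step %||% list(amplitude = NA_real_))$amplitude %||% NA_real_, 0)
  has_stim <- vapply(ss$sweeps, function(s)
    length(s$stim_times) >= 3L, TRUE)
  pp <- passive_properties(sweep_set(ss$sweeps[!is.na(amp) & amp < 0],
                                     ss$sampling_rate))
  sf <- spike_features(sweep_set(ss$sweeps[!is.na(amp) & amp > 0],
                                 ss$sampling_rate))
  row <- data.frame(Vm = pp$Vm, Rin = pp$Rin, Tau = pp$tau, Cm = pp$Cm,
                    Threshold = sf$ap_threshold, fAHP = sf$fAHP,
                    Instant_firing_freq = sf$instant_freq)
  if (any(has_stim)) {
    em <- epsp_metrics(ss$sweeps[has_stim][[1L]], ss$sampling_rate)
    row$EPSP_amplitude <- em$amplitude
    row$EPSP_auc <- em$auc
  }
  utils::write.csv(row, file.path(staging, "cells.csv"), row.names = FALSE)
  list(n_sweeps = length(ss$sweeps))
}

.params_from_config <- function(config) {
  do.call(integration_params, config$params %||% list())
}

.run_model_census <- function(config, seed, staging) {
  cen <- derive_census(.params_from_config(config))
  utils::write.csv(as.data.frame(cen), file.path(staging, "census.csv"),
                   row.names = FALSE)
  list(params = unclass(.params_from_config(config)))
}

.run_model_curve <- function(config, seed, staging) {
  params <- .params_from_config(config)
  bl_grid <- config$bl_grid %||% seq(params$bl_range[1], params$bl_range[2])
  s_values <- config$s_values %||% c(10, 25, 40, 55, 70)
  curve <- response_curve(params, bl_grid, s_values,
                          mode = config$mode %||% "clustered",
                          variant = config$variant %||% "standard_tail")
  utils::write.csv(as.data.frame(curve), file.path(staging, "curve.csv"),
                   row.names = FALSE)
  list(bl_grid = range(bl_grid), s_values = s_values,
       mode = curve$mode, variant = curve$variant)
}

.run_sim_morpho <- function(config, seed, staging) {
  spec <- do.call(morph_cohort_spec, config$params %||% list())
  cohort <- gen_morphology_cohort(spec, config$n_cells %||% 30,
                                  seed = .stage_seed(seed, "morpho"))
  write_morph_cohort(cohort, staging)
  list(spec = unclass(spec), n_cells = length(cohort$cells),
       stage_seed = .stage_seed(seed, "morpho"))
}

.run_sim_ca <- function(config, seed, staging) {
  spec <- do.call(ca_fov_spec, config$params %||% list())
  fov <- gen_ca_fov(spec, seed = .stage_seed(seed, "ca"))
  write_ca_fov(fov, staging)
  list(spec = unclass(spec), stage_seed = .stage_seed(seed, "ca"))
}

.run_sim_ephys <- function(config, seed, staging) {
  spec <- do.call(ephys_spec, config$params %||% list())
  sim <- gen_ephys_sweeps(spec, seed = .stage_seed(seed, "ephys"))
  write_ephys_sweeps(sim, staging)
  list(spec = unclass(spec), stage_seed = .stage_seed(seed, "ephys"))
}
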
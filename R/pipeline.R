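# Workflow orchestration: a YAML run configuration and the canonical
# workflows (synthetic bundle, connectivity indices, hilltop model
# comparison, time-series model grid, dispersal-mode simulation). Each
# command is an exported function; inst/exec/hilltopdyn is a thin shell
# wrapper around them.

run_config_defaults <- function() {
  list(
    paths = list(patches = NULL, hilltops = NULL, census = NULL,
                 climate = NULL, moths = NULL),
    alpha = 1,
    log_offset = 1,
    moth_pred = list(intercept = -0.89, slope_ci = 1.27, slope_elev = 0.02),
    sampler = list(chains = 2, adapt = 1000, burn = 1000, iter = 2000,
                   thin = 1, seed = 1),
    sim = list(n_reps = 10000, n_years = 15, fit_kind = "ECI", seed = 1,
               density_cap = 1e6),
    out_dir = "hilltopdyn-run",
    seed = 1
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown config key: ", paste0(path, key))
    if (is.list(defaults[[key]]) && is.list(user[[key]]))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(path, key, "."))
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and rejects unknown
#' keys. Overrides supplied as a list win over the file.
#'
#' @param path YAML config path, or NULL
#' @param overrides named list of overrides (nested lists allowed)
#' @return validated config list of class `run_config`
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "run_config")
}

config_objects <- function(cfg) {
  list(params = kernel_params(cfg$alpha),
       coefs = moth_pred_coefs(cfg$moth_pred$intercept,
                               cfg$moth_pred$slope_ci,
                               cfg$moth_pred$slope_elev),
       sampler = sampler_config(cfg$sampler$chains, cfg$sampler$adapt,
                                cfg$sampler$burn, cfg$sampler$iter,
                                cfg$sampler$thin, cfg$sampler$seed))
}

read_inputs <- function(cfg, need_moths = FALSE) {
  p <- cfg$paths
  for (nm in c("patches", "hilltops", "census", "climate")) {
    if (is.null(p[[nm]])) stop("config paths$", nm, " is required")
    if (!file.exists(p[[nm]])) stop("input file not found: ", p[[nm]])
  }
  out <- list(landscape = read_landscape(p$patches, p$hilltops),
              census = read_census(p$census),
              climate = read_climate(p$climate))
  if (need_moths) {
    if (is.null(p$moths) || !file.exists(p$moths))
      stop("config paths$moths is required for this command")
    out$moths <- read_moths(p$moths)
  }
  out
}

prepare_out_dir <- function(cfg, stage) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stage = stage, seed = cfg$seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config = unclass(cfg))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir,
                                 paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  cfg$out_dir
}

#' Write a full synthetic input bundle to disk
#'
#' Generates the default scenario under the config seed and writes the five
#' input CSVs into the output directory; the returned config fragment can be
#' fed straight back into the other commands.
#'
#' @param cfg a [run_config()]
#' @return (invisibly) list of written paths
#' @export
cmd_synth <- function(cfg = run_config()) {
  out <- prepare_out_dir(cfg, "synth")
  bundle <- gen_bundle(make_bodega_like_scenario(cfg$seed))
  paths <- list(patches = file.path(out, "patches.csv"),
                hilltops = file.path(out, "hilltops.csv"),
                census = file.path(out, "census.csv"),
                climate = file.path(out, "climate.csv"),
                moths = file.path(out, "moths.csv"))
  write_landscape(bundle$landscape, paths$patches, paths$hilltops)
  write_census(bundle$census$panel, paths$census)
  write_climate(bundle$climate, paths$climate)
  write_moths(bundle$moths$panel, paths$moths)
  invisible(paths)
}

#' Compute and export all connectivity indices
#'
#' Emits CI, HCI, ECI and hilltop-exposure long CSVs plus a JSON of the
#' scalers used.
#'
#' @param cfg a [run_config()]
#' @return (invisibly) named list of `connectivity_matrix` objects
#' @export
cmd_indices <- function(cfg = run_config()) {
  ob <- config_objects(cfg)
  inp <- read_inputs(cfg, need_moths = TRUE)
  out <- prepare_out_dir(cfg, "indices")
  A <- log_abundance(inp$census, cfg$log_offset)
  cms <- list(
    CI = hanski_ci(inp$landscape, A, ob$params),
    HCI = hilltop_ci(inp$landscape, A, ob$params),
    ECI = elevation_ci(inp$landscape, A, ob$params, ob$coefs,
                       log_offset = cfg$log_offset),
    HILLTOP_EXPOSURE = hilltop_exposure(inp$landscape, inp$moths, ob$params,
                                        cfg$log_offset))
  for (nm in names(cms))
    write_connectivity(cms[[nm]], file.path(out, paste0("index-", nm, ".csv")))
  scalers <- lapply(cms, function(cm)
    if (is.null(cm$scaler)) NULL else unclass(cm$scaler))
  jsonlite::write_json(scalers, file.path(out, "index-scalers.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(cms)
}

#' Fit and compare the hilltop moth-abundance model structures
#'
#' @param cfg a [run_config()]
#' @return (invisibly) the [compare_moth_models()] result; the table is
#'   written as `moth-model-comparison.csv`
#' @export
cmd_moth_models <- function(cfg = run_config()) {
  ob <- config_objects(cfg)
  inp <- read_inputs(cfg, need_moths = TRUE)
  out <- prepare_out_dir(cfg, "moth-models")
  frame <- build_moth_frame(inp$moths, inp$landscape, inp$census, ob$params,
                            cfg$log_offset)
  cmp <- compare_moth_models(frame, ob$sampler)
  write.csv(cmp$table, file.path(out, "moth-model-comparison.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(cmp)
}

#' Fit the nine-structure time-series model grid
#'
#' @param cfg a [run_config()]
#' @return (invisibly) the [compare_ts_models()] result; the table is
#'   written as `ts-model-comparison.csv`
#' @export
cmd_ts_grid <- function(cfg = run_config()) {
  ob <- config_objects(cfg)
  inp <- read_inputs(cfg)
  out <- prepare_out_dir(cfg, "ts-grid")
  cmp <- compare_ts_models(inp$census, inp$climate, inp$landscape,
                           ob$sampler, ob$params, ob$coefs, cfg$log_offset)
  write.csv(cmp$table, file.path(out, "ts-model-comparison.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(cmp)
}

#' Run the dispersal-mode simulation experiment
#'
#' Fits the full time-series structure with the configured index, then
#' simulates the fitted model under CI, HCI and ECI with a shared seed
#' schedule; writes per-replicate summaries and per-kind medians.
#'
#' @param cfg a [run_config()]
#' @return (invisibly) the [run_experiment()] result
#' @export
cmd_simulate <- function(cfg = run_config()) {
  ob <- config_objects(cfg)
  inp <- read_inputs(cfg)
  out <- prepare_out_dir(cfg, "simulate")
  A <- log_abundance(inp$census, cfg$log_offset)
  kind <- match.arg(cfg$sim$fit_kind, c("CI", "HCI", "ECI"))
  cm <- connectivity_index(kind, inp$landscape, A, ob$params, ob$coefs,
                           log_offset = cfg$log_offset)
  spec <- ts_model_spec(TRUE, TRUE, TRUE, TRUE, kind)
  frame <- build_ts_design(inp$census, inp$climate, cm, spec,
                           log_offset = cfg$log_offset)
  fit <- fit_ts_model(frame, spec, ob$sampler)
  params <- ts_posterior_means(fit)
  scfg <- sim_config(cfg$sim$n_reps, cfg$sim$n_years, kind, cfg$sim$seed,
                     cfg$sim$density_cap, cfg$log_offset)
  exp <- run_experiment(inp$landscape, params, inp$climate, inp$census,
                        scfg, kernel = ob$params, coefs = ob$coefs,
                        log_offset = cfg$log_offset)
  write_sim_summaries(exp, file.path(out, "simulation-summaries.csv"))
  jsonlite::write_json(
    list(medians = exp$medians, observed = exp$observed),
    file.path(out, "simulation-medians.json"),
    auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  invisible(exp)
}
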
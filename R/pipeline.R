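# Declarative pipeline: one YAML (or list) config drives
# input -> binarize -> simulate -> heatmap / calibrate, with a manifest per
# output directory. Seeds are always explicit, never wall-clock.

pipeline_keys <- c("seed", "output_dir", "input", "binarize", "simulation",
                   "heatmap", "calibrate")

validate_config <- function(config) {
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$input)) stop("config key 'input' is required")
  if (!is.null(config$simulation$diffusivity_dp) &&
      config$simulation$diffusivity_dp <= 0) {
    stop("config key 'simulation.diffusivity_dp' must be positive")
  }
  src <- c("synthetic", "map") %in% names(config$input)
  if (!any(src)) stop("config key 'input' needs either 'synthetic' or 'map'")
  if (!is.null(config$input$map) && !file.exists(config$input$map)) {
    stop("input map not found: ", config$input$map)
  }
  if (!is.null(config$input$ground_truth) &&
      !file.exists(config$input$ground_truth)) {
    stop("input ground_truth not found: ", config$input$ground_truth)
  }
  invisible(config)
}

build_sim_config <- function(sim, seed) {
  sim <- sim %||% list()
  simulation_config(
    diffusivity_dp = sim$diffusivity_dp %||% 1e-6,
    lattice_spacing_nm = sim$lattice_spacing_nm %||% 8,
    n_particles = sim$n_particles %||% 1000,
    t_end_s = sim$t_end_s %||% 0.003,
    seed = sim$seed %||% seed)
}

#' Run the image-to-diffusivity pipeline from a config
#'
#' Executes, per the configuration: input acquisition (a synthetic domain
#' plus emulated grayscale rendering, or a map image from disk), threshold
#' binarization, LKMC simulation with diffusivity estimation, and the
#' optional heatmap and calibration stages. All stage outputs land in
#' `output_dir` together with a run manifest recording the resolved
#' configuration, the seeds, input digests and the package version.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Top-level keys: `seed`, `output_dir`, `input` (with `synthetic`
#'   spec fields or a `map` path, optional `ground_truth` mask path,
#'   `pixel_size_nm`), `binarize` (`btv`, `polarity`), `simulation`
#'   (fields of [simulation_config()]), optional `heatmap` (fields of
#'   [subdomain_grid()]) and optional `calibrate` (`btv_grid`, `refine`).
#'   Unknown keys fail fast.
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, a list of the objects produced per stage.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  input_files <- character()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    input_files <- config
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  seed <- config$seed %||% 1
  out_dir <- output_dir %||% config$output_dir %||% stop("output_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()

  px_nm <- config$input$pixel_size_nm %||% 8
  if (!is.null(config$input$synthetic)) {
    syn <- config$input$synthetic
    spec <- synthetic_spec(
      class_label = syn$class_label %||% "dense",
      grid_shape = unlist(syn$grid_shape %||% c(250, 250)),
      lattice_spacing_nm = px_nm,
      target_porosity = syn$target_porosity,
      ellipse_count = syn$ellipse_count,
      min_gap_nm = syn$min_gap_nm %||% 40,
      seed = syn$seed %||% seed)
    gt <- generate_domain(spec)
    map <- emulate_grayscale(gt, grayscale_emulation_spec(seed = seed))
    write_mask(gt, file.path(out_dir, "synthetic_domain.png"))
    write_grayscale_map(map, file.path(out_dir, "synthetic_map.png"))
    outputs$ground_truth <- gt
  } else {
    map <- read_grayscale_map(config$input$map, pixel_size_nm = px_nm)
    input_files <- c(input_files, config$input$map)
    if (!is.null(config$input$ground_truth)) {
      outputs$ground_truth <- read_mask(config$input$ground_truth,
                                        lattice_spacing_nm = px_nm)
      input_files <- c(input_files, config$input$ground_truth)
    }
  }
  outputs$map <- map

  if (!is.null(config$binarize)) {
    domain <- binarize(map, config$binarize$btv,
                       config$binarize$polarity %||% "dark_pore")
    write_mask(domain, file.path(out_dir, "binarized_domain.png"))
  } else if (!is.null(outputs$ground_truth)) {
    domain <- outputs$ground_truth
  } else {
    stop("config needs a 'binarize' stage when the input is a map image")
  }
  outputs$domain <- domain

  sim_cfg <- build_sim_config(config$simulation, seed)
  t_min_s <- config$simulation$t_min_s %||% 0.001
  series <- run_simulation(domain, sim_cfg)
  est <- estimate_diffusivity(series, t_min_s = t_min_s,
                              dp = sim_cfg$diffusivity_dp)
  write_msd_csv(series, file.path(out_dir, "msd.csv"))
  write_diffusivity_json(est, file.path(out_dir, "diffusivity.json"))
  outputs$msd <- series
  outputs$diffusivity <- est

  if (!is.null(config$heatmap)) {
    grid <- subdomain_grid(
      subdomain_size_sites = config$heatmap$subdomain_size_sites %||% 250,
      stagger_sites = config$heatmap$stagger_sites %||% 125)
    hm <- local_diffusivity_map(domain, grid, sim_cfg, t_min_s = t_min_s)
    write_heatmap(hm, file.path(out_dir, "heatmap"))
    outputs$heatmap <- hm
  }

  if (!is.null(config$calibrate)) {
    if (is.null(outputs$ground_truth)) {
      stop("calibrate stage requires a ground-truth domain")
    }
    grid_b <- config$calibrate$btv_grid %||% seq(0, 255, by = 5)
    curve <- calibrate_btv(list(map), list(outputs$ground_truth),
                           btv_grid = unlist(grid_b), config = sim_cfg,
                           refine = isTRUE(config$calibrate$refine),
                           t_min_s = t_min_s)
    jsonlite::write_json(
      list(btv = curve$btv_values, ratio_mean = curve$ratio_mean,
           optimal_btv = curve$optimal_btv,
           tolerance_band = curve$tolerance_band),
      file.path(out_dir, "calibration.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    write.csv(data.frame(btv = curve$btv_values,
                         ratio_mean = curve$ratio_mean,
                         ratio_spread = curve$ratio_spread),
              file.path(out_dir, "calibration.csv"), row.names = FALSE)
    outputs$calibration <- curve
  }

  write_manifest(run_manifest("pipeline", config, seed, input_files), out_dir)
  invisible(outputs)
}
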
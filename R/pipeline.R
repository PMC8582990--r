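#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with
#' every stage's parameters in one place. Pass a modified copy, or a YAML
#' file with the same structure, to change behavior.
#'
#' @param seed Master seed.
#' @return Named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    wells_csv = NULL,                # path to an existing wells table, or NULL
    simulate = list(                 # used when wells_csv is NULL
      n_wells = 300L,
      nugget = 0.015, psill = 0.05, range = 15000,
      kind = "exponential",
      log_mean = -0.05,
      extent = c(0, 30000, 0, 25000),
      detection_limit = 0.9),
    origin = c(0, 0),                # coordinate re-centering
    split_k = 3L,
    variogram = list(kind = "exponential", bin_width = NULL,
                     max_lag = NULL, min_pairs = 30L),
    bpnn = list(structure = c(2L, 10L, 10L, 1L), restarts = 3L,
                mse_goal = 1e-2, max_epochs = 1000L),
    methods = c("ok", "bpnn"),       # compared by CV; winner draws the map
    grid = list(cell_size = 1000, padding = 1000),
    exposure = list(),               # overrides for exposure_params()
    irrigation_limit = 50)
}

#' Run the full concentration-to-risk pipeline
#'
#' Executes: well ingestion or simulation, coordinate re-centering and
#' the concentration-ordered split, cross-validated comparison of
#' ordinary kriging and the BPNN, selection of the winner by average
#' validation R^2 (ties by RMSE), spatial mapping of the winner over a
#' 1 km grid, and conversion to risk and suitability layers. All
#' artifacts are written under `out_dir` and stamped (in `log.json`)
#' with the configuration hash and seed; runs are deterministic given
#' the seeds.
#'
#' Artifacts: `wells.csv`, `split.csv`, `variogram.json` (all-well fit),
#' `cv_report.csv`, `bpnn.json` (when the BPNN runs), `conc.asc`,
#' `conc_log10.asc`, `grid.csv` (all layers), `zones_suitability.geojson`,
#' `log.json`.
#'
#' @param config A list as from [default_config()], or a path to a YAML
#'   file with the same fields.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the wells, split, CV report, selected
#'   method, concentration grid and artifact paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(config$seed %||% 1L), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log <- list(config_hash = config_hash(cfg), seed = cfg$seed,
              stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      log$stages[[name]] <<- list(status = "failed",
                                  error = conditionMessage(e))
      jsonlite::write_json(log, file.path(out_dir, "log.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    res
  }

  # -- wells -----------------------------------------------------------
  wells <- stage("wells", {
    if (!is.null(cfg$wells_csv)) {
      w <- read_wells(cfg$wells_csv)
    } else {
      s <- cfg$simulate
      fs <- field_spec(variogram_model(s$kind, s$nugget, s$psill, s$range),
                       log_mean = s$log_mean, extent = s$extent,
                       seed = cfg$seed)
      w <- simulate_wells(fs, s$n_wells,
                          detection_limit = s$detection_limit,
                          seed = derive_seed(cfg$seed, 1L))
    }
    w
  })
  wells <- recenter_wells(wells, cfg$origin)
  paths$wells <- file.path(out_dir, "wells.csv")
  write_wells(wells, paths$wells)
  log$stages$wells <- list(status = "ok", n_wells = nrow(wells),
                           n_censored = sum(wells$censored))

  # -- split -----------------------------------------------------------
  split <- stage("split", ordered_split(wells, k = cfg$split_k))
  paths$split <- file.path(out_dir, "split.csv")
  write_split(split, paths$split)
  log$stages$split <- list(status = "ok",
                           sizes = as.list(table(split$set)))

  # -- variogram on all wells (for the final OK map) -------------------
  vg <- stage("variogram", {
    emp <- empirical_semivariogram(cbind(wells$x, wells$y),
                                   log_transform(wells$conc_ugL),
                                   bin_width = cfg$variogram$bin_width,
                                   max_lag = cfg$variogram$max_lag,
                                   min_pairs = cfg$variogram$min_pairs)
    fit_variogram_model(emp, kind = cfg$variogram$kind)
  })
  paths$variogram <- file.path(out_dir, "variogram.json")
  write_variogram_json(vg, paths$variogram)
  log$stages$variogram <- list(status = "ok", kind = vg$kind,
                               nugget = vg$nugget, psill = vg$psill,
                               range = vg$range)

  # -- cross-validated comparison --------------------------------------
  net <- network_spec(cfg$bpnn$structure)
  tc <- train_config(mse_goal = cfg$bpnn$mse_goal,
                     max_epochs = cfg$bpnn$max_epochs,
                     seed = cfg$seed)
  cv <- stage("crossval",
      cross_validate(wells, split, variogram_kind = cfg$variogram$kind,
                     net_spec = net, config = tc,
                     restarts = cfg$bpnn$restarts, seed = cfg$seed,
                     methods = cfg$methods,
                     variogram_args = list(
                       bin_width = cfg$variogram$bin_width,
                       max_lag = cfg$variogram$max_lag,
                       min_pairs = cfg$variogram$min_pairs)))
  paths$cv_report <- file.path(out_dir, "cv_report.csv")
  utils::write.csv(as.data.frame(cv), paths$cv_report, row.names = FALSE,
                   quote = FALSE)
  avg <- cv_averages(cv)
  avg <- avg[order(-avg$r2, avg$rmse), ]
  selected <- avg$method[1L]
  log$stages$crossval <- list(status = "ok", selected = selected,
                              averages = avg)

  # -- map with the selected method ------------------------------------
  grid <- make_grid(wells, cell_size = cfg$grid$cell_size,
                    padding = cfg$grid$padding)
  cgrid <- stage("map", {
    if (selected == "ok") {
      ok_map(wells, grid, vg)
    } else {
      fit <- train_restarts(net, cbind(wells$x, wells$y),
                            log_transform(wells$conc_ugL), tc,
                            cfg$bpnn$restarts,
                            master_seed = derive_seed(cfg$seed, 99L))
      paths$bpnn <- file.path(out_dir, "bpnn.json")
      write_bpnn_json(fit, paths$bpnn)
      bpnn_map(fit, grid)
    }
  })
  log$stages$map <- list(status = "ok", method = selected,
                         cells = grid$ncols * grid$nrows)

  # -- risk layers and artifacts ---------------------------------------
  p <- do.call(exposure_params, cfg$exposure)
  cgrid <- stage("risk", add_risk_layers(cgrid, p))
  paths$conc_asc <- file.path(out_dir, "conc.asc")
  write_grid_asc(cgrid$layers$conc_ugL, grid, paths$conc_asc)
  paths$conc_log10_asc <- file.path(out_dir, "conc_log10.asc")
  write_grid_asc(cgrid$layers$log10_est, grid, paths$conc_log10_asc)
  paths$grid_csv <- file.path(out_dir, "grid.csv")
  write_grid_csv(cgrid, paths$grid_csv)
  paths$zones <- file.path(out_dir, "zones_suitability.geojson")
  n_zones <- write_zones(cgrid$layers$suitability, grid, paths$zones)
  log$stages$risk <- list(
    status = "ok", n_zones = n_zones,
    cells_per_class = as.list(table(cgrid$layers$conc_class)),
    cells_unsuitable = sum(cgrid$layers$suitability == 2L))

  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$log <- file.path(out_dir, "log.json")
  invisible(list(wells = wells, split = split, cv_report = cv,
                 selected = selected, grid = cgrid, variogram = vg,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a hash of the deparsed configuration: a stable stamp tying
# artifacts to the exact parameters that produced them.
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keep h as double
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
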
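#' Run the end-to-end cross-calibration experiment
#'
#' Orchestrates the full pipeline: simulate (or ingest) matchups, retrieve
#' products, filter, tune coefficients by equal-lake-weight bootstrap,
#' calibrate, and evaluate before/after agreement — writing all tables and
#' reports to an output directory together with a run manifest.
#'
#' The configuration is a named list (or a YAML/JSON path readable by
#' [read_experiment_config()]) with elements:
#' * `seed` — root seed (overrides the synthetic config's seed);
#' * `output_dir` — where artifacts are written;
#' * `matchups` — path to a matchup CSV, or `NULL` to simulate;
#' * `synthetic` — arguments forwarded to [synthetic_config()] (ignored if
#'   `matchups` given); an empty list uses the generator defaults;
#' * `registry` — coefficient registry path (`NULL` = bundled);
#' * `nechad` — per-band Nechad A/C JSON path (`NULL` = bundled synthetic
#'   fixture);
#' * `algorithms` — subset of `c("oc2", "oc3", "gilerson", "gons05",
#'   "turbidity")`;
#' * `turbidity_band` — canonical band for the turbidity pathway;
#' * `tuning` — arguments forwarded to [tuning_settings()];
#' * `per_lake` — algorithms additionally tuned per lake;
#' * `oc2_scaling` — if `TRUE`, also evaluate the linear band-ratio scaling
#'   alternative for OC2;
#' * `owt_reference` — OWT reference CSV path (`NULL` = bundled synthetic
#'   fixture; `FALSE` disables the OWT stratification).
#'
#' @param config Named list or path.
#' @return A `run_manifest` list: config hash, seeds, per-stage row counts,
#'   artifact paths, package version, timestamps.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  cfg <- utils::modifyList(list(
    seed = 1L, output_dir = tempfile("lakecal_run_"), matchups = NULL,
    synthetic = list(), registry = NULL, nechad = NULL,
    algorithms = c("oc2", "oc3", "gilerson", "gons05", "turbidity"),
    turbidity_band = "b708", tuning = list(), per_lake = character(),
    oc2_scaling = TRUE, owt_reference = NULL
  ), config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- read_registry(cfg$registry)
  nechad_path <- if (is.null(cfg$nechad)) {
    system.file("extdata", "nechad_coefficients_synthetic.json",
                package = "lakecal")
  } else {
    cfg$nechad
  }
  t_start <- Sys.time()
  artifacts <- character()
  counts <- list()
  emit <- function(name, writer) {
    path <- file.path(cfg$output_dir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
    path
  }

  # --- stage: simulate / ingest -------------------------------------------
  if (!is.null(cfg$matchups)) {
    matchups <- read_matchups(cfg$matchups)
    truth <- NULL
  } else {
    syn_args <- cfg$synthetic
    syn_args$seed <- cfg$seed
    syn <- do.call(synthetic_config, syn_args)
    ds <- generate_dataset(syn)
    matchups <- ds$matchups
    truth <- ds$truth
    emit("truth.csv", function(p) write_matchups(truth, p))
  }
  counts$matchups <- nrow(matchups)

  ts <- do.call(tuning_settings, utils::modifyList(list(seed = cfg$seed),
                                                   cfg$tuning))
  results <- list()
  for (alg in cfg$algorithms) {
    stage_log("filter", alg)
    band <- if (alg == "turbidity") cfg$turbidity_band else "b708"
    fc <- run_filter_cascade(matchups, alg, registry = registry,
                             nechad = nechad_path, band = band)
    counts[[paste0("filtered_", alg)]] <- nrow(fc$table)
    emit(paste0("filter_report_", alg, ".json"),
         function(p) write_filter_report(fc$report, p))
    emit(paste0("filtered_", alg, ".csv"),
         function(p) write_matchups(fc$table, p))
    if (nrow(fc$table) < 2) {
      warning("algorithm ", alg, ": fewer than 2 survivors; skipped",
              call. = FALSE)
      next
    }

    stage_log("tune", alg)
    init <- if (alg == "turbidity") NULL else {
      registry_coefficients(registry, "msi", alg, stage = "initial")
    }
    tr <- bootstrap_tune(fc$table, alg, init = init, settings = ts)
    emit(paste0("tuning_", alg, ".json"),
         function(p) write_tuning_result(tr, p))

    stage_log("calibrate", alg)
    kind <- if (alg == "turbidity") "turbidity" else "chla"
    if (alg == "turbidity") {
      before_x <- fc$table$turb_msi
      y <- fc$table$turb_olci
      after_x <- apply_linear_calibration(before_x,
                                          median_coefficients(tr))
    } else {
      before_x <- fc$table$chla_msi
      y <- fc$table$chla_olci
      after_tab <- retrieve_products(fc$table, alg, registry = registry,
                                     msi_coefficients =
                                       median_coefficients(tr))
      after_x <- after_tab$chla_msi
    }

    stage_log("evaluate", alg)
    metrics <- dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(dataset = "before"),
                       compute_metrics(before_x, y, kind = kind)),
      dplyr::bind_cols(tibble::tibble(dataset = "after"),
                       compute_metrics(after_x, y, kind = kind))
    )
    emit(paste0("metrics_", alg, ".csv"),
         function(p) write_metrics(metrics, path_csv = p))
    if (alg != "turbidity") {
      dev <- coefficient_deviation(init, median_coefficients(tr))
      emit(paste0("deviation_", alg, ".csv"), function(p) {
        utils::write.csv(data.frame(parameter = names(dev),
                                    multiplier = unname(dev)),
                         p, row.names = FALSE)
      })
    }
    res_after <- after_x - y
    dist_summary <- residuals_by_distance(fc$table$dist_land_km, res_after)
    emit(paste0("residuals_by_distance_", alg, ".csv"), function(p) {
      utils::write.csv(as.data.frame(
        dplyr::bind_rows(dist_summary$bins, dist_summary$split)),
        p, row.names = FALSE)
    })
    if (!isFALSE(cfg$owt_reference)) {
      ref <- read_owt_reference(
        if (is.character(cfg$owt_reference)) cfg$owt_reference else NULL)
      owt <- classify_owt(sensor_spectra(fc$table, "olci"), ref)
      strat <- stratified_metrics(after_x, y, owt$class_id, kind = kind,
                                  min_n = 10)
      emit(paste0("owt_metrics_", alg, ".csv"),
           function(p) write_metrics(strat, path_csv = p))
    }
    if (alg %in% cfg$per_lake) {
      pl <- per_lake_tune(fc$table, alg, init = init, settings = ts)
      emit(paste0("per_lake_", alg, ".csv"), function(p) {
        utils::write.csv(as.data.frame(pl$summary), p, row.names = FALSE)
      })
    }
    if (alg == "oc2" && isTRUE(cfg$oc2_scaling)) {
      scale_cal <- fit_linear_scaling(log10(fc$table$ratio_msi),
                                      log10(fc$table$ratio_olci))
      scaled <- retrieve_products(
        fc$table, "oc2", registry = registry,
        msi_coefficients = registry_coefficients(registry, "olci", "oc2"),
        msi_ratio_scaling = scale_cal)
      m_scale <- dplyr::bind_cols(
        tibble::tibble(dataset = "oc2scale"),
        compute_metrics(scaled$chla_msi, y, kind = "chla"))
      emit("metrics_oc2scale.csv",
           function(p) write_metrics(m_scale, path_csv = p))
      emit("oc2scale_calibration.json", function(p) {
        jsonlite::write_json(as.list(coef_values(scale_cal)), p,
                             auto_unbox = TRUE, digits = NA)
      })
    }
    results[[alg]] <- list(tuning = tr, metrics = metrics)
  }

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("lakecal")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    counts = counts,
    artifacts = artifacts,
    started = format(t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed ", x$seed, ", ", length(x$artifacts),
      " artifacts\n", sep = "")
  str(x$counts, give.head = FALSE)
  invisible(x)
}

stage_log <- function(stage, alg) {
  message("[", stage, "] ", alg)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  cfg$output_dir <- NULL
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
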
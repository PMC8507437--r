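#' Extract tuning predictor/target pairs from a filtered product table
#'
#' The tuning engine regresses the high-resolution sensor's predictor onto
#' the reference sensor's product:
#' * OCx: `x` = log10 MSI blue:green ratio, `y` = OLCI chl-a;
#' * gilerson: `x` = MSI red-edge:red ratio, `y` = OLCI chl-a;
#' * gons05: `x` = MSI reflectances (b665, b708, b778), `y` = OLCI chl-a;
#' * turbidity: `x` = uncalibrated MSI turbidity, `y` = OLCI turbidity
#'   (fitted with the `"linear"` model);
#' * ratio_scaling: `x` = log10 MSI ratio, `y` = log10 OLCI ratio.
#'
#' @param table A filtered product table from [run_filter_cascade()].
#' @param model Algorithm tag as above.
#' @return List with elements `x`, `y` and `fit_model` (the model tag passed
#'   to [fit_once()]).
#' @export
tuning_data <- function(table, model) {
  switch(model,
    oc2 = ,
    oc3 = list(x = log10(table$ratio_msi), y = table$chla_olci,
               fit_model = model),
    gilerson = list(x = table$ratio_msi, y = table$chla_olci,
                    fit_model = "gilerson"),
    gons05 = list(x = data.frame(b665 = table$rw_msi_b665,
                                 b708 = table$rw_msi_b708,
                                 b778 = table$rw_msi_b778),
                  y = table$chla_olci, fit_model = "gons05"),
    turbidity = list(x = table$turb_msi, y = table$turb_olci,
                     fit_model = "linear"),
    ratio_scaling = list(x = log10(table$ratio_msi),
                         y = log10(table$ratio_olci), fit_model = "linear"),
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

#' Equal-lake-weight bootstrap coefficient tuning
#'
#' Tunes an algorithm's coefficients by repeated robust fits on resampled
#' data in which every lake carries the same weight: each replicate draws
#' `n_per_lake` observations per included lake, at random with replacement,
#' and runs one [fit_once()]. Lakes with fewer unique surviving matches than
#' `min_unique_per_lake` are excluded (a unique match is a distinct
#' (lake, timestamp, lat, lon) row). The per-parameter median over
#' replicates is the tuned coefficient set; the spread (IQR, min, max)
#' quantifies the tuning's dependence on the input data. Fully reproducible
#' from the settings seed: the root seed spawns one recorded substream seed
#' per replicate, and the input table is order-normalised by
#' (lake_id, timestamp, lat, lon) before sampling.
#'
#' @param table Filtered product table (must carry `lake_id`).
#' @param model Algorithm tag (see [tuning_data()]).
#' @param init Initial [coefficient_set] (ignored for `"turbidity"` /
#'   `"ratio_scaling"`, which start from the identity calibration).
#' @param settings A [tuning_settings()].
#' @return A `tuning_result`: list with `samples` (replicate x parameter
#'   matrix), `summary` (tibble: parameter, median, iqr, min, max),
#'   `coefficients` (median coefficient set), `lakes_included`,
#'   `lakes_excluded`, `draws_per_lake`, `draw_counts` (replicate x lake
#'   matrix of realised draws), `n_failed`, `substream_seeds`, `settings`,
#'   `model`.
#' @export
bootstrap_tune <- function(table, model, init = NULL,
                           settings = tuning_settings()) {
  table <- normalize_order(table)
  if (is.null(init)) init <- default_init(model)
  uniq <- lake_unique_counts(table)
  included <- uniq$lake_id[uniq$n_unique >= settings$min_unique_per_lake]
  excluded <- setdiff(uniq$lake_id, included)
  if (length(included) == 0) {
    stop("no lake meets the minimum of ", settings$min_unique_per_lake,
         " unique matches", call. = FALSE)
  }
  lake_rows <- split(seq_len(nrow(table)), table$lake_id)[included]
  td_all <- tuning_data(table, model)
  theta0 <- model_theta(init, td_all$fit_model)
  n_par <- length(theta0)
  set.seed(settings$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, settings$n_replicates)
  samples <- matrix(NA_real_, settings$n_replicates, n_par)
  draw_counts <- matrix(0L, settings$n_replicates, length(included),
                        dimnames = list(NULL, included))
  n_failed <- 0L
  for (r in seq_len(settings$n_replicates)) {
    set.seed(sub_seeds[r])
    idx <- unlist(lapply(lake_rows, function(rows) {
      rows[sample.int(length(rows), settings$n_per_lake, replace = TRUE)]
    }), use.names = FALSE)
    draw_counts[r, ] <- as.integer(table(factor(table$lake_id[idx],
                                                levels = included)))
    td <- subset_tuning_data(td_all, idx)
    if (td$fit_model == "linear") {
      # linear calibrations are fitted by closed-form OLS
      cal <- fit_linear_scaling(td$x, td$y)
      samples[r, ] <- unname(coef_values(cal))
    } else {
      fit <- fit_once(td$x, td$y, td$fit_model, init, settings)
      if (fit$converged) samples[r, ] <- fit$theta
      else n_failed <- n_failed + 1L
    }
  }
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  colnames(samples) <- names(coef_values(init))
  med <- apply(samples, 2, stats::median)
  summary <- tibble::tibble(
    parameter = colnames(samples),
    median = med,
    iqr = apply(samples, 2, stats::IQR, type = 7),
    min = apply(samples, 2, min),
    max = apply(samples, 2, max)
  )
  structure(
    list(samples = samples, summary = summary,
         coefficients = set_coef_values(init, med),
         lakes_included = included, lakes_excluded = excluded,
         draws_per_lake = settings$n_per_lake, draw_counts = draw_counts,
         n_failed = n_failed, substream_seeds = sub_seeds,
         settings = settings, model = model),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> ", x$model, ": ", nrow(x$samples),
      " replicates (", x$n_failed, " failed), ",
      length(x$lakes_included), " lakes included",
      if (length(x$lakes_excluded) > 0)
        paste0(" (", length(x$lakes_excluded), " excluded)"),
      "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Median coefficients of a tuning result
#'
#' @param result A `tuning_result` or `per_lake_result`.
#' @return A [coefficient_set] carrying the per-parameter medians.
#' @export
median_coefficients <- function(result) {
  result$coefficients
}

#' Per-lake coefficient tuning
#'
#' One robust fit per lake on that lake's full surviving data (no
#' bootstrapping — equal weighting is not needed when lakes are fitted
#' separately). Lakes with fewer observations than parameters are skipped
#' with a warning. The summary table reports mean, standard deviation,
#' minimum, median and maximum per parameter across lakes; applying the
#' median-of-per-lake coefficients is supported as an evaluation mode via
#' [median_coefficients()].
#'
#' @inheritParams bootstrap_tune
#' @return A `per_lake_result`: `per_lake` (tibble, one row per lake, wide
#'   parameter columns), `summary` (parameter, mean, sd, min, median, max),
#'   `coefficients` (median-of-per-lake set), `lakes_skipped`.
#' @export
per_lake_tune <- function(table, model, init = NULL,
                          settings = tuning_settings()) {
  table <- normalize_order(table)
  if (is.null(init)) init <- default_init(model)
  td_all <- tuning_data(table, model)
  n_par <- length(model_theta(init, td_all$fit_model))
  lakes <- split(seq_len(nrow(table)), table$lake_id)
  skipped <- character()
  fits <- list()
  for (lk in names(lakes)) {
    idx <- lakes[[lk]]
    if (length(idx) < n_par) {
      skipped <- c(skipped, lk)
      next
    }
    td <- subset_tuning_data(td_all, idx)
    fit <- fit_once(td$x, td$y, td$fit_model, init, settings)
    if (fit$converged) fits[[lk]] <- fit$theta else skipped <- c(skipped, lk)
  }
  if (length(skipped) > 0) {
    warning("lake(s) skipped (too few observations or no convergence): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (length(fits) == 0) stop("no lake could be fitted", call. = FALSE)
  mat <- do.call(rbind, fits)
  colnames(mat) <- names(coef_values(init))
  per_lake <- tibble::as_tibble(mat)
  per_lake <- dplyr::bind_cols(tibble::tibble(lake_id = rownames(mat)),
                               per_lake)
  summary <- tibble::tibble(
    parameter = colnames(mat),
    mean = apply(mat, 2, mean),
    sd = apply(mat, 2, stats::sd),
    min = apply(mat, 2, min),
    median = apply(mat, 2, stats::median),
    max = apply(mat, 2, max)
  )
  structure(
    list(per_lake = per_lake, summary = summary,
         coefficients = set_coef_values(init,
                                        apply(mat, 2, stats::median)),
         lakes_skipped = skipped, settings = settings, model = model),
    class = "per_lake_result"
  )
}

#' @export
print.per_lake_result <- function(x, ...) {
  cat("<per_lake_result> ", x$model, ": ", nrow(x$per_lake), " lakes fitted",
      if (length(x$lakes_skipped) > 0)
        paste0(" (", length(x$lakes_skipped), " skipped)"),
      "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Serialize a tuning result to JSON (and optionally the sample matrix)
#'
#' @param result A `tuning_result`.
#' @param path Output JSON path.
#' @param samples_csv Optional path for the replicate x parameter sample
#'   matrix as CSV.
#' @export
write_tuning_result <- function(result, path, samples_csv = NULL) {
  out <- list(
    model = result$model,
    coefficients = as.list(coef_values(result$coefficients)),
    summary = as.data.frame(result$summary),
    lakes_included = result$lakes_included,
    lakes_excluded = result$lakes_excluded,
    draws_per_lake = result$draws_per_lake,
    n_replicates = result$settings$n_replicates,
    n_failed = result$n_failed,
    seed = result$settings$seed,
    loss = result$settings$loss,
    objective_space = result$settings$objective_space
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(samples_csv)) {
    utils::write.csv(as.data.frame(result$samples), samples_csv,
                     row.names = FALSE)
  }
  invisible(path)
}

# --- internal ---------------------------------------------------------------

normalize_order <- function(table) {
  table <- tibble::as_tibble(table)
  keys <- intersect(c("lake_id", "timestamp", "lat", "lon"), names(table))
  if (length(keys) > 0) table <- dplyr::arrange(table,
                                               dplyr::across(dplyr::all_of(keys)))
  table
}

lake_unique_counts <- function(table) {
  keys <- intersect(c("lake_id", "timestamp", "lat", "lon"), names(table))
  dplyr::summarise(
    dplyr::group_by(dplyr::distinct(table[, keys, drop = FALSE]),
                    .data$lake_id),
    n_unique = dplyr::n(), .groups = "drop")
}

subset_tuning_data <- function(td, idx) {
  list(x = if (is.data.frame(td$x)) td$x[idx, , drop = FALSE] else td$x[idx],
       y = td$y[idx], fit_model = td$fit_model)
}

default_init <- function(model) {
  if (model %in% c("turbidity", "ratio_scaling")) {
    linear_calibration(1, 0)
  } else {
    stop("an initial coefficient set is required for model '", model, "'",
         call. = FALSE)
  }
}
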
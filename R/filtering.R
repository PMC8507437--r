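#' Pixel-level masking of a matchup table
#'
#' Applies, in order, the five pixel-quality masks used to select clear-water
#' matchups free of cloud, land, out-of-scope atmospheric correction and
#' spatial heterogeneity:
#' 1. any MSI cloud/cirrus/shadow/land flag raised, or the MSI clear-water
#'    flag not set;
#' 2. any reflectance value > 1 on either sensor;
#' 3. the atmospheric-correction out-of-bounds flag on either sensor;
#' 4. the reference-sensor snow/ice flag;
#' 5. fewer than five valid neighbours in the 3x3 macro-pixel.
#'
#' Each removal is attributed to the first step that triggers it, so the
#' report's counts telescope exactly.
#'
#' @param table A matchup tibble with flag columns `flag_*`,
#'   `n_valid_neighbours` and per-sensor reflectance columns.
#' @return A list with elements `table` (survivors) and `report`
#'   (a `filter_report` tibble: step, n_in, n_removed, n_out).
#' @export
apply_pixel_masks <- function(table) {
  table <- tibble::as_tibble(table)
  flag_cols <- c("flag_cloud_buffer", "flag_cloud_sure", "flag_cloud",
                 "flag_cloud_ambiguous", "flag_cirrus_sure",
                 "flag_cirrus_ambiguous", "flag_potential_shadow",
                 "flag_land", "flag_clear_water", "flag_out_of_bounds_msi",
                 "flag_out_of_bounds_olci", "flag_snow_ice_olci")
  missing <- setdiff(c(flag_cols, "n_valid_neighbours"), names(table))
  if (length(missing) > 0) {
    stop("matchup table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cloudish <- c("flag_cloud_buffer", "flag_cloud_sure", "flag_cloud",
                "flag_cloud_ambiguous", "flag_cirrus_sure",
                "flag_cirrus_ambiguous", "flag_potential_shadow", "flag_land")
  any_flag <- Reduce(`|`, lapply(cloudish, function(f) table[[f]] == 1))
  rw_all <- as.matrix(table[, intersect(c(rw_cols("msi"), rw_cols("olci")),
                                        names(table))])
  steps <- list(
    cloud_shadow_land_flags = any_flag | table$flag_clear_water != 1,
    reflectance_gt_1 = apply(rw_all > 1, 1, any, na.rm = TRUE),
    out_of_bounds = table$flag_out_of_bounds_msi == 1 |
      table$flag_out_of_bounds_olci == 1,
    snow_ice = table$flag_snow_ice_olci == 1,
    too_few_neighbours = table$n_valid_neighbours < 5
  )
  apply_steps(table, steps)
}

#' Central-99.9% trim of the chlorophyll-a distributions
#'
#' Marks for removal values strictly below the 0.05th percentile or strictly
#' above the 99.95th percentile of each sensor's chl-a distribution
#' (linear-interpolation quantiles), leaving the central 99.9% of data. The
#' number removed per tail is additionally capped at `floor(0.0005 * n)` —
#' "the top and bottom 0.05%" of a sample smaller than 2,000 values is an
#' empty set, so small datasets are untouched. A record is kept only if it
#' is kept under both sensors' trims.
#'
#' @param msi_chla,olci_chla Numeric vectors of per-sensor chl-a
#'   (mg m^-3); `olci_chla` may be `NULL` for a single-sensor trim.
#' @return Logical keep-mask (`NA` inputs are kept by the trim itself; they
#'   are the concern of earlier steps).
#' @export
trim_extreme_chla <- function(msi_chla, olci_chla = NULL) {
  keep_one <- function(v) {
    fin <- is.finite(v)
    n <- sum(fin)
    if (n == 0) {
      warning("no finite chl-a values to trim", call. = FALSE)
      return(rep(FALSE, length(v)))
    }
    cap <- floor(0.0005 * n)
    if (cap == 0) return(rep(TRUE, length(v)))
    q <- stats::quantile(v[fin], c(0.0005, 0.9995), type = 7, names = FALSE)
    keep <- !fin | (v >= q[1] & v <= q[2])
    # cap removals per tail at floor(0.0005 n); drop the most extreme first
    rk <- rank(v, ties.method = "first", na.last = "keep")
    keep[fin & v < q[1] & rk > cap] <- TRUE
    keep[fin & v > q[2] & rk <= n - cap] <- TRUE
    keep
  }
  keep <- keep_one(msi_chla)
  if (!is.null(olci_chla)) keep <- keep & keep_one(olci_chla)
  keep
}

#' Two-standard-deviation filter on MSI chlorophyll-a
#'
#' Removes values strictly more than twice the (sample, n-1 denominator)
#' standard deviation away from the mean of the chl-a dataset; boundary
#' values are retained. A zero-variance dataset retains everything.
#'
#' @param msi_chla Numeric vector of MSI chl-a values.
#' @return Logical keep-mask.
#' @export
sigma_filter_chla <- function(msi_chla) {
  fin <- is.finite(msi_chla)
  if (sum(fin) < 2) return(rep(TRUE, length(msi_chla)))
  m <- mean(msi_chla[fin])
  s <- stats::sd(msi_chla[fin])
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(msi_chla)))
  !fin | abs(msi_chla - m) <= 2 * s
}

#' Per-algorithm range gates
#'
#' Restricts a product table to each algorithm's validated concentration
#' range, using the reference-sensor (OLCI) products for selection plus the
#' stated MSI-side gates:
#' * OC2/OC3: MSI band ratio > 0; OLCI 0.2 < chl-a < 10 mg m^-3, OLCI
#'   turbidity (red-edge band) < 0.5 FNU, OLCI band ratio > 0;
#' * Gilerson: MSI band ratio > 0 and 0 < MSI chl-a < 250;
#'   OLCI 2 < chl-a < 200;
#' * Gons05: 0 < MSI chl-a < 250; OLCI 2 < chl-a < 200;
#' * turbidity: MSI turbidity > 0 and OLCI turbidity > 0.
#'
#' @param table A product table from [retrieve_products()]; the OCx gates
#'   additionally require a column `turb_olci_gate` (OLCI turbidity at the
#'   red-edge band) — [run_filter_cascade()] supplies it.
#' @param algorithm Algorithm tag.
#' @return A list with `table` and `report` as in [apply_pixel_masks()].
#' @export
algorithm_range_filter <- function(table,
                                   algorithm = c("oc2", "oc3", "gilerson",
                                                 "gons05", "turbidity")) {
  algorithm <- match.arg(algorithm)
  table <- tibble::as_tibble(table)
  bad <- function(x) is.na(x) | !x   # gate not provably satisfied -> removed
  steps <- switch(algorithm,
    oc2 = ,
    oc3 = list(
      msi_ratio_gate = bad(table$ratio_msi > 0),
      olci_chla_range = bad(table$chla_olci > 0.2 & table$chla_olci < 10),
      olci_turbidity_gate = bad(table$turb_olci_gate < 0.5),
      olci_ratio_gate = bad(table$ratio_olci > 0)
    ),
    gilerson = list(
      msi_ratio_gate = bad(table$ratio_msi > 0),
      msi_chla_range = bad(table$chla_msi > 0 & table$chla_msi < 250),
      olci_chla_range = bad(table$chla_olci > 2 & table$chla_olci < 200)
    ),
    gons05 = list(
      msi_chla_range = bad(table$chla_msi > 0 & table$chla_msi < 250),
      olci_chla_range = bad(table$chla_olci > 2 & table$chla_olci < 200)
    ),
    turbidity = list(
      msi_turbidity_gate = bad(table$turb_msi > 0),
      olci_turbidity_gate = bad(table$turb_olci > 0)
    )
  )
  apply_steps(table, steps)
}

#' Full matchup filtering cascade
#'
#' Composes, in the fixed order: the five pixel masks, the central-99.9%
#' trim (step 6), the two-standard-deviation filter (step 7, on the MSI
#' product) and the per-algorithm range gates. Steps 6-7 operate on the
#' product of the algorithm being tuned, computed with the `stage`
#' coefficients, over the whole dataset (not per lake). The cascade is
#' deterministic and idempotent, and the report's counts telescope.
#'
#' @inheritParams retrieve_products
#' @param table A raw matchup tibble.
#' @return A list with `table` (the filtered table, product columns
#'   included) and `report` (a `filter_report`).
#' @export
run_filter_cascade <- function(table, algorithm, registry = read_registry(),
                               stage = "initial", nechad = NULL,
                               band = "b708") {
  algorithm <- match.arg(algorithm,
                         c("oc2", "oc3", "gilerson", "gons05", "turbidity"))
  masked <- apply_pixel_masks(table)
  tab <- retrieve_products(masked$table, algorithm, registry = registry,
                           stage = stage, nechad = nechad, band = band)
  if (algorithm %in% c("oc2", "oc3")) {
    # OLCI turbidity at the red-edge band backs the OCx turbidity gate
    sets <- resolve_nechad(nechad, "b708")
    tab$turb_olci_gate <- as.numeric(
      nechad_turbidity(tab$rw_olci_b708, sets$olci))
  }
  prod_msi <- if (algorithm == "turbidity") tab$turb_msi else tab$chla_msi
  prod_olci <- if (algorithm == "turbidity") tab$turb_olci else tab$chla_olci
  steps <- list(
    product_undefined = is.na(prod_msi) | is.na(prod_olci),
    central_999_trim = !trim_extreme_chla(prod_msi, prod_olci),
    two_sigma_filter = !sigma_filter_chla(prod_msi)
  )
  # steps 6-7 must see only rows surviving the preceding step
  stepped <- apply_steps_sequential(tab, steps,
                                    recompute = list(
    central_999_trim = function(t) {
      pm <- if (algorithm == "turbidity") t$turb_msi else t$chla_msi
      po <- if (algorithm == "turbidity") t$turb_olci else t$chla_olci
      !trim_extreme_chla(pm, po)
    },
    two_sigma_filter = function(t) {
      pm <- if (algorithm == "turbidity") t$turb_msi else t$chla_msi
      !sigma_filter_chla(pm)
    }))
  gated <- algorithm_range_filter(stepped$table, algorithm)
  report <- combine_reports(masked$report, stepped$report, gated$report)
  list(table = gated$table, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", x$n_in[1], " -> ", x$n_out[nrow(x)],
      " records\n", sep = "")
  print(tibble::as_tibble(unclass(x)))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(unclass(report)), path, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- internal ---------------------------------------------------------------

# Apply removal masks computed on the full input, attributing each removal to
# the first triggering step.
apply_steps <- function(table, steps) {
  n0 <- nrow(table)
  alive <- rep(TRUE, n0)
  rows <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    remove_i <- steps[[i]] & alive
    remove_i[is.na(remove_i)] <- FALSE
    n_in <- sum(alive)
    alive <- alive & !remove_i
    rows[[i]] <- tibble::tibble(step = names(steps)[i], n_in = n_in,
                                n_removed = sum(remove_i), n_out = sum(alive))
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("filter_report", class(report))
  list(table = table[alive, , drop = FALSE], report = report)
}

# Like apply_steps, but each step's mask is recomputed on the survivors of
# the previous step (needed for data-dependent thresholds like quantiles).
apply_steps_sequential <- function(table, steps, recompute = list()) {
  rows <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    nm <- names(steps)[i]
    mask <- if (!is.null(recompute[[nm]]) && i > 1) {
      recompute[[nm]](table)
    } else {
      steps[[i]]
    }
    mask[is.na(mask)] <- FALSE
    n_in <- nrow(table)
    table <- table[!mask, , drop = FALSE]
    rows[[i]] <- tibble::tibble(step = nm, n_in = n_in,
                                n_removed = sum(mask), n_out = nrow(table))
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("filter_report", class(report))
  list(table = table, report = report)
}

combine_reports <- function(...) {
  report <- dplyr::bind_rows(lapply(list(...), function(r) {
    tibble::as_tibble(unclass(r))
  }))
  class(report) <- c("filter_report", class(report))
  report
}
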
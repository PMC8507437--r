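#' Agreement statistics between two sensors' products
#'
#' With `x` the test sensor (MSI) and `y` the reference sensor (OLCI):
#' * MAD  = mean(|x - y|)                     (product units)
#' * MAPD = 100 * mean(|x - y| / y)           (percent)
#' * RMSD = sqrt(mean((x - y)^2))             (product units)
#' * R    = Pearson correlation
#' * bias = mean(x - y)                       (product units)
#'
#' plus the 5th/50th/95th percentiles of the residual `x - y`
#' (linear-interpolation quantiles), the OLS regression slope of `x` on `y`
#' (in log10 space for chl-a, linear space for turbidity) and `n`. Rows with
#' `y == 0` are excluded from MAPD only, with the exclusion count reported.
#'
#' @param x,y Equal-length numeric vectors (MSI and OLCI products); pairs
#'   with a missing member are dropped.
#' @param kind `"chla"` (slope on log10 scale) or `"turbidity"` (linear).
#' @return A tibble of class `metrics_report` with one row.
#' @export
#' @examples
#' compute_metrics(c(2, 4), c(1, 2), kind = "turbidity")
compute_metrics <- function(x, y, kind = c("chla", "turbidity")) {
  kind <- match.arg(kind)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  nonzero_y <- y != 0
  mapd <- if (any(nonzero_y)) {
    100 * mean(abs(d[nonzero_y]) / y[nonzero_y])
  } else {
    NA_real_
  }
  slope <- if (kind == "chla") {
    pos <- x > 0 & y > 0
    if (sum(pos) >= 2 && stats::sd(log10(y[pos])) > 0) {
      unname(stats::coef(stats::lm(log10(x[pos]) ~ log10(y[pos])))[2])
    } else {
      NA_real_
    }
  } else {
    if (stats::sd(y) > 0) unname(stats::coef(stats::lm(x ~ y))[2]) else NA_real_
  }
  rp <- stats::quantile(d, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  out <- tibble::tibble(
    n = n,
    mad = mean(abs(d)),
    mapd = mapd,
    rmsd = sqrt(mean(d^2)),
    r = if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_,
    bias = mean(d),
    rp5 = rp[1], rp50 = rp[2], rp95 = rp[3],
    slope = slope,
    mapd_excluded = sum(!nonzero_y)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test of equal means, used to ask whether a calibration
#' shifted the product distribution. Delegates to [stats::t.test()]; the
#' degenerate case of two zero-variance samples with equal means returns
#' `t = 0, p = 1` by convention.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level for the rejection flag.
#' @return A list: `t`, `df`, `p`, `reject`, `alpha`.
#' @export
welch_test <- function(sample_a, sample_b, alpha = 0.05) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, df = NA_real_, p = 1, reject = FALSE, alpha = alpha))
    }
    return(list(t = Inf, df = NA_real_, p = 0, reject = TRUE, alpha = alpha))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, reject = ht$p.value < alpha, alpha = alpha)
}

#' Residual summaries by distance to land
#'
#' Bins inter-sensor residuals by each record's distance to the nearest
#' land and summarises each bin, to expose adjacency contamination (which
#' grows toward shore). Also returns a near/far split at a configurable
#' threshold.
#'
#' @param dist_land_km Distances to nearest land (km), aligned with
#'   `residuals`.
#' @param residuals Residuals (MSI - OLCI) in product units.
#' @param breaks Monotone bin edges in km.
#' @param near_threshold_km Threshold for the near/far split (default 5 km).
#' @return List with `bins` (tibble: bin, n, median, p2.5, p97.5,
#'   max_abs) and `split` (tibble with a near and a far row, same columns).
#'   Empty bins are reported with `n = 0`.
#' @export
residuals_by_distance <- function(dist_land_km, residuals,
                                  breaks = c(0, 1, 2, 5, 10, 20, 50, 100),
                                  near_threshold_km = 5) {
  stopifnot(length(dist_land_km) == length(residuals),
            !is.unsorted(breaks, strictly = TRUE))
  ok <- is.finite(dist_land_km) & is.finite(residuals)
  d <- dist_land_km[ok]; r <- residuals[ok]
  bin <- cut(d, breaks, include.lowest = TRUE)
  summarise_group <- function(rr) {
    if (length(rr) == 0) {
      tibble::tibble(n = 0L, median = NA_real_, p2.5 = NA_real_,
                     p97.5 = NA_real_, max_abs = NA_real_)
    } else {
      q <- stats::quantile(rr, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
      tibble::tibble(n = length(rr), median = q[2], p2.5 = q[1], p97.5 = q[3],
                     max_abs = max(abs(rr)))
    }
  }
  bins <- dplyr::bind_rows(lapply(levels(bin), function(lv) {
    dplyr::bind_cols(tibble::tibble(bin = lv),
                     summarise_group(r[!is.na(bin) & bin == lv]))
  }))
  split <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(bin = paste0("<", near_threshold_km, "km")),
                     summarise_group(r[d < near_threshold_km])),
    dplyr::bind_cols(tibble::tibble(bin = paste0(">=", near_threshold_km, "km")),
                     summarise_group(r[d >= near_threshold_km]))
  )
  list(bins = bins, split = split)
}

#' Read optical-water-type reference spectra
#'
#' @param path CSV with a `class_id` column and one column per canonical
#'   band. The package ships a synthetic 13-class fixture
#'   (`extdata/owt_reference_synthetic.csv`) for testing; operational use
#'   expects externally derived cluster spectra.
#' @return A tibble of class `owt_reference`.
#' @export
read_owt_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "owt_reference_synthetic.csv",
                        package = "lakecal")
  }
  ref <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  stopifnot("class_id" %in% names(ref), nrow(ref) >= 2)
  class(ref) <- c("owt_reference", class(ref))
  ref
}

#' Spectral-angle optical water type classification
#'
#' Assigns each reflectance spectrum the reference class minimising the
#' spectral angle `acos(<s, r> / (|s| |r|))`. The angle is invariant under
#' positive scaling of either spectrum, so classification responds to
#' spectral shape, not amplitude.
#'
#' @param spectra Data frame of reflectances on canonical band columns (one
#'   row per observation), or a single named vector.
#' @param references An [read_owt_reference()] table.
#' @return Tibble with `class_id` (dominant class) and `angle` (radians);
#'   zero-norm or incomplete spectra get `NA`.
#' @export
classify_owt <- function(spectra, references = read_owt_reference()) {
  sp <- as_spectrum_frame(spectra)
  bands <- intersect(canonical_bands(), names(references))
  if (length(bands) < 2) stop("references share fewer than 2 bands with the
spectra", call. = FALSE)
  S <- as.matrix(sp[, bands, drop = FALSE])
  R <- as.matrix(references[, bands, drop = FALSE])
  Rn <- R / sqrt(rowSums(R^2))
  Sn_norm <- sqrt(rowSums(S^2))
  cosang <- (S %*% t(Rn)) / Sn_norm
  cosang <- pmin(pmax(cosang, -1), 1)
  ang <- acos(cosang)
  bad <- !is.finite(Sn_norm) | Sn_norm == 0 | apply(!is.finite(S), 1, any)
  idx <- apply(ang, 1, function(a) if (all(is.na(a))) NA_integer_ else which.min(a))
  out <- tibble::tibble(
    class_id = references$class_id[idx],
    angle = ang[cbind(seq_len(nrow(S)), idx)]
  )
  out$class_id[bad] <- NA
  out$angle[bad] <- NA_real_
  out
}

#' Agreement statistics per group
#'
#' Computes one [compute_metrics()] report per group label and, optionally,
#' per declared union of labels (e.g. the clear-water optical types versus
#' all others). Groups with fewer pairs than `min_n` are flagged and get no
#' metrics.
#'
#' @param x,y Product vectors as in [compute_metrics()].
#' @param labels Group label per row.
#' @param label_sets Optional named list of label vectors; each entry yields
#'   an additional pooled report over rows whose label is in the set.
#' @param min_n Minimum complete pairs for a group to be evaluated.
#' @inheritParams compute_metrics
#' @return Tibble with a `group` column, a `flagged` column and the
#'   metric columns (NA when flagged).
#' @export
stratified_metrics <- function(x, y, labels, label_sets = NULL,
                               kind = "chla", min_n = 2) {
  stopifnot(length(labels) == length(x), length(x) == length(y))
  groups <- c(
    stats::setNames(lapply(unique(labels), function(l) which(labels == l)),
                    as.character(unique(labels))),
    lapply(label_sets, function(set) which(labels %in% set))
  )
  dplyr::bind_rows(lapply(names(groups), function(g) {
    idx <- groups[[g]]
    ok <- sum(is.finite(x[idx]) & is.finite(y[idx]))
    if (ok < max(2, min_n)) {
      return(tibble::tibble(group = g, flagged = TRUE, n = ok))
    }
    m <- compute_metrics(x[idx], y[idx], kind = kind)
    dplyr::bind_cols(tibble::tibble(group = g, flagged = FALSE), m)
  }))
}

#' Write a metrics table as CSV and JSON
#'
#' One row per dataset/group with the metric columns, matching the layout of
#' the before/after statistics tables.
#'
#' @param metrics A tibble of metric rows (e.g. from [stratified_metrics()]
#'   or row-bound [compute_metrics()] outputs).
#' @param path_csv,path_json Output paths (either may be `NULL`).
#' @export
write_metrics <- function(metrics, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    utils::write.csv(as.data.frame(metrics), path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(as.data.frame(metrics), path_json, digits = NA,
                         pretty = TRUE)
  }
  invisible(metrics)
}
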
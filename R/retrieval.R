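#' Band ratios for the chlorophyll-a algorithms
#'
#' Computes the predictor used by each chlorophyll-a retrieval family:
#' * `"oc2"` — log10 of the blue:green ratio `Rw490 / Rw560`;
#' * `"oc3"` — log10 of `max(Rw443, Rw490) / Rw560`;
#' * `"nir_red"` — the plain red-edge:red ratio `Rw708 / Rw665`.
#'
#' Invalid inputs (missing bands, non-positive denominators, non-positive
#' ratios under the logarithm) yield `NA` with an enumerated reason, never an
#' error, so that bulk table processing can tally rejections.
#'
#' @param spectrum A data frame of reflectances with canonical band columns
#'   (`b443`, `b490`, ... — see [canonical_bands()]), or a named numeric
#'   vector for a single spectrum. Values are dimensionless normalized
#'   water-leaving reflectance.
#' @param kind `"oc2"`, `"oc3"` or `"nir_red"`.
#' @return Numeric vector of ratios (log10 ratios for OC2/OC3) with a
#'   `"reason"` attribute: character vector, `NA` where the value is valid.
#' @export
#' @examples
#' band_ratio(c(b490 = 0.02, b560 = 0.01), "oc2")   # log10(2)
#' band_ratio(c(b665 = 0.004, b708 = 0.005), "nir_red")
band_ratio <- function(spectrum, kind = c("oc2", "oc3", "nir_red")) {
  kind <- match.arg(kind)
  sp <- as_spectrum_frame(spectrum)
  n <- nrow(sp)
  reason <- rep(NA_character_, n)
  if (kind == "nir_red") {
    num <- sp$b708
    den <- sp$b665
    bad_missing <- is.na(num) | is.na(den)
    bad_den <- !bad_missing & den <= 0
    val <- ifelse(bad_missing | bad_den, NA_real_, num / den)
    reason[bad_missing] <- "missing_band"
    reason[bad_den] <- "nonpositive_denominator"
  } else {
    num <- if (kind == "oc2") sp$b490 else pmax(sp$b443, sp$b490)
    den <- sp$b560
    bad_missing <- is.na(num) | is.na(den)
    bad_den <- !bad_missing & den <= 0
    lin <- ifelse(bad_missing | bad_den, NA_real_, num / den)
    bad_ratio <- !is.na(lin) & lin <= 0
    val <- ifelse(is.na(lin) | bad_ratio, NA_real_, log10(lin))
    reason[bad_missing] <- "missing_band"
    reason[bad_den] <- "nonpositive_denominator"
    reason[bad_ratio] <- "nonpositive_ratio"
  }
  with_reason(val, reason)
}

#' Ocean-chlorophyll (OCx) polynomial retrieval
#'
#' `chla = 10 ^ (a0 + a1 x + a2 x^2 + a3 x^3 + a4 x^4)` with `x` the log10
#' blue:green band ratio. Strictly positive for any finite `x`.
#'
#' @param x Numeric vector of log10 band ratios (from [band_ratio()]).
#' @param coeffs An [ocx_coefficients()] set.
#' @return Chlorophyll-a in mg m^-3; `NA` propagates.
#' @export
#' @examples
#' msi_oc2 <- ocx_coefficients(0.2389, -1.9369, 1.7627, -3.0777, -0.1054)
#' ocx_chla(0, msi_oc2)   # 10^0.2389
ocx_chla <- function(x, coeffs) {
  stopifnot(inherits(coeffs, "ocx_coefficients"))
  a <- coef_values(coeffs)
  10^(a[["a0"]] + a[["a1"]] * x + a[["a2"]] * x^2 +
        a[["a3"]] * x^3 + a[["a4"]] * x^4)
}

#' NIR-red ratio power-law chlorophyll-a retrieval
#'
#' `chla = (a x + b)^c` with `x = Rw708 / Rw665` and `b` stored signed
#' (the published coefficient set reads `(35.75 x - 19.30)^1.124`). Defined
#' only where the base `a x + b` is positive; elsewhere `NA` with reason
#' `"nonpositive_base"`.
#'
#' @param ratio Numeric vector of red-edge:red ratios.
#' @param coeffs A [gilerson_coefficients()] set.
#' @return Chlorophyll-a in mg m^-3 with a `"reason"` attribute.
#' @export
gilerson_chla <- function(ratio, coeffs) {
  stopifnot(inherits(coeffs, "gilerson_coefficients"))
  k <- coef_values(coeffs)
  base <- k[["a"]] * ratio + k[["b"]]
  bad <- !is.na(base) & base <= 0
  val <- ifelse(is.na(base) | bad, NA_real_, base^k[["c"]])
  reason <- rep(NA_character_, length(ratio))
  reason[is.na(ratio)] <- "missing_input"
  reason[bad] <- "nonpositive_base"
  with_reason(val, reason)
}

#' NIR backscattering coefficient inversion
#'
#' `bb = k_scatter * aw779 * Rw779 / (k_gamma - k_scatter * Rw779)` with the
#' conventional constants `k_scatter = 0.6`, `k_gamma = 0.082`. Valid for
#' `0 <= Rw779 < k_gamma / k_scatter`; the denominator going non-positive
#' yields `NA` with reason `"bb_domain"`.
#'
#' @param rw779 NIR reflectance (canonical band `b778`).
#' @param coeffs A [gons_coefficients()] set (supplies `aw779` and the
#'   inversion constants).
#' @return Backscattering coefficient in m^-1 with a `"reason"` attribute.
#' @export
gons_backscatter <- function(rw779, coeffs) {
  stopifnot(inherits(coeffs, "gons_coefficients"))
  den <- coeffs$k_gamma - coeffs$k_scatter * rw779
  bad <- !is.na(rw779) & (den <= 0 | rw779 < 0)
  val <- ifelse(is.na(rw779) | bad, NA_real_,
                coeffs$k_scatter * coeffs$aw[["aw779"]] * rw779 / den)
  reason <- rep(NA_character_, length(rw779))
  reason[is.na(rw779)] <- "missing_input"
  reason[bad] <- "bb_domain"
  with_reason(val, reason)
}

#' Semi-analytical red/NIR chlorophyll-a retrieval
#'
#' `chla = ((Rw708/Rw665) * (aw709 + bb) - aw665 - bb^p) / a_chl_star`,
#' with `bb` from [gons_backscatter()]. The result may be negative for weak
#' red-edge signals; it is returned as computed and left to the downstream
#' per-algorithm range gates.
#'
#' @param rw665,rw708,rw779 Reflectances at the red, red-edge and NIR bands.
#' @param coeffs A [gons_coefficients()] set.
#' @return Chlorophyll-a in mg m^-3 with a `"reason"` attribute.
#' @export
gons_chla <- function(rw665, rw708, rw779, coeffs) {
  stopifnot(inherits(coeffs, "gons_coefficients"))
  bb <- gons_backscatter(rw779, coeffs)
  bb_reason <- attr(bb, "reason")
  k <- coef_values(coeffs)
  bad_665 <- !is.na(rw665) & rw665 <= 0
  ratio <- ifelse(is.na(rw665) | bad_665 | is.na(rw708), NA_real_,
                  rw708 / rw665)
  val <- (ratio * (coeffs$aw[["aw709"]] + bb) - coeffs$aw[["aw665"]] -
            as.numeric(bb)^k[["p"]]) / k[["a_chl_star"]]
  reason <- rep(NA_character_, length(val))
  reason[is.na(rw665) | is.na(rw708)] <- "missing_input"
  reason[!is.na(bb_reason)] <- bb_reason[!is.na(bb_reason)]
  reason[bad_665] <- "nonpositive_denominator"
  val[!is.na(reason)] <- NA_real_
  with_reason(val, reason)
}

#' Single-band turbidity retrieval
#'
#' `T = A_t * Rw / (1 - Rw / C_t)`, zero at zero reflectance and strictly
#' increasing on `[0, C_t)`. Reflectance at or above the asymptote `C_t`, or
#' negative reflectance, yields `NA` with reason `"rw_out_of_domain"`.
#'
#' @param rw Reflectance at the configured band.
#' @param coeffs A [nechad_coefficients()] set.
#' @return Turbidity in FNU with a `"reason"` attribute.
#' @export
#' @examples
#' nb <- nechad_coefficients(300, 0.2, band = "b665")
#' nechad_turbidity(0.1, nb)   # 60 FNU
nechad_turbidity <- function(rw, coeffs) {
  stopifnot(inherits(coeffs, "nechad_coefficients"))
  k <- coef_values(coeffs)
  bad <- !is.na(rw) & (rw < 0 | rw >= k[["C_t"]])
  val <- ifelse(is.na(rw) | bad, NA_real_,
                k[["A_t"]] * rw / (1 - rw / k[["C_t"]]))
  reason <- rep(NA_character_, length(rw))
  reason[is.na(rw)] <- "missing_input"
  reason[bad] <- "rw_out_of_domain"
  with_reason(val, reason)
}

#' Apply a linear calibration
#'
#' `gain * value + offset`; used both for the tuned turbidity
#' (`T_t = a T + b`) and for the band-ratio linear scaling alternative.
#'
#' @param value Numeric vector in the units of the calibrated quantity.
#' @param cal A [linear_calibration()].
#' @return Calibrated values, same units.
#' @export
apply_linear_calibration <- function(value, cal) {
  stopifnot(inherits(cal, "linear_calibration"))
  k <- coef_values(cal)
  k[["gain"]] * value + k[["offset"]]
}

#' Add per-sensor product columns to a matchup table
#'
#' Applies one retrieval algorithm to both sensors of a matchup table,
#' appending product and predictor columns:
#' * chl-a algorithms (`"oc2"`, `"oc3"`, `"gilerson"`, `"gons05"`): columns
#'   `chla_msi`, `chla_olci` and the linear band ratios `ratio_msi`,
#'   `ratio_olci` (blue:green for OCx, red-edge:red otherwise);
#' * `"turbidity"`: columns `turb_msi`, `turb_olci` at the requested band
#'   (requires `nechad` coefficient sets).
#'
#' Rows whose inputs fall outside an algorithm's domain get `NA` products;
#' the per-reason tallies are attached and retrievable with
#' [rejection_report()]. Row count is never changed.
#'
#' @param table A matchup tibble (see [read_matchups()] for the schema).
#' @param algorithm Algorithm tag.
#' @param registry A coefficient registry from [read_registry()]; used for
#'   the chl-a algorithms.
#' @param stage Registry stage for the MSI coefficients (`"initial"` or
#'   `"tuned"`); the reference sensor always uses its initial sets.
#' @param nechad For `"turbidity"`: named list with `msi` and `olci`
#'   [nechad_coefficients()] entries, or a path to a per-band JSON table
#'   readable by [read_nechad_coefficients()].
#' @param band Canonical band for the turbidity retrieval.
#' @param msi_ratio_scaling Optional [linear_calibration()] applied to the
#'   MSI band ratio before the MSI retrieval (the linear band-ratio scaling
#'   alternative; use together with `stage` pointing at the reference
#'   coefficients via `msi_coefficients`).
#' @param msi_coefficients Optional explicit [coefficient_set] overriding the
#'   registry lookup for the MSI retrieval (e.g. reference-sensor
#'   coefficients for the scaled-ratio pathway, or a freshly tuned set).
#' @return The input tibble with product columns appended and a
#'   `"rejections"` attribute.
#' @export
retrieve_products <- function(table, algorithm, registry = read_registry(),
                              stage = "initial", nechad = NULL,
                              band = "b708", msi_ratio_scaling = NULL,
                              msi_coefficients = NULL) {
  algorithm <- match.arg(algorithm,
                         c("oc2", "oc3", "gilerson", "gons05", "turbidity"))
  table <- tibble::as_tibble(table)
  reasons <- list()
  if (algorithm == "turbidity") {
    sets <- resolve_nechad(nechad, band)
    for (sensor in c("msi", "olci")) {
      rw <- table[[paste0("rw_", sensor, "_", band)]]
      if (is.null(rw)) stop("matchup table lacks column rw_", sensor, "_", band,
                            call. = FALSE)
      v <- nechad_turbidity(rw, sets[[sensor]])
      table[[paste0("turb_", sensor)]] <- as.numeric(v)
      reasons[[sensor]] <- attr(v, "reason")
    }
  } else {
    ratio_kind <- if (algorithm %in% c("oc2", "oc3")) algorithm else "nir_red"
    for (sensor in c("msi", "olci")) {
      sp <- sensor_spectra(table, sensor)
      coeffs <- if (sensor == "msi" && !is.null(msi_coefficients)) {
        msi_coefficients
      } else {
        registry_coefficients(registry, sensor,
                              algorithm,
                              stage = if (sensor == "msi") stage else "initial")
      }
      r <- band_ratio(sp, ratio_kind)
      x <- as.numeric(r)
      if (sensor == "msi" && !is.null(msi_ratio_scaling)) {
        x <- apply_linear_calibration(x, msi_ratio_scaling)
      }
      prod <- switch(algorithm,
        oc2 = ,
        oc3 = with_reason(ocx_chla(x, coeffs), attr(r, "reason")),
        gilerson = {
          g <- gilerson_chla(x, coeffs)
          with_reason(as.numeric(g),
                      dplyr::coalesce(attr(r, "reason"), attr(g, "reason")))
        },
        gons05 = {
          g <- gons_chla(sp$b665, sp$b708, sp$b778, coeffs)
          g
        })
      # linear ratio column used by the per-algorithm range gates
      table[[paste0("ratio_", sensor)]] <- if (ratio_kind == "nir_red") {
        x
      } else {
        ifelse(is.na(x), NA_real_, 10^x)
      }
      table[[paste0("chla_", sensor)]] <- as.numeric(prod)
      reasons[[sensor]] <- attr(prod, "reason")
    }
  }
  attr(table, "rejections") <- tally_reasons(reasons)
  table
}

#' Rejection tallies of the last retrieval
#'
#' @param table A table returned by [retrieve_products()].
#' @return A tibble with columns `sensor`, `reason`, `n`.
#' @export
rejection_report <- function(table) {
  rep <- attr(table, "rejections")
  if (is.null(rep)) {
    tibble::tibble(sensor = character(), reason = character(), n = integer())
  } else {
    rep
  }
}

# --- internal helpers -------------------------------------------------------

as_spectrum_frame <- function(spectrum) {
  if (is.numeric(spectrum) && !is.null(names(spectrum))) {
    spectrum <- tibble::as_tibble(as.list(spectrum))
  }
  spectrum <- tibble::as_tibble(spectrum)
  for (b in canonical_bands()) {
    if (is.null(spectrum[[b]])) spectrum[[b]] <- NA_real_
  }
  spectrum
}

sensor_spectra <- function(table, sensor) {
  cols <- rw_cols(sensor)
  out <- tibble::tibble(.rows = nrow(table))
  for (i in seq_along(cols)) {
    out[[canonical_bands()[i]]] <-
      if (is.null(table[[cols[i]]])) NA_real_ else table[[cols[i]]]
  }
  out
}

with_reason <- function(value, reason) {
  attr(value, "reason") <- reason
  value
}

tally_reasons <- function(reasons) {
  out <- lapply(names(reasons), function(sensor) {
    r <- reasons[[sensor]]
    r <- r[!is.na(r)]
    if (length(r) == 0) return(NULL)
    tab <- table(r)
    tibble::tibble(sensor = sensor, reason = names(tab),
                   n = as.integer(tab))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    tibble::tibble(sensor = character(), reason = character(), n = integer())
  } else {
    out
  }
}

resolve_nechad <- function(nechad, band) {
  if (is.null(nechad)) {
    stop("turbidity retrieval requires Nechad A/C coefficients; ",
         "pass 'nechad' as a list(msi=, olci=) or a JSON path (no defaults)",
         call. = FALSE)
  }
  if (is.character(nechad)) {
    list(msi = read_nechad_coefficients(nechad, "msi", band),
         olci = read_nechad_coefficients(nechad, "olci", band))
  } else {
    stopifnot(inherits(nechad$msi, "nechad_coefficients"),
              inherits(nechad$olci, "nechad_coefficients"))
    nechad
  }
}
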
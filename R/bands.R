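#' Canonical waveband labels
#'
#' All reflectance handling in lakecal happens on a canonical band grid. The
#' two sensors place their red-edge and NIR channels at slightly different
#' centre wavelengths (705 vs 708.75 nm, 783 vs 778.75 nm); published
#' algorithm formulations additionally quote 709 and 779 nm. These are the
#' same physical channels for the purpose of cross-sensor alignment, so they
#' collapse onto single labels (`b708`, `b778`). The mapping is exposed via
#' [band_map()] so a run can log exactly which nominal wavelengths each label
#' absorbed.
#'
#' @return Character vector of the seven canonical band labels.
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  c("b443", "b490", "b560", "b665", "b708", "b778", "b865")
}

#' Nominal wavelength to canonical label mapping
#'
#' @return A tibble with columns `nominal_nm` (as quoted in algorithm
#'   definitions or sensor band tables) and `band` (canonical label).
#' @export
#' @examples
#' band_map()
band_map <- function() {
  tibble::tibble(
    nominal_nm = c(443, 490, 560, 665, 705, 708, 708.75, 709,
                   778, 778.75, 779, 783, 865),
    band = c("b443", "b490", "b560", "b665", "b708", "b708", "b708", "b708",
             "b778", "b778", "b778", "b778", "b865")
  )
}

#' Resolve a wavelength to its canonical band label
#'
#' @param nm Numeric vector of nominal wavelengths in nanometres.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' band_label(c(705, 709, 783))
band_label <- function(nm) {
  map <- band_map()
  idx <- match(nm, map$nominal_nm)
  if (anyNA(idx)) {
    stop("no canonical band for wavelength(s): ",
         paste(nm[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  map$band[idx]
}

# Column names for a sensor's reflectances in a matchup table.
rw_cols <- function(sensor, bands = canonical_bands()) {
  paste0("rw_", sensor, "_", bands)
}
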
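#' Coefficient set constructors
#'
#' Each retrieval algorithm carries a small named coefficient set. These
#' constructors validate the invariants of each family and return a classed
#' list so that tuning and retrieval code can dispatch on the algorithm.
#'
#' @param a0,a1,a2,a3,a4 Polynomial coefficients of the ocean-chlorophyll
#'   (OCx) log-ratio polynomial, dimensionless.
#' @param sensor Optional sensor tag (e.g. `"msi"`, `"olci"`).
#' @param algorithm For OCx sets, `"oc2"` or `"oc3"`.
#' @return An object of class `coefficient_set` (subclassed per family).
#' @name coefficient_sets
NULL

#' @rdname coefficient_sets
#' @export
ocx_coefficients <- function(a0, a1, a2, a3, a4, algorithm = "oc2",
                             sensor = NULL) {
  vals <- c(a0 = a0, a1 = a1, a2 = a2, a3 = a3, a4 = a4)
  if (length(vals) != 5L || !all(is.finite(vals))) {
    stop("OCx coefficient sets require exactly five finite coefficients",
         call. = FALSE)
  }
  algorithm <- match.arg(algorithm, c("oc2", "oc3"))
  structure(
    list(coefficients = vals, algorithm = algorithm, sensor = sensor),
    class = c("ocx_coefficients", "coefficient_set")
  )
}

#' @rdname coefficient_sets
#' @param a,b,c NIR-red ratio power-law parameters. The retrieval is
#'   `(a * x + b)^c` with `b` stored signed, so the published form
#'   `(35.75 x - 19.30)^1.124` is entered as `a = 35.75, b = -19.30`.
#' @export
gilerson_coefficients <- function(a, b, c, sensor = NULL) {
  if (!is.finite(a) || a == 0) stop("'a' must be finite and nonzero", call. = FALSE)
  if (!is.finite(c) || c <= 0) stop("'c' must be positive", call. = FALSE)
  structure(
    list(coefficients = c(a = a, b = b, c = c), sensor = sensor),
    class = c("gilerson_coefficients", "coefficient_set")
  )
}

#' @rdname coefficient_sets
#' @param p Exponent applied to the backscattering coefficient, dimensionless.
#' @param a_chl_star Chlorophyll-a specific absorption at 665 nm (m^2 mg^-1).
#' @param aw665,aw709,aw779 Pure-water absorption (m^-1) at the red, red-edge
#'   and NIR wavelengths. The defaults follow the semi-analytical algorithm's
#'   source formulation and are configurable; results should always be
#'   reported together with the water-absorption set used.
#' @param k_scatter,k_gamma Constants of the NIR backscatter inversion
#'   `bb = k_scatter * aw779 * Rw779 / (k_gamma - k_scatter * Rw779)`.
#' @export
gons_coefficients <- function(p, a_chl_star,
                              aw665 = 0.40, aw709 = 0.70, aw779 = 2.71,
                              k_scatter = 0.6, k_gamma = 0.082,
                              sensor = NULL) {
  if (!is.finite(a_chl_star) || a_chl_star <= 0) {
    stop("'a_chl_star' must be positive", call. = FALSE)
  }
  aw <- c(aw665 = aw665, aw709 = aw709, aw779 = aw779)
  if (!all(is.finite(aw)) || any(aw <= 0)) {
    stop("pure-water absorption values must be positive", call. = FALSE)
  }
  structure(
    list(coefficients = c(p = p, a_chl_star = a_chl_star),
         aw = aw, k_scatter = k_scatter, k_gamma = k_gamma, sensor = sensor),
    class = c("gons_coefficients", "coefficient_set")
  )
}

#' @rdname coefficient_sets
#' @param A_t Amplitude of the single-band turbidity model (FNU).
#' @param C_t Reflectance asymptote of the model, in (0, 1).
#' @param band Canonical band label the pair applies to.
#' @export
nechad_coefficients <- function(A_t, C_t, band, sensor = NULL) {
  if (!is.finite(A_t) || A_t <= 0) stop("'A_t' must be positive", call. = FALSE)
  if (!is.finite(C_t) || C_t <= 0 || C_t >= 1) {
    stop("'C_t' must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(band %in% canonical_bands())
  structure(
    list(coefficients = c(A_t = A_t, C_t = C_t), band = band, sensor = sensor),
    class = c("nechad_coefficients", "coefficient_set")
  )
}

#' @rdname coefficient_sets
#' @param gain,offset Gain and offset of a linear calibration
#'   `y = gain * x + offset`. Units of the offset follow the calibrated
#'   quantity (FNU for turbidity, dimensionless for a band-ratio scaling).
#' @export
linear_calibration <- function(gain, offset = 0, sensor = NULL) {
  if (!is.finite(gain) || gain == 0) {
    stop("'gain' must be finite and nonzero", call. = FALSE)
  }
  structure(
    list(coefficients = c(gain = gain, offset = offset), sensor = sensor),
    class = c("linear_calibration", "coefficient_set")
  )
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<", class(x)[1], ">", if (!is.null(x$sensor)) paste0(" [", x$sensor, "]"),
      "\n", sep = "")
  print(x$coefficients)
  if (!is.null(x$aw)) {
    cat("pure-water absorption (m^-1):\n")
    print(x$aw)
  }
  invisible(x)
}

# Named numeric vector of the tunable parameters of a set.
coef_values <- function(set) set$coefficients

# Rebuild a coefficient set of the same family with new parameter values.
set_coef_values <- function(set, values) {
  stopifnot(length(values) == length(set$coefficients))
  set$coefficients[] <- values
  set
}

#' Read and write a coefficient registry
#'
#' A registry is a JSON document keyed as
#' `section -> sensor -> algorithm -> coefficient names`. The package ships
#' one at `system.file("extdata", "coefficients.json", package = "lakecal")`
#' holding, for both sensors, the published pre-tuning chlorophyll-a
#' coefficient sets, the bootstrap-tuned high-resolution-sensor sets, the
#' per-band turbidity linear calibrations and the band-ratio linear scaling.
#' Values round-trip through [write_registry()] at full double precision.
#'
#' @param path Path to a registry JSON file; `read_registry()` defaults to
#'   the bundled registry.
#' @return For `read_registry()`, a nested list of class `coef_registry`.
#' @export
read_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "coefficients.json", package = "lakecal")
  }
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(reg, class = "coef_registry")
}

#' @rdname read_registry
#' @param registry A `coef_registry` (nested list).
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(unclass(registry), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Fetch one coefficient set from a registry
#'
#' @param registry A registry as returned by [read_registry()].
#' @param sensor `"msi"` or `"olci"` (or any sensor key present).
#' @param algorithm One of `"oc2"`, `"oc3"`, `"gilerson"`, `"gons05"`.
#' @param stage `"initial"` or `"tuned"`.
#' @return A `coefficient_set` of the matching family.
#' @export
#' @examples
#' reg <- read_registry()
#' registry_coefficients(reg, "msi", "oc2", stage = "initial")
registry_coefficients <- function(registry, sensor, algorithm,
                                  stage = "initial") {
  node <- registry[[stage]][[sensor]][[algorithm]]
  if (is.null(node)) {
    stop("registry has no '", stage, "/", sensor, "/", algorithm,
         "' coefficient set", call. = FALSE)
  }
  switch(algorithm,
    oc2 = ,
    oc3 = ocx_coefficients(node$a0, node$a1, node$a2, node$a3, node$a4,
                           algorithm = algorithm, sensor = sensor),
    gilerson = gilerson_coefficients(node$a, node$b, node$c, sensor = sensor),
    gons05 = {
      args <- list(p = node$p, a_chl_star = node$a_chl_star, sensor = sensor)
      for (nm in c("aw665", "aw709", "aw779")) {
        if (!is.null(node[[nm]])) args[[nm]] <- node[[nm]]
      }
      do.call(gons_coefficients, args)
    },
    stop("unknown algorithm '", algorithm, "'", call. = FALSE)
  )
}

#' Fetch a turbidity (or ratio) linear calibration from a registry
#'
#' @inheritParams registry_coefficients
#' @param band Canonical band label for turbidity calibrations, or the
#'   ratio kind (`"oc2"`) for the band-ratio scaling section.
#' @param section `"turbidity_calibration"` or `"ratio_scaling"`.
#' @return A `linear_calibration`.
#' @export
registry_calibration <- function(registry, sensor, band,
                                 section = "turbidity_calibration") {
  node <- if (section == "ratio_scaling") {
    registry[[section]][[band]]
  } else {
    registry[[section]][[sensor]][[band]]
  }
  if (is.null(node)) {
    stop("registry has no '", section, "' entry for ", sensor, "/", band,
         call. = FALSE)
  }
  linear_calibration(node$gain, node$offset, sensor = sensor)
}

#' Read Nechad turbidity coefficients per band
#'
#' The per-band amplitude/asymptote pairs of the single-band turbidity model
#' are calibration inputs, not tuned by this package, and must be supplied by
#' the user. There are no silent defaults; a synthetic fixture set for
#' testing ships as `extdata/nechad_coefficients_synthetic.json`.
#'
#' @param path JSON file keyed `sensor -> band -> {A_t, C_t}`.
#' @param sensor,band Selection keys.
#' @return A `nechad_coefficients` set.
#' @export
read_nechad_coefficients <- function(path, sensor, band) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  node <- tab[[sensor]][[band]]
  if (is.null(node)) {
    stop("no Nechad A/C pair for ", sensor, "/", band, " in ", path,
         call. = FALSE)
  }
  nechad_coefficients(node$A_t, node$C_t, band = band, sensor = sensor)
}
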
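#' Configuration of the synthetic paired-sensor matchup generator
#'
#' Describes the statistical structure the generator emulates: a set of
#' lakes with heavily skewed observation counts and lake-specific
#' log-normal chlorophyll-a, a low-skewed turbidity regime (about 80% of
#' records below 5 FNU under the defaults), a near-linear inter-sensor
#' band-ratio distortion, positively skewed blue-green reflectance in the
#' high-resolution sensor, adjacency noise growing toward land, and
#' stochastic quality-flag contamination.
#'
#' The default distortions are chosen so that regressing the reference
#' ratio on the distorted one recovers the published blue-green scaling
#' `y = 1.442 x - 0.51`: the generator maps the reference log-ratio through
#' the inverse of that line.
#'
#' @param lakes Tibble with columns `lake_id`, `n_obs`, `chla_meanlog`,
#'   `chla_sdlog`, `turb_meanlog`, `turb_sdlog`, `dominant_owt`. The default
#'   ladder of 20 lakes spans two decades of per-lake counts.
#' @param distortion List of [linear_calibration()]s applied to the
#'   reference predictor to produce the MSI predictor: `oc2` (log-ratio
#'   space, shared by OC3), `nir_red` (ratio space) and `red_nir_amplitude`
#'   (multiplicative gain on the MSI red/NIR bands, driving the turbidity
#'   misalignment).
#' @param ratio_noise_sd Named vector: Gaussian noise added to the MSI
#'   predictor (`oc2` in log-ratio units, `nir_red` in ratio units).
#' @param bluegreen_skew `c(meanlog, sdlog)` of the common multiplicative
#'   log-normal factor on the MSI blue-green bands (mean > 1 reproduces the
#'   positive skew of the high-resolution sensor's blue-green reflectance).
#' @param adjacency `c(amplitude, efold_km)`: multiplicative perturbation of
#'   MSI bands with standard deviation `amplitude * exp(-dist / efold_km)`.
#' @param adjacency_weights Per-band multipliers of the adjacency amplitude.
#' @param rw_noise_sd Relative Gaussian noise on each MSI band.
#' @param flag_probs Named vector of Bernoulli contamination probabilities
#'   for the quality flags.
#' @param neighbour_probs Probabilities for `n_valid_neighbours = 0..8`.
#' @param dist_range_km Range of the log-uniform distance-to-land draw.
#' @param ocx_bracket Log-ratio bracket of the monotone OCx inversion
#'   branch; chl-a outside the branch's image is clamped to it (the
#'   blue-green algorithms genuinely saturate outside their range).
#' @param nechad Per-band Nechad A/C table path or list used to invert
#'   turbidity to NIR reflectance (and by downstream retrieval); defaults to
#'   the bundled synthetic fixture.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(lakes = default_lakes(),
                             distortion = list(
                               oc2 = linear_calibration(1 / 1.442,
                                                        0.51 / 1.442),
                               nir_red = linear_calibration(0.95, 0.01),
                               red_nir_amplitude = linear_calibration(1.15, 0)
                             ),
                             ratio_noise_sd = c(oc2 = 0.03, nir_red = 0.02),
                             bluegreen_skew = c(meanlog = 0.05, sdlog = 0.10),
                             adjacency = c(amplitude = 0.25, efold_km = 2),
                             adjacency_weights = c(b443 = 1, b490 = 1,
                                                   b560 = 1, b665 = 1,
                                                   b708 = 1, b778 = 1,
                                                   b865 = 1),
                             rw_noise_sd = 0.01,
                             flag_probs = c(cloud = 0.02, cloud_sure = 0.01,
                                            cirrus = 0.01, shadow = 0.01,
                                            land = 0.005,
                                            out_of_bounds = 0.01,
                                            snow_ice = 0.005,
                                            not_clear_water = 0.02),
                             neighbour_probs = c(0.005, 0.005, 0.005, 0.005,
                                                 0.01, 0.02, 0.05, 0.10,
                                                 0.80),
                             dist_range_km = c(0.1, 100),
                             ocx_bracket = c(-0.4, 0.8),
                             nechad = NULL,
                             seed = 1L) {
  stopifnot(all(lakes$n_obs >= 0), all(flag_probs >= 0 & flag_probs <= 1),
            adjacency[["efold_km"]] > 0, rw_noise_sd >= 0,
            abs(sum(neighbour_probs) - 1) < 1e-8)
  if (is.null(nechad)) {
    nechad <- system.file("extdata", "nechad_coefficients_synthetic.json",
                          package = "lakecal")
  }
  structure(
    list(lakes = tibble::as_tibble(lakes), distortion = distortion,
         ratio_noise_sd = ratio_noise_sd, bluegreen_skew = bluegreen_skew,
         adjacency = adjacency, adjacency_weights = adjacency_weights,
         rw_noise_sd = rw_noise_sd, flag_probs = flag_probs,
         neighbour_probs = neighbour_probs, dist_range_km = dist_range_km,
         ocx_bracket = ocx_bracket, nechad = nechad,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default synthetic lake set
#'
#' Twenty lakes with per-lake observation counts on a geometric ladder
#' (46 up to about 47,000) emulating the heavy skew of real archives, and
#' lake-specific chl-a log-normals spanning roughly 0.2-200 mg m^-3
#' overall; the largest lakes are the clearest, which is what funnels the
#' blue-green algorithms' filtered datasets toward large clear lakes.
#' Turbidity is log-normal with meanlog 0.55 and sdlog 1.25, placing about
#' 80% of records below 5 FNU.
#'
#' @param n_lakes Number of lakes.
#' @param n_min,n_max Smallest and largest per-lake counts of the ladder.
#' @return Tibble usable as the `lakes` field of [synthetic_config()].
#' @export
default_lakes <- function(n_lakes = 20, n_min = 46, n_max = 47000) {
  tibble::tibble(
    lake_id = sprintf("lake%02d", seq_len(n_lakes)),
    n_obs = round(exp(seq(log(n_min), log(n_max),
                          length.out = n_lakes))),
    chla_meanlog = seq(log(40), log(0.8), length.out = n_lakes),
    chla_sdlog = rep(0.8, n_lakes),
    turb_meanlog = rep(0.55, n_lakes),
    turb_sdlog = rep(1.25, n_lakes),
    dominant_owt = rep_len(c(3, 9, 13, 2, 4, 6, 11), n_lakes)
  )
}

#' Invert a retrieval algorithm to its predictor or band value
#'
#' Exact inverses used by the generator to manufacture reference-sensor
#' reflectances whose forward retrieval reproduces the true concentrations:
#' * `"oc2"` / `"oc3"`: the log10 band ratio solving the quartic
#'   `poly(x) = log10(chla)` on the monotone branch inside `bracket`
#'   (bracketed numeric root-finding);
#' * `"gilerson"`: closed form `x = (chla^(1/c) - b) / a`;
#' * `"turbidity"`: closed form `rw = T / (A_t + T / C_t)`.
#'
#' @param value True chl-a (mg m^-3) or turbidity (FNU).
#' @param algorithm Tag as above.
#' @param coeffs Matching [coefficient_set].
#' @param bracket Log-ratio bracket for the OCx branch.
#' @return Predictor (log10 ratio, ratio) or reflectance; errors if the
#'   truth lies outside the invertible branch.
#' @export
invert_retrieval <- function(value, algorithm, coeffs,
                             bracket = c(-0.4, 0.8)) {
  switch(algorithm,
    oc2 = ,
    oc3 = {
      a <- coef_values(coeffs)
      poly <- function(x) a[["a0"]] + a[["a1"]] * x + a[["a2"]] * x^2 +
        a[["a3"]] * x^3 + a[["a4"]] * x^4
      lo <- poly(bracket[2]); hi <- poly(bracket[1])  # decreasing branch
      rng <- sort(c(lo, hi))
      target <- log10(value)
      if (any(target < rng[1] | target > rng[2])) {
        stop("chl-a outside the invertible OCx branch [",
             signif(10^rng[1], 3), ", ", signif(10^rng[2], 3), "] mg m^-3",
             call. = FALSE)
      }
      vapply(target, function(tg) {
        stats::uniroot(function(x) poly(x) - tg, interval = bracket,
                       tol = 1e-13)$root
      }, numeric(1))
    },
    gilerson = {
      k <- coef_values(coeffs)
      if (any(value <= 0)) stop("chl-a must be positive", call. = FALSE)
      (value^(1 / k[["c"]]) - k[["b"]]) / k[["a"]]
    },
    turbidity = {
      k <- coef_values(coeffs)
      if (any(value < 0)) stop("turbidity must be non-negative", call. = FALSE)
      value / (k[["A_t"]] + value / k[["C_t"]])
    },
    stop("no inverse for algorithm '", algorithm, "'", call. = FALSE)
  )
}

#' Generate a synthetic paired-sensor matchup dataset
#'
#' Builds one matchup table and its ground-truth table from a
#' [synthetic_config()]. Per record: the truth (lake, chl-a, turbidity,
#' log-uniform distance to land, optical water type) is sampled; the
#' reference-sensor (OLCI) reflectances are manufactured by exact inversion
#' of the retrieval formulas, so the reference retrievals reproduce the
#' truth; the high-resolution-sensor (MSI) reflectances are derived by
#' applying the configured ratio distortions, blue-green skew, band noise
#' and distance-decaying adjacency perturbation; flags and neighbour counts
#' are drawn from the configured probabilities. Byte-identical output for
#' identical config and seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `matchups` (the standard matchup tibble), `truth`
#'   (lake_id, chla_true, turb_true, dist_land_km, owt_id) and `n_resampled`
#'   (records redrawn because an inversion left the valid reflectance
#'   domain).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  reg <- read_registry()
  oc2_olci <- registry_coefficients(reg, "olci", "oc2")
  gil_olci <- registry_coefficients(reg, "olci", "gilerson")
  nech_olci <- resolve_nechad(config$nechad, "b708")$olci
  lakes <- config$lakes
  n_total <- sum(lakes$n_obs)
  lake_id <- rep(lakes$lake_id, lakes$n_obs)

  # --- truth ---------------------------------------------------------------
  chla <- stats::rlnorm(n_total,
                        rep(lakes$chla_meanlog, lakes$n_obs),
                        rep(lakes$chla_sdlog, lakes$n_obs))
  turb <- stats::rlnorm(n_total,
                        rep(lakes$turb_meanlog, lakes$n_obs),
                        rep(lakes$turb_sdlog, lakes$n_obs))
  dist <- exp(stats::runif(n_total, log(config$dist_range_km[1]),
                           log(config$dist_range_km[2])))
  owt <- dominant_owt_draw(lakes, n_total)

  # resample truths whose turbidity inversion would leave the valid
  # reflectance domain (rw must stay below the asymptote; guaranteed by the
  # closed form, but enormous draws can overflow the band-1 reflectance cap)
  n_resampled <- 0L
  for (attempt in 1:10) {
    rw708_o <- invert_retrieval(turb, "turbidity", nech_olci)
    bad <- !is.finite(rw708_o) | rw708_o >= 1 | rw708_o < 0
    if (!any(bad)) break
    n_resampled <- n_resampled + sum(bad)
    turb[bad] <- stats::rlnorm(sum(bad),
                               rep(lakes$turb_meanlog, lakes$n_obs)[bad],
                               rep(lakes$turb_sdlog, lakes$n_obs)[bad])
    if (attempt == 10) stop("retry budget exhausted: config demands ",
                            "impossible turbidity inversions", call. = FALSE)
  }

  # --- reference-sensor (OLCI) reflectances --------------------------------
  a <- coef_values(oc2_olci)
  poly_rng <- range(vapply(config$ocx_bracket, function(x) {
    a[["a0"]] + a[["a1"]] * x + a[["a2"]] * x^2 + a[["a3"]] * x^3 +
      a[["a4"]] * x^4
  }, numeric(1)))
  chla_clamped <- pmin(pmax(chla, 10^poly_rng[1] * 1.0001),
                       10^poly_rng[2] * 0.9999)
  x_bg_o <- invert_retrieval(chla_clamped, "oc2", oc2_olci,
                             bracket = config$ocx_bracket)
  ratio_nr_o <- invert_retrieval(chla, "gilerson", gil_olci)
  rw560_o <- stats::rlnorm(n_total, log(0.010), 0.15)
  rw490_o <- rw560_o * 10^x_bg_o
  rw443_o <- 0.92 * rw490_o
  rw665_o <- rw708_o / ratio_nr_o
  rw778_o <- 0.35 * rw708_o
  rw865_o <- 0.50 * rw778_o

  # --- high-resolution-sensor (MSI) reflectances ---------------------------
  x_bg_m <- apply_linear_calibration(x_bg_o, config$distortion$oc2) +
    stats::rnorm(n_total, 0, config$ratio_noise_sd[["oc2"]])
  ratio_nr_m <- apply_linear_calibration(ratio_nr_o,
                                         config$distortion$nir_red) +
    stats::rnorm(n_total, 0, config$ratio_noise_sd[["nir_red"]])
  ratio_nr_m[ratio_nr_m <= 0] <- ratio_nr_o[ratio_nr_m <= 0]
  amp <- coef_values(config$distortion$red_nir_amplitude)[["gain"]]
  noise <- function() 1 + stats::rnorm(n_total, 0, config$rw_noise_sd)
  skew <- exp(stats::rnorm(n_total, config$bluegreen_skew[["meanlog"]],
                           config$bluegreen_skew[["sdlog"]]))
  rw560_m <- rw560_o * noise() * skew
  rw490_m <- rw560_m * 10^x_bg_m
  rw443_m <- 0.92 * rw490_m
  rw708_m <- rw708_o * amp * noise()
  rw665_m <- rw708_m / ratio_nr_m
  rw778_m <- rw778_o * amp * noise()
  rw865_m <- rw865_o * amp * noise()

  msi <- list(b443 = rw443_m, b490 = rw490_m, b560 = rw560_m,
              b665 = rw665_m, b708 = rw708_m, b778 = rw778_m,
              b865 = rw865_m)
  adj_sd <- config$adjacency[["amplitude"]] *
    exp(-dist / config$adjacency[["efold_km"]])
  for (b in names(msi)) {
    w <- config$adjacency_weights[[b]]
    msi[[b]] <- msi[[b]] *
      pmax(1 + stats::rnorm(n_total, 0, 1) * adj_sd * w, 0.01)
  }

  # --- flags, neighbours, coordinates --------------------------------------
  fp <- config$flag_probs
  bern <- function(p) as.integer(stats::runif(n_total) < p)
  lake_idx <- match(lake_id, lakes$lake_id)
  tab <- tibble::tibble(
    lake_id = lake_id,
    timestamp = format(as.POSIXct("2017-01-01", tz = "UTC") +
                         round(stats::runif(n_total, 0, 730 * 86400)),
                       "%Y-%m-%dT%H:%M:%SZ"),
    lat = round(-60 + 6 * lake_idx + stats::runif(n_total, 0, 0.2), 6),
    lon = round(-180 + 17 * lake_idx + stats::runif(n_total, 0, 0.2), 6),
    dist_land_km = dist,
    n_valid_neighbours = sample(0:8, n_total, replace = TRUE,
                                prob = config$neighbour_probs),
    flag_cloud_buffer = bern(fp[["cloud"]] / 2),
    flag_cloud_sure = bern(fp[["cloud_sure"]]),
    flag_cloud = bern(fp[["cloud"]]),
    flag_cloud_ambiguous = bern(fp[["cloud"]] / 2),
    flag_cirrus_sure = bern(fp[["cirrus"]]),
    flag_cirrus_ambiguous = bern(fp[["cirrus"]]),
    flag_potential_shadow = bern(fp[["shadow"]]),
    flag_land = bern(fp[["land"]]),
    flag_clear_water = 1L - bern(fp[["not_clear_water"]]),
    flag_out_of_bounds_msi = bern(fp[["out_of_bounds"]]),
    flag_out_of_bounds_olci = bern(fp[["out_of_bounds"]]),
    flag_snow_ice_olci = bern(fp[["snow_ice"]])
  )
  olci <- list(b443 = rw443_o, b490 = rw490_o, b560 = rw560_o,
               b665 = rw665_o, b708 = rw708_o, b778 = rw778_o,
               b865 = rw865_o)
  for (b in canonical_bands()) tab[[paste0("rw_msi_", b)]] <- msi[[b]]
  for (b in canonical_bands()) tab[[paste0("rw_olci_", b)]] <- olci[[b]]

  truth <- tibble::tibble(lake_id = lake_id, chla_true = chla,
                          turb_true = turb, dist_land_km = dist,
                          owt_id = owt)
  list(matchups = tab, truth = truth, n_resampled = n_resampled)
}

# Draw a per-record optical water type: the lake's dominant type with
# probability 0.7, otherwise uniform over 1..13.
dominant_owt_draw <- function(lakes, n_total) {
  dom <- rep(lakes$dominant_owt, lakes$n_obs)
  other <- sample(1:13, n_total, replace = TRUE)
  ifelse(stats::runif(n_total) < 0.7, dom, other)
}
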
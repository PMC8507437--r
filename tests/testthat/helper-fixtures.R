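# Shared fixtures built in code.

nechad_fixture <- function() {
  system.file("extdata", "nechad_coefficients_synthetic.json",
              package = "lakecal")
}

msi_oc2_init <- function() {
  registry_coefficients(read_registry(), "msi", "oc2", stage = "initial")
}

# A minimal clean matchup row; override fields as needed.
clean_row <- function(...) {
  row <- tibble::tibble(
    lake_id = "lakeA", timestamp = "2017-06-01T10:00:00Z",
    lat = 45, lon = 10, dist_land_km = 10, n_valid_neighbours = 8L,
    flag_cloud_buffer = 0L, flag_cloud_sure = 0L, flag_cloud = 0L,
    flag_cloud_ambiguous = 0L, flag_cirrus_sure = 0L,
    flag_cirrus_ambiguous = 0L, flag_potential_shadow = 0L, flag_land = 0L,
    flag_clear_water = 1L, flag_out_of_bounds_msi = 0L,
    flag_out_of_bounds_olci = 0L, flag_snow_ice_olci = 0L,
    rw_msi_b443 = 0.010, rw_msi_b490 = 0.012, rw_msi_b560 = 0.010,
    rw_msi_b665 = 0.004, rw_msi_b708 = 0.0005, rw_msi_b778 = 0.0004,
    rw_msi_b865 = 0.0002,
    rw_olci_b443 = 0.010, rw_olci_b490 = 0.012, rw_olci_b560 = 0.010,
    rw_olci_b665 = 0.004, rw_olci_b708 = 0.0005, rw_olci_b778 = 0.0004,
    rw_olci_b865 = 0.0002
  )
  mods <- list(...)
  for (nm in names(mods)) row[[nm]] <- mods[[nm]]
  row
}

clean_table <- function(n, ...) {
  tab <- dplyr::bind_rows(lapply(seq_len(n), function(i) clean_row(...)))
  tab$timestamp <- format(as.POSIXct("2017-06-01 10:00:00", tz = "UTC") +
                            seq_len(n) * 60, "%Y-%m-%dT%H:%M:%SZ")
  tab
}

# Synthetic generator config with no contamination, distortion as given.
quiet_config <- function(lakes, seed = 1, identity = FALSE, ...) {
  args <- utils::modifyList(list(
    lakes = lakes, seed = seed,
    flag_probs = c(cloud = 0, cloud_sure = 0, cirrus = 0, shadow = 0,
                   land = 0, out_of_bounds = 0, snow_ice = 0,
                   not_clear_water = 0),
    neighbour_probs = c(0, 0, 0, 0, 0, 0, 0, 0, 1),
    adjacency = c(amplitude = 0, efold_km = 2)
  ), list(...))
  if (identity) {
    args$distortion <- list(oc2 = linear_calibration(1, 0),
                            nir_red = linear_calibration(1, 0),
                            red_nir_amplitude = linear_calibration(1, 0))
    args$ratio_noise_sd <- c(oc2 = 0, nir_red = 0)
    args$bluegreen_skew <- c(meanlog = 0, sdlog = 0)
    args$rw_noise_sd <- 0
  }
  do.call(synthetic_config, args)
}

recovery_lakes <- function(n_lakes = 8, n_obs = 1500,
                           chla_meanlog = log(2), chla_sdlog = 0.6) {
  tibble::tibble(
    lake_id = sprintf("L%02d", seq_len(n_lakes)), n_obs = n_obs,
    chla_meanlog = chla_meanlog, chla_sdlog = chla_sdlog,
    turb_meanlog = log(0.25), turb_sdlog = 0.3,
    dominant_owt = rep_len(c(3, 9, 13), n_lakes)
  )
}

# Direct-formula oracles, intentionally independent of package internals.
oracle_metrics <- function(x, y) {
  d <- x - y
  list(mad = sum(abs(d)) / length(d),
       mapd = 100 / length(d) * sum(abs(d) / y),
       rmsd = sqrt(sum(d^2) / length(d)),
       r = sum((x - mean(x)) * (y - mean(y))) /
         sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
       bias = sum(d) / length(d))
}

oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

oracle_nechad <- function(rw, A, C) A * rw / (1 - rw / C)

oracle_gons <- function(rw665, rw708, rw779, p, astar,
                        aw665 = 0.40, aw709 = 0.70, aw779 = 2.71) {
  bb <- 0.6 * aw779 * rw779 / (0.082 - 0.6 * rw779)
  ((rw708 / rw665) * (aw709 + bb) - aw665 - bb^p) / astar
}
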
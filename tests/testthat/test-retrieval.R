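test_that("band ratios match hand-evaluated cases and flag invalid inputs", {
  expect_equal(as.numeric(band_ratio(c(b490 = 0.01, b560 = 0.01), "oc2")), 0)
  expect_equal(as.numeric(band_ratio(c(b443 = 0.02, b490 = 0.01,
                                       b560 = 0.01), "oc3")),
               log10(2))
  expect_equal(as.numeric(band_ratio(c(b665 = 0.004, b708 = 0.005),
                                     "nir_red")), 1.25)
  # invalid inputs become NA with an enumerated reason, not an error
  r <- band_ratio(tibble::tibble(b490 = c(0.01, 0.01, NA),
                                 b560 = c(0, 0.01, 0.01)), "oc2")
  expect_equal(is.na(as.numeric(r)), c(TRUE, FALSE, TRUE))
  expect_equal(attr(r, "reason")[c(1, 3)],
               c("nonpositive_denominator", "missing_band"))
})

test_that("OCx polynomial retrieval is 10^poly and strictly positive", {
  expect_equal(ocx_chla(0, msi_oc2_init()), 10^0.2389)
  zero <- ocx_coefficients(0, 0, 0, 0, 0)
  expect_equal(ocx_chla(0, zero), 1.0)
  # tuned-coefficient polynomial at x = 0.1, against a Horner-style oracle
  tuned <- registry_coefficients(read_registry(), "msi", "oc2", "tuned")
  a <- c(0.3818, -4.9640, -0.9966, 7.3857, -31.5261)
  expect_equal(ocx_chla(0.1, tuned), 10^sum(a * 0.1^(0:4)))
  expect_equal(ocx_chla(0.1, tuned), 0.7579963, tolerance = 1e-6)
  # positivity for any finite ratio
  expect_true(all(ocx_chla(seq(-1.2, 1.2, by = 0.1), tuned) > 0))
})

test_that("NIR-red power-law retrieval honours its domain and monotonicity", {
  g <- gilerson_coefficients(35.75, -19.30, 1.124)
  expect_equal(as.numeric(gilerson_chla((1 + 19.30) / 35.75, g)), 1.0)
  expect_equal(as.numeric(gilerson_chla(0.56, g)), 0.72^1.124)
  bad <- gilerson_chla(0.5, g)   # base 35.75*0.5 - 19.30 < 0
  expect_true(is.na(as.numeric(bad)))
  expect_equal(attr(bad, "reason"), "nonpositive_base")
  # monotone increasing wherever defined (a > 0, c > 0)
  xs <- seq(0.56, 3, length.out = 200)
  expect_true(all(diff(as.numeric(gilerson_chla(xs, g))) > 0))
})

test_that("backscatter inversion matches hand evaluation and its domain", {
  gc <- gons_coefficients(1.06, 0.016)
  expect_equal(as.numeric(gons_backscatter(0, gc)), 0)
  expect_equal(as.numeric(gons_backscatter(0.01, gc)),
               0.6 * 2.71 * 0.01 / (0.082 - 0.006))
  out <- gons_backscatter(0.14, gc)   # 0.082 - 0.084 < 0
  expect_true(is.na(as.numeric(out)))
  expect_equal(attr(out, "reason"), "bb_domain")
  xs <- seq(0, 0.13, length.out = 100)
  expect_true(all(diff(as.numeric(gons_backscatter(xs, gc))) > 0))
})

test_that("semi-analytical chl-a follows the closed form", {
  gc <- gons_coefficients(1.06, 0.016)
  # bb = 0 and ratio = aw665/aw709 zeroes the numerator
  expect_equal(as.numeric(gons_chla(0.02, 0.02 * 0.40 / 0.70, 0, gc)), 0)
  expect_equal(as.numeric(gons_chla(0.02, 0.02, 0, gc)),
               (0.70 - 0.40) / 0.016)
  # halving through a_chl_star
  gc2 <- gons_coefficients(1.06, 0.032)
  expect_equal(as.numeric(gons_chla(0.01, 0.02, 0.01, gc2)),
               as.numeric(gons_chla(0.01, 0.02, 0.01, gc)) / 2)
})

test_that("single-band turbidity matches hand evaluation and identities", {
  nb <- nechad_coefficients(300, 0.2, band = "b665")
  expect_equal(as.numeric(nechad_turbidity(0, nb)), 0)
  expect_equal(as.numeric(nechad_turbidity(0.1, nb)), 60)
  expect_equal(as.numeric(nechad_turbidity(0.2 / 2, nb)), 300 * 0.2)
  # T = A*C at rw = C/2 for arbitrary (A, C)
  for (i in 1:20) {
    A <- runif(1, 50, 2000); C <- runif(1, 0.05, 0.9)
    nb2 <- nechad_coefficients(A, C, band = "b708")
    expect_equal(as.numeric(nechad_turbidity(C / 2, nb2)), A * C)
  }
  out <- nechad_turbidity(0.25, nb)
  expect_true(is.na(as.numeric(out)))
  expect_equal(attr(out, "reason"), "rw_out_of_domain")
  xs <- seq(0, 0.19, length.out = 100)
  expect_true(all(diff(as.numeric(nechad_turbidity(xs, nb))) > 0))
})

test_that("linear calibration reproduces the published gain applications", {
  cal665 <- linear_calibration(0.882, -0.024)
  expect_equal(apply_linear_calibration(2.0, cal665), 1.740)
  expect_equal(apply_linear_calibration(5, linear_calibration(1, 0)), 5)
  eq6 <- linear_calibration(1.442, -0.51)
  expect_equal(apply_linear_calibration(1.0, eq6), 0.932)
})

test_that("formula kernels agree with independent scalar oracles", {
  set.seed(42)
  gc <- gons_coefficients(1.06, 0.016)
  rw <- runif(1000, 0, 0.13)
  expect_equal(as.numeric(gons_backscatter(rw, gc)),
               0.6 * 2.71 * rw / (0.082 - 0.6 * rw), tolerance = 1e-12)
  nb <- nechad_coefficients(567.23, 0.1886, band = "b708")
  rw2 <- runif(1000, 0, 0.18)
  expect_equal(as.numeric(nechad_turbidity(rw2, nb)),
               oracle_nechad(rw2, 567.23, 0.1886), tolerance = 1e-12)
  r665 <- runif(1000, 0.002, 0.05)
  r708 <- runif(1000, 0.002, 0.05)
  expect_equal(as.numeric(gons_chla(r665, r708, rw, gc)),
               oracle_gons(r665, r708, rw, 1.06, 0.016), tolerance = 1e-12)
})

test_that("bulk product retrieval equals the scalar operations row-by-row", {
  tab <- clean_table(3)
  tab$rw_msi_b490 <- c(0.012, 0.015, 0.009)
  out <- retrieve_products(tab, "oc2")
  for (i in 1:3) {
    x <- log10(tab$rw_msi_b490[i] / tab$rw_msi_b560[i])
    expect_identical(out$chla_msi[i], ocx_chla(x, msi_oc2_init()))
  }
  expect_false(any(is.na(out$chla_olci)))
  # empty table passes through
  empty <- retrieve_products(tab[0, ], "oc2")
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(rejection_report(empty)), 0)
  # a zero green band yields a missing product with a counted reason
  tab2 <- clean_table(2)
  tab2$rw_msi_b560[2] <- 0
  out2 <- retrieve_products(tab2, "oc2")
  expect_equal(nrow(out2), 2)
  expect_true(is.na(out2$chla_msi[2]))
  rej <- rejection_report(out2)
  expect_equal(rej$n[rej$sensor == "msi" &
                       rej$reason == "nonpositive_denominator"], 1L)
  expect_error(retrieve_products(tab, "nope"))
})

test_that("coefficient registry round-trips through JSON bit-identically", {
  reg <- read_registry()
  tmp <- tempfile(fileext = ".json")
  write_registry(reg, tmp)
  reg2 <- read_registry(tmp)
  expect_identical(unclass(reg), unclass(reg2))
  # transcribed values spot-check
  expect_identical(reg$initial$msi$oc2$a0, 0.2389)
  expect_identical(reg$tuned$msi$oc2$a4, -31.5261)
  expect_identical(reg$turbidity_calibration$msi$b778$offset, -0.333)
})

test_that("band labels absorb the interchangeable nominal wavelengths", {
  expect_equal(band_label(c(705, 708.75, 709)), rep("b708", 3))
  expect_equal(band_label(c(778.75, 779, 783)), rep("b778", 3))
  expect_error(band_label(512), "no canonical band")
})
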
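test_that("pixel masks remove in order with first-trigger attribution", {
  # 8 rows: 2 cloud-flagged, 1 with a reflectance of 1.2, 1 with 3
  # neighbours, 4 clean -> survivors 4, removals 2/1/0/0/1
  tab <- clean_table(8)
  tab$flag_cloud[1] <- 1L
  tab$flag_cloud_sure[2] <- 1L
  tab$rw_msi_b490[3] <- 1.2
  tab$n_valid_neighbours[4] <- 3L
  res <- apply_pixel_masks(tab)
  expect_equal(nrow(res$table), 4)
  expect_equal(res$report$n_removed, c(2, 1, 0, 0, 1))
  expect_equal(res$report$n_in[1], 8)
  expect_equal(res$report$n_out[nrow(res$report)], 4)
  # telescoping
  expect_equal(res$report$n_in - res$report$n_removed, res$report$n_out)
  expect_equal(res$report$n_in[-1], res$report$n_out[-nrow(res$report)])
})

test_that("neighbour and clear-water rules behave as specified", {
  few <- apply_pixel_masks(clean_row(n_valid_neighbours = 4L))
  expect_equal(nrow(few$table), 0)
  expect_equal(few$report$step[few$report$n_removed == 1],
               "too_few_neighbours")
  ok <- apply_pixel_masks(clean_row())
  expect_equal(nrow(ok$table), 1)
  notclear <- apply_pixel_masks(clean_row(flag_clear_water = 0L))
  expect_equal(nrow(notclear$table), 0)
  expect_error(apply_pixel_masks(clean_row()[, -7]), "flag_cloud_buffer")
})

test_that("central-99.9% trim retains the documented fractions", {
  set.seed(7)
  v <- runif(10000)
  expect_equal(sum(trim_extreme_chla(v)), 9990)
  expect_true(all(trim_extreme_chla(rep(1, 100))))
  expect_true(all(trim_extreme_chla(c(1, 2))))
  # a record is kept only if kept under both sensors' trims
  m <- runif(10000); o <- runif(10000)
  keep <- trim_extreme_chla(m, o)
  expect_equal(keep, trim_extreme_chla(m) & trim_extreme_chla(o))
  expect_true(sum(keep) >= 9980 && sum(keep) <= 9990)
  # per-tail cap property
  for (n in c(50, 2000, 4001, 25000)) {
    vv <- runif(n)
    removed <- !trim_extreme_chla(vv)
    expect_lte(sum(vv[removed] < median(vv)), ceiling(0.0005 * n))
    expect_lte(sum(vv[removed] > median(vv)), ceiling(0.0005 * n))
  }
})

test_that("two-sigma filter removes gross outliers and keeps boundaries", {
  v <- c(rep(0, 9), 100)
  expect_equal(sum(sigma_filter_chla(v)), 9)
  expect_false(sigma_filter_chla(v)[10])
  expect_true(all(sigma_filter_chla(rep(3.2, 50))))
  expect_true(all(sigma_filter_chla(c(-1, 1))))   # |v - mean| = sd
})

test_that("per-algorithm range gates enforce the documented ranges", {
  base <- tibble::tibble(ratio_msi = 1.2, ratio_olci = 1.2, chla_msi = 5,
                         chla_olci = 5, turb_olci_gate = 0.3)
  ok <- algorithm_range_filter(base, "oc2")
  expect_equal(nrow(ok$table), 1)
  # OLCI chl-a = 12 out of the 0.2-10 blue-green range
  out <- algorithm_range_filter(dplyr::mutate(base, chla_olci = 12), "oc2")
  expect_equal(nrow(out$table), 0)
  expect_equal(out$report$step[out$report$n_removed == 1], "olci_chla_range")
  # turbid water removed from the blue-green set
  out2 <- algorithm_range_filter(dplyr::mutate(base, turb_olci_gate = 0.8),
                                 "oc2")
  expect_equal(nrow(out2$table), 0)
  # negative MSI chl-a removed for the semi-analytical algorithm
  g <- tibble::tibble(chla_msi = -3, chla_olci = 50)
  expect_equal(nrow(algorithm_range_filter(g, "gons05")$table), 0)
  expect_equal(nrow(algorithm_range_filter(
    tibble::tibble(chla_msi = 3, chla_olci = 50), "gons05")$table), 1)
  # turbidity: both sensors positive retained
  tt <- tibble::tibble(turb_msi = 1.0, turb_olci = 1.0)
  expect_equal(nrow(algorithm_range_filter(tt, "turbidity")$table), 1)
  expect_equal(nrow(algorithm_range_filter(
    tibble::tibble(turb_msi = -1, turb_olci = 1), "turbidity")$table), 0)
  expect_error(algorithm_range_filter(base, "nope"))
})

test_that("filter cascade telescopes, attributes removals and survives reruns", {
  # planted violations on a tie-heavy clean background so the quantile steps
  # are at a fixed point and the cascade is idempotent
  tab <- clean_table(40)
  tab$flag_cloud[1:3] <- 1L
  tab$rw_olci_b443[4] <- 1.5
  tab$n_valid_neighbours[5:6] <- 2L
  tab$flag_snow_ice_olci[7] <- 1L
  res <- run_filter_cascade(tab, "oc2", nechad = nechad_fixture())
  expect_equal(nrow(res$table), 33)
  expect_equal(sum(res$report$n_removed), 7)
  expect_equal(res$report$n_in - res$report$n_removed, res$report$n_out)
  expect_equal(res$report$n_in[-1], res$report$n_out[-nrow(res$report)])
  by_step <- res$report$n_removed[res$report$n_removed > 0]
  expect_equal(sum(by_step), 40 - 33)   # every removal has exactly one step
  # idempotence
  res2 <- run_filter_cascade(res$table, "oc2", nechad = nechad_fixture())
  expect_equal(nrow(res2$table), nrow(res$table))
  expect_equal(res2$table$chla_msi, res$table$chla_msi)
  expect_true(all(res2$report$n_removed == 0))
})

test_that("a zero-contamination synthetic fixture passes masks and gates", {
  cfg <- quiet_config(recovery_lakes(4, 250), seed = 5, identity = TRUE)
  ds <- generate_dataset(cfg)
  res <- run_filter_cascade(ds$matchups, "oc2", nechad = nechad_fixture())
  rep <- res$report
  mask_steps <- c("cloud_shadow_land_flags", "reflectance_gt_1",
                  "out_of_bounds", "snow_ice", "too_few_neighbours",
                  "product_undefined")
  expect_true(all(rep$n_removed[rep$step %in% mask_steps] == 0))
})
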
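# A small product table directly in the post-cascade schema, with controlled
# per-lake unique counts; products follow the identity y = 2x + 1 plus noise
# unless overridden.
product_table <- function(counts, f = function(x) 2 * x + 1, noise = 0.05,
                          seed = 99) {
  set.seed(seed)
  dplyr::bind_rows(lapply(names(counts), function(lk) {
    n <- counts[[lk]]
    x <- runif(n, 0.5, 5)
    tibble::tibble(
      lake_id = lk,
      timestamp = format(as.POSIXct("2017-01-01", tz = "UTC") + seq_len(n),
                         "%Y-%m-%dT%H:%M:%SZ"),
      lat = 50, lon = 10,
      turb_msi = x, turb_olci = f(x) + rnorm(n, 0, noise)
    )
  }))
}

test_that("lakes below the unique-match threshold are excluded", {
  tab <- product_table(list(small = 139, edge = 140, big = 500))
  tr <- bootstrap_tune(tab, "turbidity",
                       settings = tuning_settings(n_replicates = 5, seed = 1))
  expect_setequal(tr$lakes_included, c("edge", "big"))
  expect_equal(tr$lakes_excluded, "small")
  expect_equal(tr$draws_per_lake, 150)
  expect_error(
    bootstrap_tune(product_table(list(a = 50)), "turbidity",
                   settings = tuning_settings(n_replicates = 2, seed = 1)),
    "no lake meets")
})

test_that("bootstrap tuning is bit-reproducible from its seed", {
  tab <- product_table(list(a = 200, b = 300))
  s <- tuning_settings(n_replicates = 10, seed = 42)
  t1 <- bootstrap_tune(tab, "turbidity", settings = s)
  t2 <- bootstrap_tune(tab[sample(nrow(tab)), ], "turbidity", settings = s)
  expect_identical(t1$samples, t2$samples)   # order-normalised input
  expect_identical(t1$substream_seeds, t2$substream_seeds)
  t3 <- bootstrap_tune(tab, "turbidity",
                       settings = tuning_settings(n_replicates = 10,
                                                  seed = 43))
  expect_false(identical(t1$samples, t3$samples))
})

test_that("perfectly aligned products tune to the identity", {
  tab <- product_table(list(a = 200, b = 300), f = identity, noise = 0)
  tr <- bootstrap_tune(tab, "turbidity",
                       settings = tuning_settings(n_replicates = 20,
                                                  seed = 7))
  expect_equal(unname(tr$summary$median), c(1, 0), tolerance = 1e-6)
  # and the chl-a path: MSI == OLCI with the reference coefficients as init
  cfg <- quiet_config(recovery_lakes(3, 400), seed = 4, identity = TRUE)
  ds <- generate_dataset(cfg)
  fc <- run_filter_cascade(ds$matchups, "gilerson", nechad = nechad_fixture())
  init <- registry_coefficients(read_registry(), "olci", "gilerson")
  tr2 <- bootstrap_tune(fc$table, "gilerson", init = init,
                        settings = tuning_settings(n_replicates = 10,
                                                   seed = 7))
  expect_equal(unname(tr2$summary$median),
               unname(init$coefficients), tolerance = 1e-6)
})

test_that("median coefficients lie within the per-parameter extremes", {
  tab <- product_table(list(a = 200, b = 300))
  tr <- bootstrap_tune(tab, "turbidity",
                       settings = tuning_settings(n_replicates = 25,
                                                  seed = 5))
  expect_true(all(tr$summary$median >= tr$summary$min &
                    tr$summary$median <= tr$summary$max))
  expect_equal(nrow(tr$samples), 25 - tr$n_failed)
})

test_that("per-lake tuning summarises the fit distribution across lakes", {
  # two lakes generated from two different line parameter sets
  tab <- product_table(list(a = 300, b = 300), noise = 0)
  tab$turb_olci[tab$lake_id == "b"] <- 3 * tab$turb_msi[tab$lake_id == "b"] - 1
  pl <- per_lake_tune(tab, "turbidity",
                      settings = tuning_settings(loss = "linear"))
  a_row <- pl$per_lake[pl$per_lake$lake_id == "a", ]
  b_row <- pl$per_lake[pl$per_lake$lake_id == "b", ]
  expect_equal(c(a_row$gain, a_row$offset), c(2, 1), tolerance = 1e-3)
  expect_equal(c(b_row$gain, b_row$offset), c(3, -1), tolerance = 1e-3)
  expect_true(all(pl$summary$sd > 0))
  expect_equal(pl$summary$median,
               (pl$summary$min + pl$summary$max) / 2)   # two lakes
  # single lake: mean = median = min = max
  one <- per_lake_tune(product_table(list(solo = 200), noise = 0),
                       "turbidity", settings = tuning_settings())
  expect_equal(one$summary$mean, one$summary$median)
  expect_equal(one$summary$min, one$summary$max)
  # applying median-of-per-lake coefficients is a supported evaluation mode
  cal <- median_coefficients(pl)
  expect_s3_class(cal, "linear_calibration")
  expect_equal(apply_linear_calibration(2, cal),
               unname(pl$summary$median[1] * 2 + pl$summary$median[2]))
})

test_that("tuning results serialize with provenance", {
  tab <- product_table(list(a = 200, b = 300))
  tr <- bootstrap_tune(tab, "turbidity",
                       settings = tuning_settings(n_replicates = 5,
                                                  seed = 11))
  tmp <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  write_tuning_result(tr, tmp, samples_csv = csv)
  out <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(out$seed, 11)
  expect_equal(out$n_replicates, 5)
  expect_setequal(out$lakes_included, c("a", "b"))
  expect_equal(nrow(utils::read.csv(csv)), nrow(tr$samples))
})
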
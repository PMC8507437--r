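test_that("agreement statistics match hand-evaluated cases", {
  m <- compute_metrics(c(2, 4), c(1, 2), kind = "turbidity")
  expect_equal(m$mad, 1.5)
  expect_equal(m$bias, 1.5)
  expect_equal(m$rmsd, sqrt(2.5))
  expect_equal(m$mapd, 100)
  expect_equal(m$n, 2L)
  same <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$mad, same$rmsd, same$bias, same$rp50), rep(0, 4))
  prop <- compute_metrics(2 * c(1, 3, 7), c(1, 3, 7))
  expect_equal(prop$r, 1)
  expect_error(compute_metrics(1, 1), "at least 2")
  # zero reference values are excluded from MAPD only, with a count
  z <- compute_metrics(c(1, 2, 3), c(0, 2, 3), kind = "turbidity")
  expect_equal(z$mapd_excluded, 1L)
  expect_equal(z$n, 3L)
})

test_that("all metrics agree with direct-formula oracles", {
  set.seed(11)
  for (i in 1:5) {
    x <- rlnorm(200, 0, 1)
    y <- rlnorm(200, 0, 1)
    m <- compute_metrics(x, y)
    o <- oracle_metrics(x, y)
    expect_equal(m$mad, o$mad, tolerance = 1e-10)
    expect_equal(m$mapd, o$mapd, tolerance = 1e-10)
    expect_equal(m$rmsd, o$rmsd, tolerance = 1e-10)
    expect_equal(m$r, o$r, tolerance = 1e-10)
    expect_equal(m$bias, o$bias, tolerance = 1e-10)
    # RMSD^2 = bias^2 + population variance of residuals
    d <- x - y
    expect_equal(m$rmsd^2, m$bias^2 + mean((d - mean(d))^2),
                 tolerance = 1e-10)
    expect_true(m$rmsd >= abs(m$bias))
    expect_true(m$rp5 <= m$rp50 && m$rp50 <= m$rp95)
  }
})

test_that("regression slope follows the product-specific convention", {
  set.seed(12)
  y <- rlnorm(500, 1, 0.5)
  x <- 10^(0.8 * log10(y) + 0.1)
  m <- compute_metrics(x, y, kind = "chla")
  expect_equal(m$slope, 0.8, tolerance = 1e-8)
  yt <- runif(500, 0, 10)
  xt <- 0.7 * yt + 0.3
  mt <- compute_metrics(xt, yt, kind = "turbidity")
  expect_equal(mt$slope, 0.7, tolerance = 1e-8)
})

test_that("Welch's test matches the hand formula and handles degeneracy", {
  a <- c(1.2, 2.3, 0.8, 1.9, 2.5)
  b <- c(2.1, 3.3, 2.8, 1.7)
  w <- welch_test(a, b)
  expect_equal(w$t, oracle_welch_t(a, b), tolerance = 1e-10)
  expect_equal(w$p, stats::t.test(a, b)$p.value, tolerance = 1e-12)
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_false(same$reject)
  sep <- welch_test(rep(0, 50), c(rep(1, 49), 1.001))
  expect_true(sep$reject)
  const <- welch_test(rep(2, 5), rep(2, 7))
  expect_equal(const$p, 1)
  expect_false(const$reject)
})

test_that("distance binning partitions residuals and summarises spread", {
  set.seed(13)
  d <- exp(runif(500, log(0.1), log(100)))
  r <- rnorm(500)
  out <- residuals_by_distance(d, r)
  expect_equal(sum(out$bins$n), 500)
  expect_equal(sum(out$split$n), 500)
  # constant residuals: every occupied bin's median is that constant
  outc <- residuals_by_distance(d, rep(2.5, 500))
  expect_true(all(outc$bins$median[outc$bins$n > 0] == 2.5))
  # all records at one distance occupy a single bin
  out1 <- residuals_by_distance(rep(3, 50), rnorm(50))
  expect_equal(sum(out1$bins$n > 0), 1)
  expect_equal(out1$split$n, c(50L, 0L))
})

test_that("spectral-angle classification is exact and scale-invariant", {
  ref <- read_owt_reference()
  # a reference spectrum classifies to itself with angle 0
  sp <- ref[3, canonical_bands()]
  got <- classify_owt(sp, ref)
  expect_equal(got$class_id, ref$class_id[3])
  expect_equal(got$angle, 0, tolerance = 1e-8)
  # invariance under positive scaling
  expect_equal(classify_owt(2 * sp, ref), got, tolerance = 1e-10)
  expect_equal(classify_owt(0.01 * sp, ref), got, tolerance = 1e-10)
  # two orthogonal references
  orth <- tibble::tibble(class_id = 1:2, b443 = c(1, 0), b490 = c(0, 1))
  q <- classify_owt(c(b443 = 0.7, b490 = 0), orth)
  expect_equal(q$class_id, 1L)
  expect_equal(q$angle, 0)
  # zero-norm query is unclassifiable
  z <- classify_owt(c(b443 = 0, b490 = 0), orth)
  expect_true(is.na(z$class_id))
})

test_that("stratified metrics recover group structure", {
  set.seed(14)
  y <- rlnorm(400, 0, 0.5)
  g <- rep(c("clear", "turbid"), each = 200)
  x <- y + ifelse(g == "clear", 0.2, -1.0) + rnorm(400, 0, 0.01)
  out <- stratified_metrics(x, y, g, kind = "turbidity")
  expect_equal(out$bias[out$group == "clear"], 0.2, tolerance = 0.01)
  expect_equal(out$bias[out$group == "turbid"], -1.0, tolerance = 0.01)
  # single group equals compute_metrics
  one <- stratified_metrics(x, y, rep("all", 400), kind = "turbidity")
  expect_equal(one$mad, compute_metrics(x, y, kind = "turbidity")$mad)
  # label-set unions and small-group flagging
  u <- stratified_metrics(x, y, g, label_sets = list(both = c("clear",
                                                              "turbid")),
                          kind = "turbidity")
  expect_equal(u$n[u$group == "both"], 400L)
  small <- stratified_metrics(c(x, 5), c(y, 5), c(g, "rare"),
                              kind = "turbidity", min_n = 10)
  expect_true(small$flagged[small$group == "rare"])
})
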
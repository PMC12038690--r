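test_that("linear fit solves the normal equations with the flat-y convention", {
  f <- linear_fit(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)

  flat <- linear_fit(c(0, 1, 2), c(1, 1, 1))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  f2 <- linear_fit(c(0, 1, 2), c(0, 2, 3))
  expect_equal(f2$slope, 1.5)
  expect_equal(f2$intercept, 1 / 6)
  expect_equal(f2$r_squared, 27 / 28)

  expect_error(linear_fit(c(1, 1, 1), c(0, 1, 2)), class = "pegs_degenerate_fit")

  # cross-check against stats::lm on random data
  set.seed(3)
  x <- rnorm(40); y <- 2 + 0.7 * x + rnorm(40, 0, 0.3)
  lmfit <- stats::lm(y ~ x)
  mine <- linear_fit(x, y)
  expect_equal(mine$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(mine$intercept, unname(coef(lmfit)[1]), tolerance = 1e-12)
  expect_equal(mine$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)

  # R^2 is invariant to affine rescaling of x
  resc <- linear_fit(3 * x - 5, y)
  expect_equal(resc$r_squared, mine$r_squared, tolerance = 1e-12)
})

test_that("calibration curves aggregate replicates and stay order-invariant", {
  runs <- data.frame(conc = rep(c(0.5, 1, 5), each = 3),
                     slope = -c(0.01, 0.011, 0.009,
                                0.021, 0.02, 0.019,
                                0.1, 0.102, 0.098))
  cal <- build_calibration(runs)
  expect_equal(cal$points$n, c(3, 3, 3))
  expect_equal(cal$points$mean_slope[1], -0.01)
  expect_gt(cal$r_squared, 0.99)

  # identical replicates have zero SD per point
  same <- data.frame(conc = c(1, 1, 2, 2), slope = c(0.5, 0.5, 1, 1))
  expect_equal(build_calibration(same)$points$sd_slope, c(0, 0))

  shuffled <- runs[sample(nrow(runs)), ]
  expect_equal(build_calibration(shuffled), cal)

  expect_error(build_calibration(data.frame(conc = c(1, 1), slope = c(1, 2))),
               class = "pegs_degenerate_fit")
})

test_that("calibration inversion round-trips within the fit residuals", {
  runs <- data.frame(conc = c(0.5, 1, 2, 5), slope = c(0.011, 0.019, 0.042, 0.1))
  cal <- build_calibration(runs)
  at1 <- cal$fit_intercept + cal$fit_slope * 1
  expect_equal(invert_calibration(cal, at1), 1, tolerance = 1e-12)
  expect_equal(invert_calibration(cal, cal$fit_intercept), 0)
  # round trip over all points bounded by residuals
  resid_x <- abs(runs$slope - cal$fit_intercept - cal$fit_slope * runs$conc) /
    abs(cal$fit_slope)
  back <- vapply(runs$slope, function(s) invert_calibration(cal, s), numeric(1))
  expect_lte(max(abs(back - runs$conc)), max(resid_x) + 1e-12)

  flatcal <- suppressWarnings(
    build_calibration(data.frame(conc = c(1, 2), slope = c(0.5, 0.5))))
  expect_error(invert_calibration(flatcal, 1), class = "pegs_degenerate_fit")
})

test_that("limit of detection applies the three-sigma blank criterion", {
  runs <- data.frame(conc = rep(c(0.05, 0.1, 0.5), each = 2),
                     slope = c(0.001, 0.0012, 0.01, 0.011, 0.05, 0.049))
  cal <- build_calibration(runs)
  # zero blanks: lowest tested concentration detected
  expect_equal(estimate_lod(cal, c(0, 0, 0))$lod, 0.05)
  # huge blank scatter: nothing detected
  expect_equal(estimate_lod(cal, c(0, 1, -1))$lod, Inf)
  # threshold between the first and second point
  lod <- estimate_lod(cal, c(0.002, 0.0015, 0.0025))
  expect_equal(lod$lod, 0.1)
  expect_error(estimate_lod(cal, c(0, 0)), class = "pegs_insufficient_blanks")
})

test_that("one-tailed paired t test matches its closed form", {
  same <- paired_t_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 0.5)

  # d = (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, df = 2, p ~ 0.0371
  r <- paired_t_one_tailed(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$degrees_of_freedom, 2)
  expect_equal(r$p_value, 0.0371, tolerance = 1e-3)
  expect_equal(r$p_value, stats::pt(2 * sqrt(3), 2, lower.tail = FALSE))
  # agreement with stats::t.test as an independent route
  tt <- stats::t.test(c(1, 2, 3), c(0, 0, 0), paired = TRUE,
                      alternative = "greater")
  expect_equal(r$p_value, unname(tt$p.value), tolerance = 1e-12)

  # reversing the roles maps p to 1 - p
  rev <- paired_t_one_tailed(c(1, 2, 3), c(0, 0, 0))
  expect_equal(rev$p_value, 1 - r$p_value, tolerance = 1e-12)

  # zero-SD differences
  shift <- paired_t_one_tailed(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shift$p_value, 0)
  expect_error(paired_t_one_tailed(1, 2), class = "pegs_invalid_parameter")
  expect_error(paired_t_one_tailed(1:3, 1:4), class = "pegs_invalid_parameter")
})
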
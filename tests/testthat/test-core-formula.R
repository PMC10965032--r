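test_that("calibration returns k at the range midpoint and spans se*sqrt(3m)", {
  p <- nl_params()
  r <- size_range(15, 25)
  expect_equal(as.numeric(calibrate_k(p, r, 20)), 469.89)

  set.seed(42)
  for (i in 1:100) {
    pr <- random_params_and_range()
    mid <- (pr$range$l_min + pr$range$l_max) / 2
    expect_equal(as.numeric(calibrate_k(pr$params, pr$range, mid)),
                 pr$params$k, tolerance = 1e-9)
    spread <- as.numeric(calibrate_k(pr$params, pr$range, pr$range$l_min)) -
      as.numeric(calibrate_k(pr$params, pr$range, pr$range$l_max))
    expect_equal(spread, pr$params$se * sqrt(3 * pr$params$m),
                 tolerance = 1e-9)
  }
})

test_that("worked N. littoralis calibration agrees with the exact formula and the published rounded line", {
  p <- nl_params()
  r <- size_range(15, 25)
  exact <- 469.89 - 24.59 * sqrt(24) / 10 * 5
  expect_equal(as.numeric(calibrate_k(p, r, 25)), exact)
  # published coefficients are rounded to 2 dp; evaluating them at l = 25
  # lands within 0.15 ADD of the full-precision value
  printed <- 710.82 - 12.05 * 25
  expect_lt(abs(exact - printed), 0.15)
})

test_that("calibration is monotone, linear in l, and sign-aware", {
  p <- nl_params()
  r <- size_range(15, 25)
  l <- c(15, 18, 21, 25)
  neg <- as.numeric(calibrate_k(p, r, l))
  expect_true(all(diff(neg) < 0))
  pos <- as.numeric(calibrate_k(p, r, l, correlation_sign = "positive"))
  expect_true(all(diff(pos) > 0))

  a <- 0.3
  l1 <- 16.5; l2 <- 23
  expect_equal(
    as.numeric(calibrate_k(p, r, a * l1 + (1 - a) * l2)),
    a * as.numeric(calibrate_k(p, r, l1)) +
      (1 - a) * as.numeric(calibrate_k(p, r, l2))
  )
})

test_that("degenerate inputs: zero se returns k, out-of-range warns, zero-width range errors", {
  r <- size_range(15, 25)
  p0 <- thermal_summation_params(400, 0, 5)
  got <- calibrate_k(p0, r, c(15, 22))
  expect_equal(as.numeric(got), c(400, 400))
  expect_match(attr(got, "note"), "no calibration")

  p <- nl_params()
  expect_warning(out <- calibrate_k(p, r, c(14, 20)), "outside the size range")
  expect_identical(attr(out, "extrapolated"), c(TRUE, FALSE))
  # extrapolation continues the same line
  expect_equal(as.numeric(out)[1],
               predict(calibration_line(p, r), 14))

  expect_error(size_range(20, 20), "degenerate")
  expect_error(size_range(-1, 5))
})

test_that("sd of the true k follows se*sqrt(m)/2", {
  expect_equal(sd_true_k(0, 7), 0)
  expect_equal(sd_true_k(10, 4), 10)
  expect_equal(sd_true_k(24.59, 8), 24.59 * sqrt(8) / 2)
  expect_equal(round(sd_true_k(24.59, 8), 2), 34.78)
})

test_that("length sd approximation matches the uniform limit and converges for arithmetic sequences", {
  r <- size_range(15, 25)
  expect_equal(sd_length_approx(r), sqrt(3) * 10 / 6)
  expect_equal(round(sd_length_approx(r), 4), 2.8868)
  expect_equal(mean_length_approx(r), 20)
  expect_equal(mean_length_approx(size_range(1.3, 2.2)), 1.75)
  expect_equal(mean_length_approx(size_range(12, 22)), 17)

  # brute-force sd of n-point arithmetic sequences vs the closed form
  # (l_max - l_min) * sqrt((n+1) / (12 (n-1))), and convergence of the
  # approximation: the relative error shrinks like ~1/n and is below 1%
  # from about n = 101 points on
  errs <- sapply(c(5, 21, 101, 201), function(n) {
    s <- seq(15, 25, length.out = n)
    exact <- pop_sd(s)
    expect_equal(exact, 10 * sqrt((n + 1) / (12 * (n - 1))))
    abs(sd_length_approx(r) - exact) / exact
  })
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[2], 0.04)   # n = 21: still ~4.7% off
  expect_lt(errs[3], 0.01)   # n = 101
  expect_lt(errs[4], 0.01)   # n = 201
})

test_that("calibration lines reproduce published coefficients and agree with pointwise calibration", {
  ln <- calibration_line(nl_params(), size_range(15, 25))
  expect_equal(round(ln$intercept, 2), 710.82)
  expect_equal(round(-ln$slope, 2), 12.05)

  lc <- calibration_line(cm_params(), size_range(15, 25))
  expect_equal(round(lc$intercept, 2), 548.50)
  expect_equal(round(-lc$slope, 2), 7.17)

  set.seed(7)
  for (i in 1:20) {
    pr <- random_params_and_range()
    sgn <- sample(c("negative", "positive"), 1)
    line <- calibration_line(pr$params, pr$range, sgn)
    l <- runif(5, pr$range$l_min, pr$range$l_max)
    expect_equal(predict(line, l),
                 as.numeric(calibrate_k(pr$params, pr$range, l, sgn)))
  }
})

test_that("positive-correlation line for the parasitoid is computed from first principles", {
  p <- thermal_summation_params(4768.8, 431.5, 6, unit = "ADH")
  r <- size_range(1.3, 2.2)
  line <- calibration_line(p, r, "positive")
  mag <- 431.5 * sqrt(18) / 0.9
  expect_equal(round(line$slope, 1), 2034.1)
  expect_equal(line$intercept, 4768.8 - mag * 1.75)
  expect_equal(round(line$intercept, 1), 1209.1)
  # it passes through k at the midpoint, which a line with intercept
  # k + |slope| * midpoint and positive slope cannot do
  expect_equal(predict(line, 1.75), 4768.8)
  expect_equal(4768.8 + mag * 1.75, 8328.49, tolerance = 1e-5)
})

test_that("converting between ADD and ADH scales the whole line by 24", {
  p <- nl_params()
  r <- size_range(15, 25)
  p24 <- convert_unit(p, "ADH")
  expect_equal(p24$k, p$k * 24)
  l <- c(15, 19, 25)
  expect_equal(as.numeric(calibrate_k(p24, r, l)),
               24 * as.numeric(calibrate_k(p, r, l)))
  expect_equal(convert_unit(p24, "ADD")$se, p$se)
})
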
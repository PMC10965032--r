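make_records <- function(length_mm, true_k) {
  data.frame(species = "test", length_mm = length_mm, true_k = true_k,
             unit = "ADD")
}

test_that("length binning snaps to the half-mm grid and takes class medians", {
  rec <- make_records(c(15, 15.1, 14.9, 15.5, 15.6),
                      c(400, 410, 420, 500, 520))
  cl <- bin_by_length(rec)
  expect_equal(cl$length_mm, c(15, 15.5))
  expect_equal(cl$median_k, c(410, 510))
  expect_equal(cl$n, c(3L, 2L))

  # singletons: median is the value itself
  rec2 <- make_records(c(16, 17, 18), c(390, 380, 370))
  cl2 <- bin_by_length(rec2)
  expect_equal(cl2$n, rep(1L, 3))
  expect_equal(cl2$median_k, c(390, 380, 370))

  # half-up tie at the .25 midpoint
  expect_equal(snap_length(c(15.25, 15.75, 15.24)), c(15.5, 16.0, 15.0))

  # missing true k is excluded with a warning
  rec3 <- make_records(c(15, 15), c(400, NA))
  expect_warning(cl3 <- bin_by_length(rec3), "missing true k")
  expect_equal(cl3$n, 1L)

  # a dataset covering every half-mm from 15 to 24 yields 19 classes
  grid <- seq(15, 24, by = 0.5)
  cl4 <- bin_by_length(make_records(grid, 560 - 8 * grid))
  expect_equal(nrow(cl4), 19)
})

test_that("the three fitted models behave on constructed class patterns", {
  p <- nl_params()
  r <- size_range(12, 22)
  kc <- calibration_line(p, r)
  grid <- seq(12, 22, by = 0.5)

  # medians exactly on the calibration line: RMA recovers it, constant k worst
  cl <- bin_by_length(make_records(grid, predict(kc, grid)))
  ms <- fit_three_models(cl, p)
  expect_equal(ms$rma$slope, ms$kc$slope, tolerance = 1e-6)
  expect_equal(mse(cl, ms$kc), 0, tolerance = 1e-18)
  expect_equal(mse(cl, ms$rma), 0, tolerance = 1e-18)
  expect_gt(mse(cl, ms$constant), 1000)

  # flat medians at k: the constant model is exact, the calibrated line is not
  flat <- bin_by_length(make_records(grid, rep(p$k, length(grid)) +
                                       c(1e-9, rep(0, length(grid) - 1))))
  ms2 <- fit_three_models(flat, p)
  expect_lt(mse(flat, ms2$constant), 1e-18)
  expect_gt(mse(flat, ms2$kc), 1)

  expect_error(fit_three_models(bin_by_length(make_records(c(15, 16), c(2, 1))),
                                p), "at least 3")
})

test_that("mse is the unweighted mean of squared class residuals", {
  cl <- bin_by_length(make_records(c(15, 16), c(403, 399)))
  expect_equal(mse(cl, list(intercept = 400, slope = 0)), 5)  # (3^2 + 1^2)/2
  one <- bin_by_length(make_records(15, 403))
  expect_equal(mse(one, list(intercept = 400, slope = 0)), 9)
  expect_equal(mse(cl, list(intercept = 463, slope = -4)), 0)
})

test_that("the extreme subset keeps the tails defined by interpolated percentiles", {
  rec <- make_records(1:100, rnorm(100))
  sub <- extreme_subset(rec)
  # type-7 percentiles of 1..100: q33 = 33.67, q66 = 66.34
  expect_equal(unname(attr(sub, "thresholds")), c(33.67, 66.34))
  expect_equal(sub$length_mm, c(1:33, 67:100))

  expect_error(extreme_subset(make_records(rep(18, 10), rnorm(10))), "empty")

  # synthetic C. maxillosus emulation: thresholds land near the published
  # 19 and 21 mm cutoffs (consistency check only)
  rec2 <- generate_records(default_spec("C_maxillosus"), seed = 5)
  thr <- attr(extreme_subset(rec2), "thresholds")
  expect_gt(thr[["low"]], 17.5); expect_lt(thr[["low"]], 20)
  expect_gt(thr[["high"]], 19.5); expect_lt(thr[["high"]], 22)
})

test_that("ANOVA with LSD post hoc matches a from-scratch computation", {
  mk_err <- function(g1, g2, g3) {
    data.frame(model = rep(c("rma", "kc", "constant"),
                           times = c(length(g1), length(g2), length(g3))),
               sq_error = c(g1, g2, g3))
  }

  # three identical groups: no between-group signal at all
  same <- mk_err(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  cmp <- compare_models_anova(same)
  expect_equal(cmp$anova$F, 0)
  expect_equal(cmp$anova$p, 1)
  expect_equal(cmp$pairwise$p_adj, rep(1, 3))

  # textbook oracle on (1,2,3), (1,2,3), (7,8,9)
  groups <- list(c(1, 2, 3), c(1, 2, 3), c(7, 8, 9))
  orc <- anova_oracle(groups)
  cmp2 <- compare_models_anova(mk_err(groups[[1]], groups[[2]], groups[[3]]))
  expect_equal(cmp2$anova$F, orc$F)
  expect_equal(cmp2$anova$p, orc$p)
  # LSD t for the distant pair, from the pooled within-group variance
  t13 <- (2 - 8) / sqrt(orc$msw * (1 / 3 + 1 / 3))
  p13 <- 2 * pt(-abs(t13), orc$dfw)
  got <- cmp2$pairwise[cmp2$pairwise$t != 0, ]
  expect_equal(abs(got$t), rep(abs(t13), 2))
  expect_equal(got$p, rep(p13, 2))
  expect_equal(cmp2$pairwise$p_adj, bh_stepup(cmp2$pairwise$p))
  expect_true(all(cmp2$pairwise$p_adj >= cmp2$pairwise$p))
})

test_that("BH adjustment matches the closed-form step-up and ignores input order", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(21)
  for (i in 1:50) {
    p <- runif(3)
    expect_equal(p.adjust(p, "BH"), bh_stepup(p))
    perm <- sample(3)
    expect_equal(p.adjust(p, "BH")[perm], p.adjust(p[perm], "BH"))
  }
})

test_that("the full pipeline is deterministic and orders the models as expected", {
  rec <- generate_records(default_spec("N_littoralis"), seed = 1)
  p <- nl_params()
  a <- validate_models(rec, p, extremes = TRUE)
  b <- validate_models(rec, p, extremes = TRUE)
  expect_identical(a$mse, b$mse)
  expect_identical(a$pairwise, b$pairwise)

  full <- validate_models(rec, p)
  expect_lt(full$mse[["kc"]], full$mse[["constant"]])
  expect_lt(full$mse[["rma"]], full$mse[["constant"]])
  expect_null(full$thresholds)
  expect_false(is.null(a$thresholds))

  js <- comparison_json(a)
  expect_true(jsonlite::validate(js))
})

test_that("the RMA product loss beats other centroid lines of either sign", {
  rec <- generate_records(default_spec("N_littoralis"), seed = 8)
  cl <- bin_by_length(rec)
  x <- cl$length_mm; y <- cl$median_k
  f <- rma_fit(x, y)
  at_fit <- rma_loss(x, y, f)
  for (fac in c(-1.5, -1, -0.5, 0.5, 0.8, 1.2, 2)) {
    b <- f$slope * fac
    line <- list(slope = b, intercept = mean(y) - b * mean(x))
    expect_gte(rma_loss(x, y, line), at_fit - 1e-9)
  }
})
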
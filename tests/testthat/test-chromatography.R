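test_that("capacity factor is log10((t_r - t_0)/t_0) and rejects non-retained solutes", {
  expect_equal(capacity_factor(2.0, 1.0), 0.0)
  expect_equal(capacity_factor(11.0, 1.0), 1.0)
  expect_equal(capacity_factor(1.5, 1.0), log10(0.5))
  expect_error(capacity_factor(0.9, 1.0), "non-retained")
  expect_error(capacity_factor(1.0, 1.0), "non-retained")
  expect_error(capacity_factor(2.0, 0), "dead time")
  expect_error(capacity_factor(2.0, -1), "dead time")
  # strictly increasing in t_r at fixed t_0
  tr <- sort(runif(20, 1.1, 30))
  expect_true(all(diff(capacity_factor(tr, 1.0)) > 0))
})

test_that("calibration lines reproduce their printed coefficients and are exactly affine", {
  expect_identical(brlogd(0), 2.79)
  expect_equal(brlogd(-2.79 / 3.31), 0)
  expect_equal(brlogd(1), 6.10)
  expect_identical(clogkw_iam(0), -1.03)
  expect_equal(clogkw_iam(1.03 / 0.92), 0)
  expect_equal(clogkw_iam(2), 0.81)
  set.seed(11)
  for (f in list(brlogd, clogkw_iam)) {
    x <- rnorm(1)
    y <- rnorm(1)
    for (a in c(0, 0.25, 0.5, 0.8, 1)) {
      expect_equal(f(a * x + (1 - a) * y), a * f(x) + (1 - a) * f(y))
    }
  }
  expect_error(brlogd(NA_real_), "finite")
})

test_that("delta log kw IAM cancels the predicted baseline and flags excessive polarity", {
  expect_equal(delta_logkw_iam(2.0, 2.0), 2.0 - 0.81)
  expect_false(flag_excessive_polarity(delta_logkw_iam(2.0, 2.0)))
  expect_equal(delta_logkw_iam(2.4, 0.0), 2.4 - (-1.03))
  expect_true(flag_excessive_polarity(delta_logkw_iam(2.4, 0.0)))
  set.seed(21)
  b <- rnorm(25, 0, 3)
  d <- rnorm(25, 0, 2)
  expect_equal(delta_logkw_iam(clogkw_iam(b) + d, b), d)
})

test_that("retention line fitting is exact on collinear points and matches the closed-form OLS oracle", {
  ln <- fit_retention_line(c(50, 60, 70), c(-0.5, -1.0, -1.5))
  expect_equal(ln$slope, -0.05)
  expect_equal(ln$intercept, 2.0)
  expect_equal(ln$r2, 1)
  expect_identical(ln$n_points, 3L)

  set.seed(31)
  for (rep in 1:10) {
    a <- rnorm(1)
    b <- rnorm(1, 0, 0.05)
    x <- c(50, 60, 70)
    ln <- fit_retention_line(x, a + b * x)
    expect_equal(ln$slope, b, tolerance = 1e-12)
    expect_equal(ln$intercept, a, tolerance = 1e-10)
  }

  # noisy data: agreement with textbook least-squares formulas, and
  # recovery of the truth within 3 analytic standard errors
  set.seed(41)
  x <- c(50, 55, 60, 65, 70)
  a <- 2
  b <- -0.05
  sigma <- 0.01
  y <- a + b * x + rnorm(length(x), 0, sigma)
  ln <- fit_retention_line(x, y)
  orc <- ols_oracle(x, y)
  expect_equal(ln$slope, orc$slope, tolerance = 1e-12)
  expect_equal(ln$intercept, orc$intercept, tolerance = 1e-12)
  se_slope <- sigma / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(ln$slope - b), 3 * se_slope)

  expect_error(fit_retention_line(60, -1), "insufficient")
  expect_error(fit_retention_line(c(60, 60), c(-1, -1.1)), "insufficient")
})

test_that("log kw IAM extrapolation returns the fully aqueous intercept", {
  expect_equal(logkw_iam_extrapolate(c(10, 30, 50), c(2.9, 2.7, 2.5)), 3.0)
  expect_error(logkw_iam_extrapolate(30, 2.7), "insufficient")
  set.seed(51)
  x <- c(10, 20, 30, 40, 50)
  y <- 2.5 - 0.03 * x + rnorm(5, 0, 0.02)
  expect_lt(abs(logkw_iam_extrapolate(x, y) - 2.5), 0.06)
  # the extrapolation target is a parameter
  expect_equal(logkw_iam_extrapolate(c(10, 30, 50), c(2.9, 2.7, 2.5),
                                     target_fraction = 100),
               2.0)
})

test_that("Chamelogk is the measured 100% deviation from the 50-70% trend", {
  pts <- function(a, b) data.frame(organic_fraction = c(50, 60, 70),
                                   logk = a + b * c(50, 60, 70))
  expect_equal(chamelogk(pts(2, -0.05), 2 - 0.05 * 100), 0)
  expect_equal(chamelogk(pts(1.3, -0.041), 1.3 - 4.1 + 0.8), 0.8)
  # invariant to adding a constant to all four observations
  set.seed(61)
  for (k in c(-1, 0.5, 2)) {
    p <- pts(2, -0.05)
    p$logk <- p$logk + k
    expect_equal(chamelogk(p, 2 - 5 + 0.37 + k), 0.37)
  }
  expect_identical(classify_chameleon(0.65), "strong")
  expect_identical(classify_chameleon(0.5), "weak")
  # extra compositions ignored with a warning
  p4 <- rbind(pts(2, -0.05),
              data.frame(organic_fraction = 80, logk = 99))
  expect_warning(ch <- chamelogk(p4, -3), "ignoring")
  expect_equal(ch, 0)
  expect_error(chamelogk(pts(2, -0.05)[1:2, ], -3), "insufficient")
  expect_error(chamelogk(pts(2, -0.05), NA_real_), "insufficient")
})

test_that("ETR divides EPSA by TPSA with a guarded denominator", {
  x <- runif(5, 50, 300)
  expect_equal(etr(x, x), rep(1, 5))
  expect_equal(etr(140, 200), 0.7)
  expect_error(etr(120, 0), "denominator")
  expect_error(etr(-5, 100), ">= 0")
})

test_that("pH-retention profiles classify ionization", {
  expect_identical(ionization_class(c(`2` = 1.0, `7` = 1.0, `12` = 1.0)), "NEUTRAL")
  expect_identical(ionization_class(c(`2` = 0.2, `7` = 1.0, `12` = 1.0)), "BASE_IONIZED")
  expect_identical(ionization_class(c(`2` = 1.0, `7` = 0.9, `12` = 0.2)), "NEUTRAL")
  expect_identical(ionization_class(c(`2` = 0.2, `7` = 1.0, `12` = 0.2)), "AMPHOTERIC")
  expect_identical(ionization_class(c(`2` = 1.0, `7` = 0.5, `12` = 0.2)), "ACID_IONIZED")
  expect_warning(out <- ionization_class(c(`2` = 1.0, `7` = 1.0)), "incomplete")
  expect_identical(out, "UNDETERMINED")
})

test_that("compute_descriptors assembles the per-compound suite and rejects bad measurements", {
  cfg <- generator_config(seed = 5, n_compounds = 3, retention_noise_sd = 0)
  g <- gen_retention(cfg)
  meta <- data.frame(compound_id = g$truth$compound_id,
                     epsa = c(140, 150, 160), tpsa = c(200, 250, NA))
  d <- compute_descriptors(g$retention, meta)
  expect_equal(nrow(d), 3)
  expect_equal(d$brlogd, g$truth$brlogd_true, tolerance = 1e-10)
  expect_equal(d$chamelogk, rep(0.8, 3), tolerance = 1e-10)
  expect_equal(d$logkw_iam, g$truth$logkw_iam_true, tolerance = 1e-8)
  expect_equal(d$delta_logkw_iam, d$logkw_iam - d$clogkw_iam)
  expect_equal(d$etr[1:2], c(140 / 200, 150 / 250))
  expect_true(is.na(d$etr[3]))
  expect_identical(unique(d$ionization_class), "NEUTRAL")
  # a non-retained injection is rejected with a warning, not fatal
  bad <- g$retention
  bad$t_r[1] <- bad$t_0[1]
  expect_warning(d2 <- compute_descriptors(bad, meta), "rejected")
  expect_equal(nrow(d2), 3)
})
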
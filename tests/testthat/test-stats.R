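test_that("pearson matches the textbook formula and handles edge cases", {
  x <- c(1, 3, 4, 7, 9)
  y <- c(2, 3, 7, 8, 12)
  # hand computation: r = S_xy / sqrt(S_xx S_yy)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r_hand <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson(x, y)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$n, 5)
  # perfect linear relation
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  # independence: |r| small at n = 1e4
  set.seed(99)
  a <- rnorm(1e4)
  b <- rnorm(1e4)
  expect_lt(abs(pearson(a, b)$r), 0.05)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("noiseless regression recovers coefficients exactly", {
  d <- data.frame(leaf_order = rep(2:10, 3), uvi = 0)
  d$uvi <- d$leaf_order * 0.8 + rep(c(0, 1, 2), each = 9)
  d$y <- 1.5 + 0.3 * d$leaf_order + 0.6 * d$uvi
  names(d)[3] <- "resp"
  fit <- fit_regression(d, "resp")
  expect_equal(unname(fit$coefficients["lo"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["uvi"]), 0.6, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("standardized coefficients of orthogonal predictors equal marginal r", {
  set.seed(4)
  n <- 40
  lo_raw <- rnorm(n)
  uvi_raw <- rnorm(n)
  uvi_orth <- stats::resid(stats::lm(uvi_raw ~ lo_raw)) # exactly orthogonal
  y <- 0.7 * lo_raw + 0.4 * uvi_orth + rnorm(n, 0, 0.5)
  d <- data.frame(leaf_order = lo_raw, uvi = uvi_orth, y = y)
  fit <- fit_regression(d, "y")
  expect_equal(unname(fit$std_coefficients["lo"]),
    pearson(lo_raw, y)$r,
    tolerance = 1e-9
  )
  expect_equal(unname(fit$std_coefficients["uvi"]),
    pearson(uvi_orth, y)$r,
    tolerance = 1e-9
  )
})

test_that("standardizing variables first reproduces the standardized coefficients", {
  d <- synth_assays(seed = 21)
  fit <- fit_regression(d, "tpc")
  z <- function(v) (v - mean(v)) / stats::sd(v)
  dz <- data.frame(
    leaf_order = z(d$leaf_order), uvi = z(d$uvi), y = z(d$tpc)
  )
  fitz <- fit_regression(dz, "y")
  expect_equal(unname(fitz$coefficients[c("lo", "uvi")]),
    unname(fit$std_coefficients[c("lo", "uvi")]),
    tolerance = 1e-9
  )
})

test_that("rank-deficient designs raise a collinearity error", {
  d <- data.frame(leaf_order = 2:10, uvi = (2:10) * 2, y = rnorm(9))
  expect_error(fit_regression(d, "y"), "collinearity")
})

test_that("effect ratios compare absolute standardized coefficients", {
  fit <- structure(
    list(std_coefficients = c(lo = 0.16, uvi = 0.80)),
    class = "regression_fit"
  )
  expect_equal(effect_ratio(fit, "uvi", "lo"), 5.0)
  fit2 <- structure(
    list(std_coefficients = c(lo = 0.54, uvi = 0.53)),
    class = "regression_fit"
  )
  expect_equal(effect_ratio(fit2, "uvi", "lo"), 0.53 / 0.54)
  fit3 <- structure(
    list(std_coefficients = c(lo = 0.4, uvi = 0.4)),
    class = "regression_fit"
  )
  expect_equal(effect_ratio(fit3), 1.0)
  expect_error(effect_ratio(fit, "uvi", "nope"), "not in fit")
  fit4 <- structure(
    list(std_coefficients = c(lo = 0, uvi = 0.4)),
    class = "regression_fit"
  )
  expect_error(effect_ratio(fit4, "uvi", "lo"), "undefined ratio")
})

test_that("the saturating logistic fit recovers its generating surface", {
  set.seed(12)
  co <- default_assay_coefficients()
  d <- synth_assays(seed = 31)
  fit <- fit_regression(d, "rsa", link = "logistic-saturating",
                        rmax = co$rsa[["rmax"]])
  expect_gt(fit$r_squared, 0.5)
  # positive effects of both age and dose on the linear predictor
  expect_gt(fit$coefficients[["lo"]], 0)
  expect_gt(fit$coefficients[["uvi"]], 0)
})

test_that("distribution summaries use type-7 quartiles and Tukey fences", {
  s <- summarize_distribution(1:100, rep(1, 100))
  expect_equal(s$q1, 25.75)
  expect_equal(s$median, 50.5)
  expect_equal(s$q3, 75.25)
  # constant group: zero IQR, no outliers
  s2 <- summarize_distribution(rep(5, 10), rep(1, 10))
  expect_equal(s2$q3 - s2$q1, 0)
  expect_equal(s2$n_outliers, 0)
  # a planted outlier is caught
  s3 <- summarize_distribution(c(rnorm(50), 50), rep(1, 51))
  expect_gte(s3$n_outliers, 1)
  # bimodal group: median between the modes, wide IQR
  v <- c(rnorm(50, -10, 0.1), rnorm(50, 10, 0.1))
  s4 <- summarize_distribution(v, rep(1, 100))
  expect_gt(s4$median, -5)
  expect_lt(s4$median, 5)
  expect_gt(s4$q3 - s4$q1, 10)
  expect_warning(summarize_distribution(c(1, NA), c(1, 2)), "no values")
})

test_that("the shipped NPQ reference table is well formed", {
  npq <- npq_reference()
  expect_equal(npq$leaf_order, 2:10)
  expect_true(all(npq$npq_control > 0))
  expect_true(all(npq$npq_uvb > 0))
})
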
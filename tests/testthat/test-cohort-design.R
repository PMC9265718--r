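test_that("strata group days by year, month and weekday", {
  s <- build_strata(c("1992-04-06", "1992-04-13", "1992-05-04", "1993-04-05",
                      "1992-04-07"))
  expect_identical(s[1], s[2])        # two Mondays of April 1992
  expect_false(s[1] == s[3])          # Monday, different month
  expect_false(s[1] == s[4])          # Monday of April, different year
  expect_false(s[1] == s[5])          # Tuesday of the same month
  expect_error(build_strata("not-a-date"), "invalid")
})

test_that("every stratum over complete months 1990-2005 has 4 or 5 days", {
  days <- seq(as.Date("1990-01-01"), as.Date("2005-12-31"), by = "day")
  sizes <- table(build_strata(days))
  expect_true(all(sizes %in% c(4L, 5L)))
})

test_that("study day counting is inclusive and leap-aware", {
  expect_identical(study_day_count("1992-04-01", "2002-03-31"), 3652L)
  expect_identical(study_day_count("1992-04-01", "1992-04-01"), 1L)
  expect_identical(study_day_count("1996-02-01", "1996-03-01"), 30L)
  expect_error(study_day_count("2000-01-02", "2000-01-01"), "reversed")
})

test_that("lagging aligns counts with earlier covariates", {
  s <- small_series(seed = 5, n_days = 400)
  l0 <- lag_series(s, 0)
  expect_identical(nrow(l0), nrow(s))
  expect_identical(l0$exposure, s$exposure)
  l1 <- lag_series(s, 1)
  expect_identical(nrow(l1), nrow(s) - 1L)
  expect_identical(l1$exposure, s$exposure[-nrow(s)])
  expect_identical(l1$count, s$count[-1])
  l9 <- lag_series(s, 9)
  expect_identical(nrow(l9), nrow(s) - 9L)
  # stratum labels always come from the event day
  expect_identical(as.character(l9$stratum),
                   as.character(build_strata(s$date)[-(1:9)]))
  expect_error(lag_series(s, nrow(s)), "smaller")
  expect_error(lag_series(s, -1), "non-negative")
})

test_that("natural spline basis spans linear functions and is linear in the tails", {
  set.seed(31)
  x <- c(rnorm(200, 10, 4))
  B <- natural_spline_basis(x, df = 3)
  expect_identical(ncol(B), 3L)
  y <- 2 + 0.5 * x
  fit <- lm(y ~ B)
  expect_lt(max(abs(fitted(fit) - y)), 1e-8)
  # second differences vanish outside the boundary knots
  xo <- seq(max(x) + 1, max(x) + 11, by = 0.5)
  Bo <- predict(B, xo)
  co <- coef(lm(sin(x / 3) + rnorm(length(x), 0, 0.1) ~ B))
  curve_out <- drop(cbind(1, Bo) %*% co)
  expect_lt(max(abs(diff(diff(curve_out)))), 1e-8)
  # affine rescaling of x leaves the fitted values unchanged
  B2 <- natural_spline_basis(10 * x - 3, df = 3)
  yy <- sin(x / 4)
  expect_lt(max(abs(fitted(lm(yy ~ B)) - fitted(lm(yy ~ B2)))), 1e-8)
  expect_error(natural_spline_basis(rep(1, 50), df = 3), "degenerate")
})

test_that("lagged designs drop missing rows and uninformative strata", {
  s <- small_series(seed = 6, n_days = 400)
  s$exposure[50:60] <- NA
  s$temperature[100] <- NA
  suppressWarnings(d <- build_lagged_design(s, 2))
  expect_identical(d$n_dropped_na, 12L)
  expect_identical(length(d$y), nrow(s) - 2L - 12L - d$n_dropped_strata)
  # strata retained for fitting all have >= 2 rows and events
  expect_true(all(table(d$strata) >= 2))
  expect_true(all(tapply(d$y, d$strata, sum) > 0))
  expect_identical(d$r, max(d$z) - min(d$z))
})

test_that("daily series validation catches malformed inputs", {
  expect_error(daily_series("2000-01-01", -1, 10, 0, 50), "non-negative")
  expect_error(daily_series(c("2000-01-02", "2000-01-01"), c(1, 1), c(1, 1),
                            c(0, 0), c(50, 50)), "increasing")
  expect_error(daily_series("2000-01-01", 1, 10, 0, 150), "humidity")
  expect_warning(daily_series(c("2000-01-01", "2000-01-03"), c(1, 1), c(1, 1),
                              c(0, 0), c(50, 50)), "consecutive")
})

test_that("CSV round trip preserves the series and the truth sidecar", {
  s <- small_series(seed = 7, n_days = 120)
  s$exposure[3] <- NA
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_daily_series(s, csv, truth_path = js)
  s2 <- read_daily_series(csv)
  theta_true <- attr(s, "truth")$theta
  attr(s, "truth") <- NULL
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-12)
  truth <- jsonlite::read_json(js)
  expect_equal(truth$theta, theta_true)
})
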
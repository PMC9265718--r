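test_that("per-lag curves exponentiate to the published relative risks", {
  fa <- lag_fit(WORKED_BETAS_A[1], WORKED_SE_A, transform_spec("identity"),
                r = REF_RANGE, lag = 0)
  cu <- rr_curve(fa, 30)
  expect_equal(round(exp(cu$beta), 4), 1.0564)
  expect_equal(round(exp(cu$lower), 4), 1.0325)
  expect_equal(round(exp(cu$upper), 4), 1.0809)
  # zero slope: flat curve at RR 1
  f0 <- lag_fit(0, 1e-6, transform_spec("identity"), r = REF_RANGE, lag = 0)
  expect_true(all(exp(rr_curve(f0, 0:50)$beta) == 1))
  # envelope brackets the central curve for positive slopes
  zz <- seq(0, 60, by = 1)
  cc <- rr_curve(fa, zz)
  expect_true(all(cc$lower <= cc$beta & cc$beta <= cc$upper))
})

test_that("lag selection keeps exactly the positive slopes", {
  fits <- Map(function(b, L) lag_fit(b, WORKED_SE_A, transform_spec("identity"),
                                     r = REF_RANGE, lag = L),
              WORKED_BETAS_A, 0:9)
  keep <- select_lags(fits)
  expect_identical(vapply(fits[keep], function(f) f$lag, 0), as.numeric(0:8))
  neg <- lapply(fits, function(f) { f$beta <- -abs(f$beta) - 1e-6; f })
  expect_error(select_lags(neg), class = "crflag_no_positive_lags")
  zero <- fits
  zero[[1]]$beta <- 0
  expect_false(1 %in% select_lags(zero))   # beta = 0 is excluded
})

test_that("pooling an exact pooled-form curve is a fixed point", {
  zg <- seq(0, 80, length.out = 200)
  spec <- transform_spec("scaled_log", A = 20, mu = 12, tau = 0.02)
  f <- lag_fit(0.05, 0.004, spec, r = REF_RANGE, lag = 0)
  p <- pool_crf(list(rr_curve(f, zg)))
  expect_lt(p$central$rss, 1e-12)
  expect_equal(p$central$theta * log1p(30 / p$central$A) *
                 lwf(30, p$central$mu, p$central$tau, REF_RANGE),
               0.05 * apply_transform(30, spec, REF_RANGE), tolerance = 1e-6)
  # boundary fits reproduce the envelope curves too
  expect_lt(p$lower$rss, 1e-10)
  expect_lt(p$upper$rss, 1e-10)
})

test_that("pooled least squares is optimal against candidate parameter vectors", {
  zg <- seq(0, 70, length.out = 200)
  fits <- Map(function(b, L) lag_fit(b, WORKED_SE_A, transform_spec("identity"),
                                     r = REF_RANGE, lag = L),
              WORKED_BETAS_A[1:9], 0:8)
  curves <- lapply(fits, rr_curve, zgrid = zg)
  p <- pool_crf(curves, r = REF_RANGE)
  B <- vapply(curves, function(c) c$beta, numeric(length(zg)))
  rss <- function(th, A, mu, tau)
    sum((th * log1p(zg / A) * lwf(zg, mu, tau, REF_RANGE) - B)^2)
  expect_equal(p$central$rss,
               rss(p$central$theta, p$central$A, p$central$mu, p$central$tau),
               tolerance = 1e-8)
  set.seed(8)
  for (i in 1:25) {
    cand <- rss(runif(1, 0.001, 1), runif(1, 1, 200), runif(1, 0, 40),
                runif(1, 0.005, 2))
    expect_lte(p$central$rss, cand + 1e-9)
  }
  # independent oracle: for straight-line inputs the optimal pooled curve
  # is the line with the mean slope (the form can degenerate to linear)
  ideal <- sum((outer(zg, rep(mean(WORKED_BETAS_A[1:9]), 9)) -
                  outer(zg, WORKED_BETAS_A[1:9]))^2)
  expect_equal(p$central$rss, ideal, tolerance = 1e-4)
  ev <- evaluate_rr(p, 30)
  expect_equal(ev$rr, exp(mean(WORKED_BETAS_A[1:9]) * 30), tolerance = 1e-3)
})

test_that("pooled RR evaluates published parameter sets correctly", {
  p <- pooled_crf(WORKED_2C$central, WORKED_2C$lower, WORKED_2C$upper,
                  r = REF_RANGE)
  ev <- evaluate_rr(p, 30)
  expect_equal(ev$rr, 1.0387, tolerance = 0.001)
  expect_equal(ev$lower, 1.0240, tolerance = 0.002)
  expect_equal(ev$z, 30)
  # RR(0) = 1 exactly for the scaled-log family
  expect_identical(evaluate_rr(p, 0)$rr, 1)
  expect_error(evaluate_rr(p, -3), "non-negative")
})

test_that("pooled curves are non-decreasing whenever theta > 0", {
  zz <- seq(0, 90, length.out = 2000)
  set.seed(14)
  for (i in 1:30) {
    p <- pooled_crf(c(theta = runif(1, 1e-4, 5), A = runif(1, 0.1, 500),
                      mu = runif(1, -10, 60), tau = runif(1, 1e-4, 3)),
                    r = runif(1, 20, 90))
    expect_true(all(diff(evaluate_rr(p, zz)$rr) >= -1e-10))
  }
})

test_that("threshold detection matches the curve geometry", {
  p <- pooled_crf(WORKED_2C$central, r = REF_RANGE, zmax = 60)
  thr <- detect_threshold(p, epsilon = 0.005)
  expect_gte(thr, 9)
  expect_lt(thr, 13)    # the sigmoid turns on just above its mu ~ 13 ppb
  # flat curve: the whole grid is below tolerance
  p0 <- pooled_crf(c(theta = 0, A = 20, mu = 10, tau = 0.1), r = 50, zmax = 60)
  expect_equal(detect_threshold(p0, 0.005), 60)
  # a log-linear curve admits no threshold above zero as epsilon -> 0
  lin <- lag_fit(0.00183, WORKED_SE_A, transform_spec("identity"),
                 r = REF_RANGE, lag = 0)
  thr_lin <- detect_threshold(rr_curve(lin, seq(0, 60, by = 0.5)), 1e-9)
  expect_identical(thr_lin, 0)
  expect_error(detect_threshold(p, epsilon = 0), "epsilon")
})
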
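# Rate-extraction pipeline: normalisation, differences, Gaussian window,
# logistic fit, classification, population statistics.

test_that("normalisation modes behave as defined", {
  tr <- kinetic_trace(0:10, rep(4, 11))
  expect_equal(normalize_trace(tr, "to_point")$A, rep(1, 11))
  tr2 <- kinetic_trace(0:2, c(0, 5, 10))
  expect_equal(normalize_trace(tr2, "minmax")$A, c(0, 0.5, 1),
               tolerance = 1e-12)
  expect_error(normalize_trace(kinetic_trace(0:5, rep(0, 6)), "to_point"),
               "normalization")
})

test_that("difference series places raw differences at interval midpoints", {
  tr <- kinetic_trace(seq(0, 10, 2), 3 * seq(0, 10, 2) + 1)
  ds <- difference_series(tr)
  expect_equal(ds$d, rep(6, 5))       # slope 3 * dt 2
  expect_equal(ds$t, seq(1, 9, 2))
  expect_equal(difference_series(kinetic_trace(0:5, rep(2, 6)))$d, rep(0, 5))
  expect_error(difference_series(kinetic_trace(0:1, c(1, 2))), "3 samples")
})

test_that("difference maximum of a sampled logistic sits at the inflection", {
  t <- seq(0, 240, 3)
  tr <- logistic_trace(k = -0.05, x0 = 120, t = t)
  ds <- difference_series(tr)
  expect_lt(abs(ds$t[which.max(ds$d)] - 120), 3)
})

test_that("Gaussian difference fit recovers exact parameters and flags
           no-growth input", {
  x <- seq(0, 30, 0.5)
  d <- 2 * exp(-((x - 10) / 4)^2)
  g <- fit_gaussian_difference(data.frame(t = x, d = d))
  expect_true(g$converged)
  expect_equal(g$a1, 2, tolerance = 1e-6)
  expect_equal(g$b1, 10, tolerance = 1e-6)
  expect_equal(g$c1, 4, tolerance = 1e-6)
  expect_equal(g$f_half, 1, tolerance = 1e-6)
  z <- fit_gaussian_difference(data.frame(t = x, d = rep(0, length(x))))
  expect_false(z$converged)
})

test_that("Gaussian centre of logistic differences matches the midpoint", {
  t <- seq(0, 240, 3)
  g <- fit_gaussian_difference(difference_series(
    logistic_trace(k = -0.05, x0 = 120, t = t)))
  expect_true(g$converged)
  expect_lt(abs(g$b1 - 120), 3)
})

test_that("midpoint-to-decay inverts the Gaussian on its falling side", {
  g <- structure(list(a1 = 2, b1 = 10, c1 = 4, converged = TRUE, f_half = 1),
                 class = "gaussian_diff_fit")
  expect_equal(midpoint_to_decay(g, f = 2), 10)
  expect_equal(midpoint_to_decay(g, f = 1), 10 + 4 * sqrt(log(2)),
               tolerance = 1e-12)
  # numeric inversion oracle for the half-maximum crossing
  root <- uniroot(function(x) 2 * exp(-((x - 10) / 4)^2) - 1,
                  c(10, 40), tol = 1e-12)$root
  expect_equal(midpoint_to_decay(g, f = 1), root, tolerance = 1e-9)
  g0 <- g; g0$c1 <- 0
  expect_equal(midpoint_to_decay(g0, f = 0.5), 10)
  expect_error(midpoint_to_decay(g, f = 3), "f <= a1")
  gu <- g; gu$converged <- FALSE
  expect_error(midpoint_to_decay(gu), "unconverged")
})

test_that("logistic fit recovers exact parameters on the printed model", {
  t <- seq(0, 90, 3)
  tr <- logistic_trace(k = -0.1, x0 = 120, t = t)
  lf <- fit_logistic(tr, t_f = 90)
  expect_true(lf$converged)
  expect_equal(lf$rate, 0.1, tolerance = 1e-3)
  expect_error(fit_logistic(tr, t_f = 5), "window")
  flat <- fit_logistic(kinetic_trace(0:20, rep(3, 21)), t_f = 20)
  expect_false(flat$converged)
})

test_that("noisy replicates recover the printed buffer-scale rate constant", {
  set.seed(11)
  t <- seq(0, 200, 2)
  rates <- replicate(100, {
    tr <- logistic_trace(k = -0.092, x0 = 120, t = t, noise_sd = 0.02)
    estimate_rate(tr, fallback_t_f = 140)$rate
  })
  expect_lt(abs(mean(rates) - 0.092) / 0.092, 0.05)
})

test_that("estimate_rate runs the Gaussian-window path on simulated
           autocatalytic growth", {
  ts <- simulate_compartment_network(pen_params(), autocat_layout(0.41),
                                     1, 450, 3)
  tr <- traces_of_pop(ts, "population1")[[1]]
  rf <- estimate_rate(tr)
  expect_equal(rf$window_source, "gaussian")
  expect_false(rf$no_growth)
  expect_gt(rf$t_f, rf$gaussian$b1)  # window end is past the inflection
  # reference: logistic fit with the same window, run directly
  ref <- fit_logistic(tr, rf$t_f)
  expect_equal(rf$rate, ref$rate, tolerance = 0.1)
})

test_that("estimate_rate flags flat traces and falls back on truncated ones", {
  set.seed(2)
  flat <- kinetic_trace(seq(0, 150, 3), 100 + rnorm(51, 0, 2))
  rf <- estimate_rate(flat)
  expect_true(rf$no_growth)
  expect_equal(rf$rate, 0)
  # trace truncated before the inflection: Gaussian midpoint undefined
  t <- seq(0, 90, 3)
  tr <- logistic_trace(k = -0.05, x0 = 150, t = t)
  rf2 <- estimate_rate(tr)
  expect_equal(rf2$window_source, "fallback")
})

test_that("the fitted rate is invariant to affine scaling and time shift", {
  t <- seq(0, 240, 3)
  A <- 1 / (1 + exp(-0.07 * (t - 110)))
  r1 <- estimate_rate(kinetic_trace(t, A))$rate
  r2 <- estimate_rate(kinetic_trace(t, 50 + 700 * A))$rate
  expect_equal(r1, r2, tolerance = 1e-6)
  sh <- estimate_rate(kinetic_trace(t, 1 / (1 + exp(-0.07 * (t - 140)))))
  expect_equal(sh$rate, r1, tolerance = 1e-2)
  expect_gt(sh$x0, 135)
})

test_that("rate_fit behaves as a model object", {
  t <- seq(0, 240, 3)
  rf <- estimate_rate(logistic_trace(k = -0.07, x0 = 110, t = t))
  cf <- coef(rf)
  expect_equal(unname(cf["rate"]), 0.07, tolerance = 1e-4)
  expect_equal(predict(rf, newdata = c(110))[1], rf$L / 2, tolerance = 1e-4)
  expect_lt(max(abs(residuals(rf))), 1e-6)
  expect_output(print(rf), "rate")
  expect_output(summary(rf), "window")
})

test_that("profile classification separates flat, sigmoidal and pulse", {
  t <- seq(0, 300, 3)
  expect_equal(classify_profile(kinetic_trace(t, rep(7, length(t)))), "flat")
  expect_equal(classify_profile(logistic_trace(k = -0.05, x0 = 150, t = t)),
               "sigmoidal")
  pulse <- kinetic_trace(t, 100 + 50 * exp(-((t - 100) / 40)^2))
  expect_equal(classify_profile(pulse), "pulse")
  ts <- simulate_compartment_network(pen_params(), twonode_layout(8),
                                     50, 450, 3)
  expect_equal(classify_profile(traces_of_pop(ts, "population1")[[1]]),
               "pulse")
})

test_that("rate-vs-template regression matches the closed-form OLS oracle", {
  tmpl <- c(0.2, 0.4, 0.8, 1.6)
  fit <- suppressWarnings(rate_vs_template_slope(tmpl, 144.5 * tmpl))
  expect_equal(fit$slope, 144.5, tolerance = 1e-9)
  expect_lt(fit$stderr_slope, 1e-9)
  perm <- sample(4)
  fit2 <- suppressWarnings(rate_vs_template_slope(tmpl[perm], (144.5 * tmpl)[perm]))
  expect_equal(fit2$slope, fit$slope)
  set.seed(31)
  x <- runif(30, 0, 2); y <- 3 + 10 * x + rnorm(30, 0, 0.5)
  f <- rate_vs_template_slope(x, y)
  # closed-form OLS oracle
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  se <- sqrt(sum((y - (mean(y) + b * (x - mean(x))))^2) / 28 /
               sum((x - mean(x))^2))
  expect_equal(f$slope, b, tolerance = 1e-10)
  expect_equal(f$stderr_slope, se, tolerance = 1e-10)
  expect_lt(abs(f$slope - 10), 3 * f$stderr_slope)
  expect_error(rate_vs_template_slope(c(1, 1, 1), c(1, 2, 3)), "rank")
})

test_that("population kinetics aggregates profiles and Tukey box statistics", {
  t <- seq(0, 240, 3)
  same <- lapply(1:4, function(i) logistic_trace(k = -0.06, x0 = 100, t = t))
  pk <- population_kinetics(same)
  expect_equal(pk[[1]]$profile$sd, rep(0, length(t)))
  s <- pk[[1]]$summary
  expect_equal(s$q1, s$median)
  expect_equal(s$q3, s$median)
  bx <- penkit:::.box_stats(c(1, 2, 3, 4, 100))
  expect_equal(bx$median, 3)
  expect_equal(bx$outside_points, 100)
  expect_equal(bx$upper_adjacent, 4)
  # quantile/fence oracle on random data
  set.seed(5)
  for (i in 1:20) {
    v <- rexp(sample(10:200, 1))
    b <- penkit:::.box_stats(v)
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    expect_equal(c(b$q1, b$median, b$q3), q)
    fence <- 1.5 * (q[3] - q[1])
    expect_equal(sort(b$outside_points),
                 sort(v[v < q[1] - fence | v > q[3] + fence]))
    expect_true(b$lower_adjacent >= min(v) && b$upper_adjacent <= max(v))
  }
  expect_error(population_kinetics(list()), "empty")
})
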
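# Segmentation, trace extraction, size statistics and calibration.

px <- 0.65

test_that("segmentation recovers noiseless disks with tight geometry", {
  set.seed(1)
  s <- synthesize_image_stack(radii = rep(10, 6), traces = matrix(100, 6, 1),
                              pixel_size = px, frame_shape = c(256, 256),
                              seed = 3)
  rec <- segment_proteinosomes(s$stack[, , 1], pixel_size = px)
  expect_equal(nrow(rec), 6)
  expect_true(all(rec$circularity >= 0.9))
  expect_true(all(abs(2 * rec$radius_um - 20) <= px))
  # centroids within 1 px of the ground truth (match by nearest)
  for (i in seq_len(6)) {
    d <- sqrt((rec$x_um - s$truth$x_um[i])^2 +
              (rec$y_um - s$truth$y_um[i])^2)
    expect_lt(min(d), px)
  }
})

test_that("size and shape filters exclude out-of-range objects", {
  big <- render_frame(list(list(type = "disk", cx = 80, cy = 80, r = 20,
                                intensity = 100)))
  expect_equal(nrow(segment_proteinosomes(big, px)), 0)
  small <- render_frame(list(list(type = "disk", cx = 80, cy = 80, r = 5,
                                  intensity = 100)))
  expect_equal(nrow(segment_proteinosomes(small, px)), 0)
  # 3:1 ellipse with equivalent diameter 20 um: circularity ~ 0.66 < 0.7
  b <- 10 / sqrt(3)
  ell <- render_frame(list(list(type = "ellipse", cx = 80, cy = 80,
                                a = 3 * b, b = b, intensity = 100)))
  expect_equal(nrow(segment_proteinosomes(ell, px)), 0)
  # same ellipse passes when the circularity filter is relaxed
  rec <- segment_proteinosomes(ell, px, circularity_range = c(0.3, 1))
  expect_equal(nrow(rec), 1)
  expect_lt(rec$circularity, 0.7)
})

test_that("segmentation is invariant to positive scaling under Otsu and
           honours the filters actually passed", {
  set.seed(8)
  s <- synthesize_image_stack(radii = c(9, 10, 11),
                              traces = matrix(100, 3, 1),
                              pixel_size = px, frame_shape = c(256, 256),
                              noise_sd = 5, seed = 8)
  f <- s$stack[, , 1]
  r1 <- segment_proteinosomes(f, px)
  r2 <- segment_proteinosomes(f * 7.5, px)
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(r1$x_um, r2$x_um)
  expect_equal(r1$radius_um, r2$radius_um)
  for (dr in list(c(17, 25), c(10, 60), c(21, 23))) {
    rec <- segment_proteinosomes(f, px, diameter_range_um = dr,
                                 circularity_range = c(0.8, 1))
    if (nrow(rec)) {
      expect_true(all(2 * rec$radius_um >= dr[1] & 2 * rec$radius_um <= dr[2]))
      expect_true(all(rec$circularity >= 0.8 & rec$circularity <= 1))
    }
  }
})

test_that("degenerate frames give empty results, bad arguments error", {
  expect_equal(nrow(segment_proteinosomes(matrix(3, 64, 64), px)), 0)
  expect_error(segment_proteinosomes(matrix(1, 4, 4), -1), "pixel_size")
})

test_that("trace extraction returns the mean interior intensity per frame", {
  ramp <- c(0.5, 50, 100)
  s <- synthesize_image_stack(radii = 10, traces = matrix(ramp, 1, 3),
                              positions = matrix(c(60, 60), 1),
                              pixel_size = px, frame_shape = c(192, 192))
  rec <- segment_proteinosomes(s$stack[, , 3], pixel_size = px)
  expect_equal(nrow(rec), 1)
  trs <- extract_traces(s$stack, rec, frame_times = c(0, 3, 6))
  expect_equal(length(trs), 1)
  expect_equal(trs[[1]]$A, ramp, tolerance = 0.02)
  expect_equal(trs[[1]]$t, c(0, 3, 6))
})

test_that("extraction round-trips a simulated autocatalytic stack", {
  ts <- simulate_compartment_network(pen_params(), autocat_layout(0.81, n = 3),
                                     1, 300, 3)
  noise_sd <- 4
  s <- synthesize_image_stack(radii = rep(10, 3), traces = ts,
                              pixel_size = px, frame_shape = c(256, 256),
                              noise_sd = noise_sd, seed = 21,
                              frame_times = ts$time_grid)
  rec <- segment_proteinosomes(s$stack[, , dim(s$stack)[3]], pixel_size = px)
  expect_equal(nrow(rec), 3)
  trs <- extract_traces(s$stack, rec, frame_times = ts$time_grid)
  truth <- do.call(rbind, lapply(traces_of_pop(ts, "population1"),
                                 function(tr) tr$A))
  for (tr in trs) {
    i <- which.min(vapply(seq_len(3), function(j)
      sum(abs(truth[j, ] - tr$A)), numeric(1)))
    # noise term from mask averaging plus a 2% allowance for the
    # discretised mask boundary
    tol <- 3 * noise_sd / sqrt(min(rec$n_pixels)) + 0.02 * max(truth[i, ])
    expect_lt(max(abs(tr$A - truth[i, ])), tol)
  }
})

test_that("size statistics use the sample standard deviation", {
  s <- size_statistics(c(10, 10, 10))
  expect_equal(c(s$mean_radius, s$sd_radius, s$rsd), c(10, 0, 0))
  s2 <- size_statistics(c(12, 24, 36))
  expect_equal(s2$mean_radius, 24)
  expect_equal(s2$sd_radius, 12)   # n-1 denominator
  expect_equal(s2$rsd, 50)
  expect_equal(round(relative_sd(24.0, 11.4)), 48)
  one <- size_statistics(5)
  expect_true(one$flagged)
  expect_true(is.na(one$rsd))
})

test_that("size statistics converge to the generator's target", {
  r <- sample_proteinosome_population(5e4, 24.0, 48, "lognormal", seed = 13)
  s <- size_statistics(r, shape = "lognormal")
  expect_lt(abs(s$mean_radius - 24.0) / 24.0, 0.02)
  expect_lt(abs(s$rsd - 48), 2)
})

test_that("count calibration fits, inverts and matches the OLS oracle", {
  cal <- suppressWarnings(fit_calibration(c(10, 20, 40), c(100, 200, 400)))
  expect_equal(cal$slope, 10, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)
  expect_equal(estimate_proteinosome_count(250, cal), 25)
  expect_equal(estimate_proteinosome_count(120, cal), 12)
  expect_equal(estimate_proteinosome_count(cal$intercept, cal), 0)
  set.seed(9)
  n <- c(5, 10, 20, 40, 80, 160)
  fl <- 12 * n + 30 + rnorm(6, 0, 8)
  cal2 <- fit_calibration(n, fl)
  b <- sum((n - mean(n)) * (fl - mean(fl))) / sum((n - mean(n))^2)
  expect_equal(cal2$slope, b, tolerance = 1e-10)
  expect_lt(abs(cal2$slope - 12),
            3 * summary(cal2$lm)$coefficients["counts", "Std. Error"])
  expect_equal(estimate_proteinosome_count(predict(cal2, 33), cal2), 33,
               tolerance = 1e-9)
  expect_error(fit_calibration(c(5, 5, 5), c(1, 2, 3)), "rank")
})

test_that("total template concentration scales with the volume fraction", {
  expect_equal(total_template_concentration(0.005, 1), 0.6)
  expect_equal(total_template_concentration(0.01358, 1), 1.63, tolerance = 1e-3)
  expect_equal(total_template_concentration(0, 1), 0)
  expect_error(total_template_concentration(2, 1), "sample volume")
})
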
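# Mechanistic simulator and synthetic-data generators.

test_that("bulk reaction without template stays at baseline", {
  tr <- simulate_bulk_reaction(pen_params(), template_conc = 0,
                               primer0 = 0, duration = 60, dt = 1)
  expect_equal(tr$A, rep(pen_params()$F0, length(tr$t)))
  # with primer but no template there is no production: the residual
  # free-strand fluorescence can only decay
  tr2 <- simulate_bulk_reaction(pen_params(), 0, primer0 = 5,
                                duration = 60, dt = 1)
  expect_true(all(diff(tr2$A) <= 1e-12))
})

test_that("bulk reaction matches a fine-step forward-Euler oracle and is
           monotone without exonuclease", {
  p <- pen_params(E = 0)
  tr <- simulate_bulk_reaction(p, template_conc = 0.12, primer0 = 1,
                               duration = 30, dt = 0.5)
  expect_true(all(diff(tr$A) >= -1e-12))
  s_euler <- euler_bulk(p, 0.12, 1, 30, 0.5 / 100)
  A_euler <- fluor_of(s_euler[seq(1, length(s_euler), by = 100)], 0.12, p)
  expect_lt(max(abs(tr$A - A_euler) / pmax(A_euler, 1)), 0.005)
})

test_that("fluorescence gain is linear: doubling alpha doubles F - F0", {
  p1 <- pen_params(alpha = 1)
  p2 <- pen_params(alpha = 2)
  t1 <- simulate_bulk_reaction(p1, 0.12, 1, 30, 0.5)
  t2 <- simulate_bulk_reaction(p2, 0.12, 1, 30, 0.5)
  expect_equal(t2$A - p2$F0, 2 * (t1$A - p1$F0), tolerance = 1e-10)
})

test_that("integration rejects bad grids and layouts", {
  expect_error(simulate_bulk_reaction(pen_params(), 1, 1, 10, 2), "dt")
  expect_error(network_layout(list(list(node_kind = "autocatalytic",
                                        n_compartments = 1, radius_um = 10)),
                              volume_fraction = 1.2), "volume_fraction")
  expect_error(network_layout(list(), 0.5), "non-empty")
})

test_that("single isolated compartment reduces to the bulk model", {
  p <- pen_params(k_ex = 0)
  lay <- autocat_layout(0.6, n = 1)
  ts <- simulate_compartment_network(p, lay, primer0_outside = 1,
                                     duration = 60, dt = 0.5)
  bulk <- simulate_bulk_reaction(p, 0.12, 1, 60, 0.5)
  comp <- traces_of_pop(ts, "population1")[[1]]
  expect_equal(comp$A, bulk$A, tolerance = 1e-8)
})

test_that("fast exchange equalises compartment and bulk concentrations", {
  p <- pen_params(k_pol = 0.01, k_ex = 0.01 * 1000, E = 0.6)
  lay <- autocat_layout(0.6, n = 2)
  ts <- simulate_compartment_network(p, lay, primer0_outside = 5,
                                     duration = 10, dt = 0.1)
  s_in <- ts$truth$s2
  s_out <- ts$truth$s2_out
  sel <- s_out > 1e-6
  gap <- abs(sweep(s_in[sel, , drop = FALSE], 1, s_out[sel], "-")) /
    s_out[sel]
  expect_lt(max(gap), 0.01)
})

test_that("final signal responds monotonically to template and exonuclease", {
  Ts <- seq(0.04, 0.20, length.out = 5)   # T_in sweep (uM)
  Es <- seq(0.6, 9.6, length.out = 5)
  final <- matrix(NA_real_, 5, 5)
  for (i in seq_along(Ts)) for (j in seq_along(Es)) {
    lay <- network_layout(list(list(node_kind = "autocatalytic",
                                    T_in = Ts[i], n_compartments = 1,
                                    radius_um = 12.1)),
                          volume_fraction = 0.005)
    ts <- simulate_compartment_network(pen_params(E = Es[j]), lay, 1,
                                       duration = 150, dt = 3)
    final[i, j] <- utils::tail(traces_of_pop(ts, "population1")[[1]]$A, 1)
  }
  for (j in 1:5) expect_true(all(diff(final[, j]) >= -1e-6 * final[1, j]))
  for (i in 1:5) expect_true(all(diff(final[i, ]) <= 1e-6 * final[i, 1]))
})

test_that("simulated signals are non-negative and deterministic under a seed", {
  lay <- autocat_layout(0.6, n = 3)
  a <- simulate_compartment_network(pen_params(), lay, 1, 90, 3,
                                    seed = 42, noise_sd = 2)
  b <- simulate_compartment_network(pen_params(), lay, 1, 90, 3,
                                    seed = 42, noise_sd = 2)
  for (k in seq_along(a$traces)) {
    expect_identical(a$traces[[k]]$A, b$traces[[k]]$A)
    expect_true(all(a$traces[[k]]$A >= 0))
  }
})

test_that("radius sampling honours the requested mean, spread and shape", {
  expect_equal(sample_proteinosome_population(5, 12.1, 0, seed = 1),
               rep(12.1, 5))
  r <- sample_proteinosome_population(1e4, 12.1, 14, "normal", seed = 7)
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) - 12.1) / 12.1, 0.01)
  expect_lt(abs(100 * sd(r) / mean(r) - 14), 1)
  rl <- sample_proteinosome_population(2e4, 24.0, 48, "lognormal", seed = 7)
  expect_lt(abs(mean(rl) - 24.0) / 24.0, 0.02)
  expect_lt(abs(100 * sd(rl) / mean(rl) - 48), 2)
  expect_identical(sample_proteinosome_population(100, 10, 20, seed = 3),
                   sample_proteinosome_population(100, 10, 20, seed = 3))
})

test_that("image synthesis renders exact uniform disks with ground truth", {
  s <- synthesize_image_stack(radii = 10, traces = matrix(100, 1, 2),
                              positions = matrix(c(40, 40), 1),
                              pixel_size = 0.65, frame_shape = c(128, 128))
  frame <- s$stack[, , 1]
  xs <- (seq_len(128) - 0.5) * 0.65
  mask <- outer((xs - 40)^2, (xs - 40)^2, "+") <= 100
  expect_equal(sum(frame[mask]) / sum(mask), 100)
  expect_true(all(frame[!mask] == 0))
  expect_equal(s$truth$true_intensity, rep(100, 2))
  a <- synthesize_image_stack(radii = c(8, 8), traces = matrix(50, 2, 1),
                              pixel_size = 0.65, frame_shape = c(128, 128),
                              noise_sd = 3, seed = 5)
  b <- synthesize_image_stack(radii = c(8, 8), traces = matrix(50, 2, 1),
                              pixel_size = 0.65, frame_shape = c(128, 128),
                              noise_sd = 3, seed = 5)
  expect_identical(a$stack, b$stack)
})

test_that("image synthesis refuses impossible placements", {
  expect_error(synthesize_image_stack(radii = 60, traces = matrix(1, 1, 1),
                                      pixel_size = 0.65,
                                      frame_shape = c(128, 128)),
               "placement")
  expect_error(synthesize_image_stack(radii = rep(20, 12),
                                      traces = matrix(1, 12, 1),
                                      pixel_size = 0.65,
                                      frame_shape = c(128, 128), seed = 1),
               "placement")
})

test_that("FRAP synthesis produces the piecewise recovery with the stated
           plateau", {
  tg <- seq(0, 100, 0.5)
  syn <- synthesize_frap_trace(A = 0.8, tau = 5, immobile_fraction = 0.3,
                               t0 = 10, t_grid = tg)
  I <- syn$trace$I
  expect_true(all(I[tg < 10] == 1))
  expect_equal(I[tg == 10], 1 - 0.8, tolerance = 1e-12)
  expect_equal(utils::tail(I, 1), 1 - 0.3 * 0.8, tolerance = 1e-6)
  flat <- synthesize_frap_trace(A = 0, tau = 5, t0 = 10, t_grid = tg)
  expect_true(all(flat$trace$I == 1))
})
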
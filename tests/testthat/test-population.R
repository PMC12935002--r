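test_that("time-series aggregation matches brute-force mean, SEM and n", {
  m <- data.frame(ratio = c(0.1, 0.3, 0.5), frame = c(1, 1, 2),
                  compartment = "cytosol")
  s <- aggregate_timeseries(m, burn_in_hours = 0)
  f1 <- s[s$frame == 1, ]
  expect_equal(f1$mean_ratio, 0.2)
  # brute-force SEM: sqrt(sum((x - mean)^2) / (n - 1)) / sqrt(n)
  expect_equal(f1$sem, sqrt(((0.1 - 0.2)^2 + (0.3 - 0.2)^2) / 1) / sqrt(2))
  expect_equal(f1$sem, 0.1)
  expect_true(is.na(s$sem[s$frame == 2]))  # single object: SEM undefined
  expect_equal(s$n, c(2L, 1L))
})

test_that("burn-in of 3 h at 20-min frames flags the first 9 frames", {
  m <- data.frame(ratio = rep(0.2, 15), frame = 1:15, compartment = "c")
  s <- aggregate_timeseries(m, burn_in_hours = 3, frame_interval_min = 20)
  expect_equal(s$frame[s$burn_in], 1:9)
  expect_false(s$burn_in[s$frame == 10])  # t = 180 min is outside burn-in
})

test_that("aggregation is invariant to object relabeling", {
  set.seed(8)
  m <- data.frame(ratio = runif(60), frame = rep(1:3, 20),
                  compartment = rep(c("a", "b"), 30),
                  object_id = 1:60)
  shuffled <- m[sample(nrow(m)), ]
  shuffled$object_id <- rev(shuffled$object_id)
  expect_equal(aggregate_timeseries(m), aggregate_timeseries(shuffled))
})

test_that("empty groups warn and return an empty series", {
  m <- data.frame(ratio = NA_real_, frame = 1, compartment = "x")
  expect_warning(s <- aggregate_timeseries(m), "no defined ratios")
  expect_equal(nrow(s), 0)
})

test_that("ratio histograms count mass, overflow and undefined objects", {
  h <- ratio_histogram(rep(0.15, 10), bins = 30, range = c(0, 0.3))
  expect_equal(sum(h$table$count > 0), 1)
  expect_equal(sum(h$table$frequency), 1)

  x <- c(runif(50, 0, 0.29), 0.5, NA)
  h2 <- ratio_histogram(x, bins = 10, range = c(0, 0.3))
  expect_equal(h2$n_overflow, 1)
  expect_equal(h2$n_undefined, 1)
  expect_equal(sum(h2$table$count), 50)
  expect_equal(sum(h2$table$frequency), 50 / 51)  # overflow keeps its mass
  expect_error(ratio_histogram(x, bins = 0), "positive")
})

test_that("the bimodality detector separates mixtures from unimodal samples", {
  set.seed(99)
  x2 <- c(rnorm(250, 0.08, 0.02), rnorm(250, 0.25, 0.02))
  x1 <- rnorm(500, 0.15, 0.03)
  b2 <- detect_bimodality(x2)
  b1 <- detect_bimodality(x1)
  expect_equal(b2$n_components, 2L)
  expect_equal(b1$n_components, 1L)
  expect_equal(sum(b2$weights), 1)
  expect_true(all(diff(b2$means) > 0))
  expect_equal(b2$means, c(0.08, 0.25), tolerance = 0.1)

  # identical component means collapse to one mode
  set.seed(5)
  same <- c(rnorm(200, 0.15, 0.02), rnorm(200, 0.15, 0.02))
  expect_equal(detect_bimodality(same)$n_components, 1L)

  # determinism under a fixed seed
  expect_identical(detect_bimodality(x2, seed = 4),
                   detect_bimodality(x2, seed = 4))

  ins <- detect_bimodality(rnorm(10, 0.2, 0.01))
  expect_false(ins$sufficient)
  expect_true(is.na(ins$n_components))
})

test_that("the dip alternative agrees on clear cases", {
  set.seed(17)
  x2 <- c(rnorm(120, 0.08, 0.015), rnorm(120, 0.25, 0.015))
  x1 <- rnorm(240, 0.15, 0.03)
  expect_equal(detect_bimodality(x2, method = "dip")$n_components, 2L)
  expect_equal(detect_bimodality(x1, method = "dip")$n_components, 1L)
})

test_that("hysteresis assessment recovers a persistent post-return offset", {
  st <- strain_spec("carb", "carboxysome", n_cells = 1,
                    oxd_air = 0.9, oxd_high = 0.7,
                    oxd_return_offset = -0.05, start_offset = 0)
  sched <- data.frame(frame = c(1, 21, 41), condition = c("air", "high", "air"))
  sim <- simulate_population_series(st, n_objects = 150, n_frames = 70,
                                    co2_schedule = sched, seed = 12,
                                    ratio_noise_sd = 0.01)
  series <- aggregate_timeseries(sim, group_by = character(0))
  hy <- assess_hysteresis(series, shift_frame = 21, return_frame = 41,
                          window = 6)
  expected <- oxd_to_ratio(0.9) - oxd_to_ratio(0.85)
  expect_gt(hy$difference, 0)        # did not return to the pre-shift state
  expect_lt(hy$p_value, 0.05)
  expect_equal(hy$difference, expected, tolerance = 0.35)

  # a series that returns exactly to baseline shows no hysteresis
  st0 <- strain_spec("carb", "carboxysome", n_cells = 1,
                     oxd_air = 0.9, oxd_high = 0.7,
                     oxd_return_offset = 0, start_offset = 0)
  sim0 <- simulate_population_series(st0, n_objects = 150, n_frames = 70,
                                     co2_schedule = sched, seed = 12,
                                     ratio_noise_sd = 0.01)
  hy0 <- assess_hysteresis(aggregate_timeseries(sim0, group_by = character(0)),
                           shift_frame = 21, return_frame = 41, window = 6)
  expect_lt(abs(hy0$difference), abs(hy$difference) / 2)

  expect_error(assess_hysteresis(series, 21, 41, window = 40), "window")
})

test_that("group comparison reproduces the closed-form Student t", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  r <- compare_groups(a, b)
  # hand computation of the pooled two-sample t statistic
  sp2 <- ((3 - 1) * stats::var(a) + (3 - 1) * stats::var(b)) / (3 + 3 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t, t_hand)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * stats::pt(-abs(t_hand), df = 4))

  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  set.seed(2)
  apart <- compare_groups(rnorm(4, 0, 1e-3), 1 + rnorm(4, 0, 1e-3))
  expect_lt(apart$p_value, 0.05)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("star annotations follow the configured thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 5e-4, 5e-5)), c("ns", "*", "**", "***"))
})
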
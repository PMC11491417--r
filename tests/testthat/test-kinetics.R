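test_that("the leaching curve honours its limits and closed form", {
  m <- leaching_model(A = 31, B = 0.6, C = 0.4, k1 = 0.5, k2 = 0.05)
  expect_equal(evaluate_leaching(m, 0), 0)               # B + C = 1
  expect_equal(evaluate_leaching(m, 1e7), 31)            # plateau
  expect_equal(evaluate_leaching(m, 10),
               31 * (1 - 0.6 * exp(-5) - 0.4 * exp(-0.5)))
  expect_error(evaluate_leaching(m, -2), "t must be")
  expect_error(leaching_model(31, 0.6, 0.4, 0.05, 0.5), "k1 >= k2")
  expect_error(leaching_model(-1, 0.6, 0.4, 0.5, 0.05), "A must be")
})

test_that("noiseless bi-exponential data are recovered exactly", {
  truth <- leaching_model(A = 25, B = 0.7, C = 0.3, k1 = 0.8, k2 = 0.08)
  ser <- simulate_leaching_series(truth, seq(0.5, 92, by = 1), sd = 0)
  fit <- fit_leaching(ser, n_starts = 20, seed = 1)
  m <- fit$model
  expect_equal(m$A, 25, tolerance = 1e-4)
  expect_equal(m$B, 0.7, tolerance = 1e-4)
  expect_equal(m$C, 0.3, tolerance = 1e-4)
  expect_equal(m$k1, 0.8, tolerance = 1e-4)
  expect_equal(m$k2, 0.08, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("refitting the model to its own predictions is a fixed point", {
  truth <- leaching_model(A = 31, B = 0.6, C = 0.4, k1 = 0.5, k2 = 0.05)
  pred <- data.frame(time = 1:92,
                     concentration = evaluate_leaching(truth, 1:92))
  fit <- fit_leaching(pred, n_starts = 20, seed = 2)
  refit <- fit_leaching(data.frame(
    time = 1:92,
    concentration = evaluate_leaching(fit$model, 1:92)
  ), n_starts = 20, seed = 3)
  for (p in c("A", "B", "C", "k1", "k2")) {
    expect_equal(refit$model[[p]], fit$model[[p]], tolerance = 1e-6)
  }
  # the fitted plateau is the asymptote
  expect_lt(abs(evaluate_leaching(fit$model, 9200) - fit$model$A),
            1e-6 * fit$model$A)
})

test_that("canonical ordering resolves the label-swap symmetry", {
  a <- leaching_model(31, 0.6, 0.4, 0.5, 0.05)
  # swapping (B,k1) and (C,k2) leaves predictions identical
  t <- seq(0, 50, by = 0.5)
  swapped <- 31 * (1 - 0.4 * exp(-0.05 * t) - 0.6 * exp(-0.5 * t))
  expect_equal(evaluate_leaching(a, t), swapped)
  # the fitter always reports k1 >= k2
  ser <- simulate_leaching_series(a, 1:60, sd = 0.3, seed = 6)
  fit <- fit_leaching(ser, n_starts = 10, seed = 6)
  expect_gte(fit$model$k1, fit$model$k2)
})

test_that("a mono-exponential truth is flagged by the nested comparison", {
  mono_truth <- leaching_model(20, 1, 0, 0.3, 0.299)  # C = 0: single phase
  ser <- simulate_leaching_series(mono_truth, 1:92, sd = 0.4, seed = 12)
  fit <- fit_leaching(ser, n_starts = 20, seed = 12)
  expect_false(is.null(fit$mono))
  # the richer model can only lower the RSS
  expect_lte(fit$rss, fit$mono$rss + 1e-9)
  # and the comparison prefers the mono-exponential description
  expect_true(fit$mono$preferred)
})

test_that("plateau recovery holds at 5% noise on hourly sampling", {
  truth <- fig4_truth()
  ok <- 0
  for (s in 1:25) {
    ser <- simulate_leaching_series(truth, 1:92, sd = 0.05, seed = 900 + s,
                                    noise_type = "proportional")
    fit <- fit_leaching(ser, n_starts = 20, seed = 900 + s)
    ok <- ok + (abs(fit$model$A - 31) / 31 < 0.1)
  }
  expect_gte(ok / 25, 0.9)
})

test_that("condition comparison reports rate and time ratios", {
  truth <- fig4_truth()
  ser <- simulate_leaching_series(truth, 1:92, sd = 0)
  fit_a <- fit_leaching(ser, n_starts = 10, seed = 1)
  # identical fits: all ratios 1
  self <- compare_conditions(fit_a, fit_a)
  expect_equal(self$rate_ratio, 1)
  expect_equal(self$time_ratio, 1)
  expect_equal(self$plateau_ratio, 1)
  # rates scaled by 5 -> time to 90% scaled by 1/5
  fast <- leaching_model(31, 0.6, 0.4, 5 * 0.5, 5 * 0.05)
  ser_b <- simulate_leaching_series(fast, seq(0.2, 20, by = 0.2), sd = 0)
  fit_b <- fit_leaching(ser_b, n_starts = 10, seed = 2)
  cmp <- compare_conditions(fit_a, fit_b)
  expect_equal(cmp$time_ratio, 1 / 5, tolerance = 1e-3)
  # accelerated condition (rates >= 10x, 60C-like) plateaus within hours
  hot <- leaching_model(31, 0.6, 0.4, 20 * 0.5, 20 * 0.05)
  expect_lt(time_to_fraction(hot, 0.9), 2)
  expect_gt(time_to_fraction(truth, 0.9), 10)
  bad <- fit_a; bad$converged <- FALSE
  expect_error(compare_conditions(bad, fit_b), "converged")
})
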
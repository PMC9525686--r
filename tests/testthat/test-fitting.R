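# descriptive and mechanistic fits: round trips, calibration, R^2

test_that("joint DoG fit recovers noiseless generative parameters", {
  th <- seq(-45, 45, 5)
  truth <- list(a = 0.37, m = 0, s = 28.4, b = -0.9,
                scatter_a = -5.3, scatter_m = -10, scatter_b = 13.2)
  s <- data.frame(
    theta = th,
    bias = truth$a * (th - truth$m) * exp(-(th - truth$m)^2 / truth$s^2) +
      truth$b,
    scatter = truth$scatter_a * exp(-(th - truth$scatter_m)^2 / truth$s^2) +
      truth$scatter_b)
  fit <- fit_dog(s)
  for (p in names(truth)) {
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6, label = p)
  }
  expect_true(fit$converged)
  expect_lt(fit$sse_bias + fit$sse_scatter, 1e-12)
})

test_that("DoG fit handles flat data, reordering and target shifts", {
  th <- seq(-45, 45, 5)
  flat <- data.frame(theta = th, bias = 0)
  f <- fit_dog(flat, include_scatter = FALSE)
  expect_lt(abs(f$a), 1e-6)
  expect_lt(abs(f$b), 1e-6)

  set.seed(3)
  s <- data.frame(theta = th,
                  bias = 0.3 * th * exp(-th^2 / 25^2) + rnorm(19, 0, 0.3))
  f1 <- fit_dog(s, include_scatter = FALSE)
  f2 <- fit_dog(s[sample.int(19), ], include_scatter = FALSE)
  expect_equal(f2$a, f1$a, tolerance = 1e-6)
  expect_equal(f2$m, f1$m, tolerance = 1e-5)

  expect_error(fit_dog(s[1:4, ], include_scatter = FALSE),
               "at least 6 distinct offsets")

  # pinning the centre via `fixed` constrains the fit
  f3 <- fit_dog(s, include_scatter = FALSE, fixed = list(m = 5))
  expect_equal(f3$m, 5)
})

test_that("reliability calibration averages the extreme offsets", {
  th <- seq(-45, 45, 5)
  s <- data.frame(theta = th, scatter = ifelse(abs(th) >= 30, 13.2, 8))
  expect_equal(estimate_reliability(s), 13.2)
  s$scatter <- ifelse(abs(th) >= 30, 10.0, 8)
  expect_equal(estimate_reliability(s), 10.0)
  s$scatter <- ifelse(th >= 30, 14, ifelse(th <= -30, 12, 8))
  expect_equal(estimate_reliability(s), 13.0)
  expect_error(estimate_reliability(data.frame(theta = 0, scatter = 8)),
               "no offsets")
})

test_that("regression to the mean comes from the target-mean separation", {
  expect_equal(regression_to_mean(50.5, 37.2), 0.665)
  expect_equal(round_half_up(regression_to_mean(50.5, 37.2), 2), 0.67)
  expect_equal(regression_to_mean(55, 35), 1)
  expect_equal(regression_to_mean(45, 45), 0)
})

test_that("R^2 follows its definition", {
  expect_equal(r_squared(1:5, 1:5), 1)
  obs <- c(2, 4, 9, 1)
  expect_equal(r_squared(rep(mean(obs), 4), obs), 0)
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_warning(r2 <- r_squared(c(1, 2, 3), c(2, 2, 2)), "zero total")
  expect_true(is.na(r2))
})

test_that("alpha fit is exact on noiseless curves and flags degenerate data", {
  th <- seq(-45, 45, 5)
  io <- ideal_observer_params(13.2, 10, rho = 0.665, alpha = 0.7)
  s <- data.frame(theta = th, bias = predicted_bias(th, io),
                  scatter = predicted_scatter(th, io))
  fit <- fit_alpha(s, 13.2, 10, 0.665)
  expect_equal(fit$alpha, 0.7, tolerance = 1e-6)
  expect_equal(fit$r2_bias, 1)
  expect_equal(fit$r2_scatter, 1)

  s0 <- data.frame(theta = th, bias = 0)
  expect_warning(f0 <- fit_alpha(s0, 13.2, 10, 0.665), "degenerate")
  expect_equal(f0$alpha, 0)
  expect_false(f0$converged)
})

test_that("alpha recovery from synthetic trials at moderate n", {
  spec <- small_yoked_spec(n_per_cell = 30, n_obs = 10, seed = 6)
  tr <- simulate_experiment(spec, clean_params())
  s <- summarize_conditions(tr)
  fit <- fit_alpha(s, 13.2, 10, 0.665)
  expect_lt(abs(fit$alpha - 0.7), 0.1)
  expect_gt(fit$r2_bias, 0.5)
})

test_that("beta/gamma fit round-trips and flags unidentifiable gamma", {
  th <- seq(-45, 45, 5)
  cp <- causal_inference_params(13.2, 10, rho = 0.665, beta = 0.71,
                                gamma = 1.51)
  s <- data.frame(theta = th, bias = ci_bias(th, cp),
                  scatter = ci_scatter(th, cp))
  fit <- fit_beta_gamma(s, 13.2, 10, 0.665)
  expect_equal(fit$beta, 0.71, tolerance = 1e-4)
  expect_equal(fit$gamma, 1.51, tolerance = 1e-4)
  expect_true(fit$converged)

  s0 <- data.frame(theta = th, bias = rep(0, 19),
                   scatter = rep(13.2, 19))
  expect_warning(f0 <- fit_beta_gamma(s0, 13.2, 10, 0.665),
                 "not identifiable")
  expect_lt(f0$beta, 1e-3)
  expect_false(f0$converged)
})

test_that("beta/gamma recovery from synthetic trials at moderate n", {
  spec <- small_yoked_spec(n_per_cell = 30, n_obs = 10, seed = 61)
  tr <- simulate_experiment(spec, clean_params("causal_inference"))
  s <- summarize_conditions(tr)
  fit <- fit_beta_gamma(s, 13.2, 10, 0.665)
  expect_lt(abs(fit$beta - 0.71), 0.15)
  expect_lt(abs(fit$gamma - 1.51), 0.4)
})
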
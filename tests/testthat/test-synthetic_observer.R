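# design generation and the generative response models

test_that("designs have the factorial cell structure", {
  spec <- design_spec("yoked", n_trials_per_cell = 1, n_observers = 1,
                      seed = 3)
  d <- make_design(spec)
  expect_equal(nrow(d), 19 * 2 * 2)     # offsets x targets x conditions
  expect_setequal(unique(d$flanker_offset1), seq(-45, 45, 5))
  expect_true(all(d$flanker_offset1 == d$flanker_offset2))
  expect_error(design_spec("yoked", n_trials_per_cell = 0),
               ">= 1")
  expect_error(design_spec("yoked", offsets = c(-45, 40)), "symmetric")
})

test_that("locked-flanker designs pin exactly one flanker at +15", {
  spec <- design_spec("locked_flanker", n_trials_per_cell = 2,
                      n_observers = 2, seed = 4)
  d <- make_design(spec)
  locked_off <- ifelse(d$locked_flanker == 1, d$flanker_offset1,
                       d$flanker_offset2)
  variable_off <- ifelse(d$locked_flanker == 1, d$flanker_offset2,
                         d$flanker_offset1)
  expect_true(all(locked_off == 15))
  expect_setequal(unique(variable_off), seq(-45, 45, 5))
  expect_true(all(d$locked_flanker %in% c(1, 2)))
})

test_that("designs and simulations are reproducible under the seed", {
  spec <- small_yoked_spec(n_per_cell = 2, n_obs = 2, seed = 11)
  expect_identical(make_design(spec), make_design(spec))
  expect_identical(simulate_experiment(spec, clean_params()),
                   simulate_experiment(spec, clean_params()))
  spec2 <- small_yoked_spec(n_per_cell = 2, n_obs = 2, seed = 12)
  d1 <- make_design(spec)
  d2 <- make_design(spec2)
  expect_false(identical(d1$flanker_offset1, d2$flanker_offset1))
  # same cells, different permutation
  expect_equal(sort(d1$flanker_offset1), sort(d2$flanker_offset1))
})

test_that("degenerate null model reproduces the target exactly", {
  rel <- data.frame(target_aspect = 1.4, sigma_t = 0, sigma_f = 0)
  p <- generative_params("null", reliability = rel, rho = 1,
                         rt_outlier_rate = 0, gross_error_rate = 0)
  spec <- small_yoked_spec(n_per_cell = 1, n_obs = 1, seed = 2)
  tr <- simulate_experiment(spec, p)
  expect_equal(tr$response_ori, tr$target_ori)
})

test_that("ideal-observer cells match the closed-form bias and scatter", {
  spec <- small_yoked_spec(n_per_cell = 200, n_obs = 10, seed = 8)
  tr <- simulate_experiment(spec, clean_params())
  s <- summarize_conditions(tr)
  io <- ideal_observer_params(13.2, 10, rho = 0.665, alpha = 0.7)
  expect_true(all(abs(s$bias - predicted_bias(s$theta, io)) < 0.6))
  expect_true(all(abs(s$scatter - predicted_scatter(s$theta, io)) < 0.6))
  # flankers at the target pull nothing
  expect_lt(abs(s$bias[s$theta == 0]), 0.6)
})

test_that("causal-inference cells match the gated closed forms", {
  spec <- small_yoked_spec(n_per_cell = 200, n_obs = 10, seed = 9)
  tr <- simulate_experiment(spec, clean_params("causal_inference"))
  s <- summarize_conditions(tr)
  cp <- causal_inference_params(13.2, 10, rho = 0.665, beta = 0.71,
                                gamma = 1.51)
  expect_true(all(abs(s$bias - ci_bias(s$theta, cp)) < 0.6))
  expect_true(all(abs(s$scatter - ci_scatter(s$theta, cp)) < 0.6))
})

test_that("pooled generative bias is antisymmetric in the offset", {
  for (model in c("ideal_observer", "causal_inference",
                  "independent_flanker")) {
    spec <- small_yoked_spec(n_per_cell = 150, n_obs = 8, seed = 21,
                             offsets = c(-30, -15, 15, 30))
    tr <- simulate_experiment(spec, clean_params(model))
    s <- summarize_conditions(tr)
    pos <- s$bias[match(c(15, 30), s$theta)]
    neg <- s$bias[match(c(-15, -30), s$theta)]
    expect_true(all(abs(pos + neg) < 1.0), label = model)
  }
})

test_that("null-model scatter recovers the generative sigma", {
  spec <- small_yoked_spec(n_per_cell = 30, n_obs = 10, seed = 14)
  tr <- simulate_experiment(spec, clean_params("null"))
  expect_gt(nrow(tr), 5000)
  s <- summarize_conditions(tr)
  expect_lt(abs(mean(s$scatter) - 13.2), 0.3)
})

test_that("control conditions share the unflanked scatter level", {
  spec <- design_spec("control", conditions = rounded_condition,
                      n_trials_per_cell = 40, n_observers = 8, seed = 25)
  ctrl <- simulate_experiment(spec, clean_params())
  s <- summarize_conditions(ctrl,
                            grouping = c("experiment_id", "flanker_kind"))
  s_ort <- s$scatter[s$flanker_kind == "orthogonal"]
  s_abs <- s$scatter[s$flanker_kind == "absent"]
  expect_lt(abs(s_ort - s_abs), 0.5)
  # parallel flankers at theta = 0 integrate and so improve precision
  spec2 <- small_yoked_spec(n_per_cell = 80, n_obs = 8, seed = 26,
                            offsets = 0)
  par0 <- summarize_conditions(simulate_experiment(spec2, clean_params()))
  expect_lt(par0$scatter + 1, min(s_ort, s_abs))
})

test_that("the spacing fall-off follows the critical-spacing profile", {
  nd <- normalized_distance(c(5.5, 7.5, 11, 16.6), 26)
  f <- default_spacing_falloff(nd)
  expect_equal(f[1], 1, tolerance = 1e-3)
  expect_lt(abs(f[2] - 0.8), 0.05)
  expect_lt(abs(f[3] + 0.1), 0.02)
  expect_equal(f[4], 0)
  expect_true(all(diff(default_spacing_falloff(seq(0, 0.4, 0.01))) <= 0))
})

test_that("lapses land mostly outside the gross-error criterion", {
  rel <- data.frame(target_aspect = 1.4, sigma_t = 0.01, sigma_f = 0.01)
  p <- generative_params("null", reliability = rel, rho = 1,
                         lapse_rate = 1, rt_outlier_rate = 0,
                         gross_error_rate = 0)
  spec <- small_yoked_spec(n_per_cell = 5, n_obs = 4, seed = 33)
  tr <- simulate_experiment(spec, p)
  expect_true(all(tr$response_ori >= 0 & tr$response_ori <= 90))
  # uniform lapses on (0,90) exceed the 35 deg criterion for ~22% of
  # draws at these targets
  err <- abs(tr$response_ori - tr$target_ori)
  expect_gt(mean(err > 35), 0.15)
})
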
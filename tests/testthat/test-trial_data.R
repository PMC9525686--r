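# trial-table I/O, exclusion filters, condition summaries

test_that("read_trials derives offsets and applies a column dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subj,targ,f1,f2,resp,rt",
               "o1,35,50,50,38,1.2",
               "o1,55,40,40,52,0.8",
               "o2,35,20,20,30,1.5"), path)
  tr <- read_trials(path, dialect = c(observer_id = "subj",
                                      target_ori = "targ",
                                      flanker1_ori = "f1",
                                      flanker2_ori = "f2",
                                      response_ori = "resp",
                                      response_time = "rt"))
  expect_equal(nrow(tr), 3)
  expect_equal(tr$flanker_offset1, c(15, -15, -15))
  expect_equal(tr$flanker_offset2, c(15, -15, -15))
})

test_that("read_trials reports missing columns, empty files, bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("observer_id,target_ori", "o1,35"), path)
  expect_error(read_trials(path), "missing required column.*response_ori")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("observer_id,target_ori,response_ori", empty)
  expect_error(read_trials(empty), "empty trial table")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("observer_id,target_ori,flanker1_ori,flanker2_ori,response_ori",
               "o1,35,50,50,38", "o1,oops,50,50,38"), bad)
  expect_warning(tr <- read_trials(bad), "unparseable.*rows 2")
  expect_equal(nrow(tr), 1)
})

test_that("write/read round trip preserves a seeded table bit for bit", {
  spec <- small_yoked_spec(n_per_cell = 2, n_obs = 2, seed = 31)
  tr <- simulate_experiment(spec, clean_params())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  for (col in names(tr)) {
    expect_identical(back[[col]], tr[[col]], label = col)
  }
})

test_that("filters count sequentially and retain boundary values", {
  rt <- c(rep(1, 7), 3.5, 3.5, 1)
  resp <- c(rep(0, 9), 40) + 35       # last survivor has error 40
  tr <- tiny_trials(resp, rt = 1)
  tr$response_time <- rt
  out <- filter_trials(tr)
  expect_equal(out$report$n_rt_removed, 2)
  expect_equal(out$report$n_error_removed, 1)
  expect_equal(out$report$n_retained, 7)
  expect_equal(out$report$n_input, 10)

  # boundaries are retained: exactly 0.5 s, 3.0 s, 35 deg
  tb <- tiny_trials(c(35 + 35, 35 - 35, 35))
  tb$response_time <- c(0.5, 3.0, 1)
  outb <- filter_trials(tb)
  expect_equal(outb$report$n_retained, 3)
  expect_equal(outb$report$fraction_rt_removed, 0)
  expect_equal(outb$report$fraction_error_removed, 0)
})

test_that("filtering is idempotent and requires response times", {
  spec <- small_yoked_spec(seed = 13)
  tr <- simulate_experiment(spec, generative_params("null"))
  once <- filter_trials(tr)
  twice <- filter_trials(once$trials)
  expect_identical(twice$trials, once$trials)
  expect_equal(twice$report$n_rt_removed, 0)
  expect_equal(twice$report$n_error_removed, 0)

  tr$response_time <- NA_real_
  expect_error(filter_trials(tr), "response_time")
})

test_that("artifact rates surface as the expected removal fractions", {
  # sigma_t = 10 keeps the natural >35 deg tail negligible, isolating the
  # injected artifact rates
  rel <- data.frame(target_aspect = 1.4, sigma_t = 10, sigma_f = 10)
  spec <- small_yoked_spec(n_per_cell = 53, n_obs = 10, seed = 99)
  p <- generative_params("null", reliability = rel,
                         rt_outlier_rate = 0.159, gross_error_rate = 0.069)
  tr <- simulate_experiment(spec, p)
  expect_gt(nrow(tr), 19000)
  rep <- filter_trials(tr)$report
  expect_lt(abs(rep$fraction_rt_removed - 0.159), 0.01)
  expect_lt(abs(rep$fraction_error_removed - 0.069), 0.01)
})

test_that("summaries reproduce hand-computed bias and scatter", {
  # one observer, target 35, responses {40, 30}: bias 0, residuals +/-5
  tr <- tiny_trials(c(40, 30))
  s <- summarize_conditions(tr)
  expect_equal(s$bias, 0)
  expect_equal(s$scatter, sd(c(5, -5)))   # 7.0711, n-1 denominator

  # constant +3 deg error for both targets: bias 3, scatter 0
  tr2 <- rbind(tiny_trials(c(38, 38), targets = 35),
               tiny_trials(c(58, 58), targets = 55))
  s2 <- summarize_conditions(tr2)
  expect_equal(s2$bias, 3)
  expect_equal(s2$scatter, 0)
})

test_that("summaries are invariant to trial order and observer labels", {
  spec <- small_yoked_spec(seed = 17)
  tr <- simulate_experiment(spec, clean_params())
  s1 <- summarize_conditions(tr)
  s2 <- summarize_conditions(tr[sample.int(nrow(tr)), ])
  expect_equal(s2, s1)
  relab <- tr
  relab$observer_id <- paste0("observer_", relab$observer_id)
  s3 <- summarize_conditions(relab)
  expect_equal(s3$bias, s1$bias)
  expect_equal(s3$scatter, s1$scatter)
  expect_error(summarize_conditions(tr, grouping = "nope"),
               "unknown grouping key")
})

test_that("single-trial cells feed bias but are flagged for scatter", {
  tr <- rbind(tiny_trials(c(40, 30), observer = "o1"),
              tiny_trials(38, observer = "o2"))
  expect_warning(s <- summarize_conditions(tr), "fewer than 2 trials")
  expect_false(s$scatter_ok)
  expect_equal(s$bias, mean(c(0, 3)))     # both observers' cell means
  expect_equal(s$scatter, sd(c(5, -5)))   # only o1 contributes
})

test_that("RMSE is the Pythagorean sum and matches brute force per cell", {
  s <- data.frame(theta = c(0, 15), bias = c(3, 0), scatter = c(4, 9))
  expect_equal(rmse_by_condition(s)$rmse, c(5, 9))

  # one observer, one cell: E^2 = bias^2 + var_{n-1}; raw RMS uses /n
  resp <- 35 + c(4, -2, 7, 1, -5, 3)
  tr <- tiny_trials(resp)
  e <- rmse_by_condition(summarize_conditions(tr))$rmse
  err <- resp - 35
  n <- length(err)
  rms <- sqrt(mean(err^2))
  expect_equal(e^2, mean(err)^2 + var(err))
  expect_equal(e^2 * 1, rms^2 + var(err) / n)  # ddof bookkeeping
})

test_that("two-target averaging cancels the regression constant", {
  # alpha = 1 generator: at theta = +/-45 pooled over the two signs the
  # flanker terms cancel, and over the two targets the (1-rho)*10 terms
  # cancel, leaving zero mean bias
  spec <- small_yoked_spec(n_per_cell = 480, n_obs = 6, seed = 5,
                           offsets = c(-45, 45))
  tr <- simulate_experiment(spec, clean_params(alpha = 1))
  s <- summarize_conditions(tr)
  expect_lt(abs(mean(s$bias)), 0.35)      # ~3 sigma at n = 11520
})

test_that("normalized distance follows the stimulus geometry", {
  expect_equal(round(normalized_distance(5.5, 26), 2), 0.21)
  expect_equal(normalized_distance(26, 26), 1)
  expect_equal(normalized_distance(11, 26), 11 / 26)
  expect_equal(round(normalized_distance(c(5.5, 7.5, 11, 16.6), 26), 3),
               c(0.212, 0.288, 0.423, 0.638))
  expect_error(normalized_distance(5.5, 0), "positive")
})

test_that("total error is U-shaped when bias is flat and scatter dips", {
  th <- seq(-45, 45, 5)
  s <- data.frame(theta = th, bias = 0,
                  scatter = 11 + 4 * (1 - exp(-th^2 / 28^2)))
  e <- rmse_by_condition(s)$rmse
  expect_equal(th[which.min(e)], 0)
  expect_true(all(e[abs(th) == 45] > e[th == 0]))
})
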
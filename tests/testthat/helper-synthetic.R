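# shared fixture builders (everything is generated in code, seeded)

rounded_condition <- data.frame(target_aspect = 1.4, flanker_aspect = 2.8)

# small yoked design, single (rounded-target) reliability condition
small_yoked_spec <- function(n_per_cell = 10, n_obs = 4, seed = 7, ...) {
  design_spec("yoked", conditions = rounded_condition,
              n_trials_per_cell = n_per_cell, n_observers = n_obs,
              seed = seed, ...)
}

# clean generator: no lapses/artifacts, so statistics match closed forms
clean_params <- function(model = "ideal_observer", ...) {
  generative_params(model, rt_outlier_rate = 0, gross_error_rate = 0,
                    lapse_rate = 0, ...)
}

# hand-built tiny trial table
tiny_trials <- function(responses, targets = 35, observer = "o1",
                        offset = 0, rt = 1) {
  n <- length(responses)
  targets <- rep_len(targets, n)
  as_trials(data.frame(
    observer_id = rep_len(observer, n),
    experiment_id = "yoked",
    target_ori = targets,
    flanker1_ori = targets + offset,
    flanker2_ori = targets + offset,
    target_aspect = 1.4, flanker_aspect = 2.8,
    spacing = 5.5, eccentricity = 26,
    response_ori = responses,
    response_time = rep_len(rt, n),
    flanker_kind = "parallel_pair"
  ))
}

# brute-force minimizer of the total squared error over the flanker
# weight: 4 w^2 d^2 + 2 w^2 sf^2 + (1 - 2w)^2 st^2 on a fine grid
grid_optimal_weight <- function(st, sf, d, step = 1e-4) {
  w <- seq(0, 0.5, by = step)
  e2 <- 4 * w^2 * d^2 + 2 * w^2 * sf^2 + (1 - 2 * w)^2 * st^2
  w[which.min(e2)]
}
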
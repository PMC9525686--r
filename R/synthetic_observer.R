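# Seeded synthetic observers: experiment designs and trial-level responses
# under the competing generative hypotheses, so every downstream stage is
# testable without experimental data.

#' Experiment design specification
#'
#' Defaults reproduce the main yoked-flanker experiment: targets 35 and 55
#' deg clockwise from vertical, flanker offsets -45..45 deg in 5-deg steps,
#' 5.5 deg centre-to-centre spacing at 26 deg eccentricity (normalized
#' distance 0.21), and the two reliability conditions (rounded target with
#' elongated flankers, aspect ratios 1.4/2.8, and vice versa). The spacing
#' experiment adds spacings 7.5, 11.0 and 16.6 deg; the locked-flanker
#' experiment fixes one flanker at +15 deg while the other spans the grid;
#' the control experiment shows orthogonal or absent flankers with targets
#' on a 22.5-67.5 deg grid.
#'
#' @param experiment one of `"yoked"`, `"spacing"`, `"locked_flanker"`,
#'   `"control"`.
#' @param targets target orientations, degrees.
#' @param offsets flanker offsets, degrees, symmetric about 0.
#' @param spacings centre-to-centre spacings, degrees of visual angle.
#' @param eccentricity target eccentricity, degrees of visual angle.
#' @param conditions data.frame with columns `target_aspect`,
#'   `flanker_aspect`, one row per reliability condition.
#' @param flanker_kinds control experiment only: kinds to interleave.
#' @param locked_offset locked-flanker experiment: the fixed offset,
#'   degrees.
#' @param n_trials_per_cell trials per design cell per observer (>= 1).
#' @param n_observers number of simulated observers (>= 1).
#' @param seed integer seed governing trial order and responses.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(experiment = c("yoked", "spacing", "locked_flanker",
                                       "control"),
                        targets = NULL,
                        offsets = seq(-45, 45, by = 5),
                        spacings = NULL,
                        eccentricity = 26,
                        conditions = data.frame(
                          target_aspect = c(1.4, 2.8),
                          flanker_aspect = c(2.8, 1.4)),
                        flanker_kinds = c("orthogonal", "absent"),
                        locked_offset = 15,
                        n_trials_per_cell = 8,
                        n_observers = 10,
                        seed = 1) {
  experiment <- match.arg(experiment)
  if (is.null(targets)) {
    targets <- if (experiment == "control") seq(22.5, 67.5, by = 5) else
      c(35, 55)
  }
  if (is.null(spacings)) {
    spacings <- if (experiment == "spacing") c(5.5, 7.5, 11.0, 16.6) else 5.5
  }
  if (length(offsets) == 0L || length(targets) == 0L ||
      length(spacings) == 0L || nrow(conditions) == 0L) {
    stop("design factors must be non-empty", call. = FALSE)
  }
  if (n_trials_per_cell < 1L || n_observers < 1L) {
    stop("n_trials_per_cell and n_observers must be >= 1", call. = FALSE)
  }
  if (max(abs(sort(offsets) + rev(sort(offsets)))) > 1e-9) {
    stop("offsets must be symmetric about 0", call. = FALSE)
  }
  stopifnot(eccentricity > 0, all(spacings > 0))
  structure(list(experiment = experiment, targets = targets,
                 offsets = offsets, spacings = spacings,
                 eccentricity = eccentricity, conditions = conditions,
                 flanker_kinds = flanker_kinds,
                 locked_offset = locked_offset,
                 n_trials_per_cell = as.integer(n_trials_per_cell),
                 n_observers = as.integer(n_observers),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Generative parameters for the synthetic observer
#'
#' `model` selects the hypothesis that generates responses:
#' `"ideal_observer"` (both flankers pooled, optimal offset-dependent
#' weight), `"causal_inference"` (compound cue fused under common-cause
#' gating), `"independent_flanker"` (each flanker acts on the target with
#' its own offset-dependent weight), or `"null"` (no flanker influence).
#'
#' Internal scatters are given per reliability condition through
#' `reliability` (matched on `target_aspect`); the default encodes the
#' study's calibration: rounded targets (aspect 1.4) 13.2 deg with 10.0 deg
#' flankers, elongated targets (aspect 2.8) 10.0 deg with 13.2 deg
#' flankers. The deterministic response component is
#' `rho*target + (1-rho)*45` plus the model's flanker-induced bias scaled
#' by `alpha*rho` (or `beta*rho*gate`); the stochastic component realizes
#' the weighted-combination variance at response scale, so measured scatter
#' matches [predicted_scatter()] / [ci_scatter()] and the null model
#' recovers `sigma_t`.
#'
#' Artifact rates emulate the exclusion statistics of real sessions:
#' `rt_outlier_rate` of trials get response times forced outside the
#' 0.5-3 s window, and `gross_error_rate` of the remaining trials get gross
#' reproduction errors (beyond 35 deg). Lapses replace the response with a
#' uniform draw on (0, 90) deg. `spacing_falloff` maps normalized
#' target-flanker distance to a multiplier on the flanker weight
#' (see [default_spacing_falloff()]).
#'
#' @param model generative hypothesis, see above.
#' @param reliability data.frame with columns `target_aspect`, `sigma_t`,
#'   `sigma_f` (degrees). Rows are matched to stimuli by `target_aspect`;
#'   stimuli with no match use the first row.
#' @param rho regression-to-the-mean factor in (0, 1].
#' @param alpha bias scaling for the ideal-observer and
#'   independent-flanker generators.
#' @param beta,gamma amplitude and width scaling for the causal-inference
#'   generator.
#' @param motor_noise additional response noise sd, degrees.
#' @param lapse_rate probability of a uniform (0, 90) lapse response.
#' @param rt_meanlog,rt_sdlog log-normal response-time parameters
#'   (seconds).
#' @param rt_outlier_rate probability of forcing the RT outside 0.5-3 s.
#' @param gross_error_rate probability of forcing a gross (> 35 deg)
#'   reproduction error.
#' @param spacing_falloff function of normalized distance returning a
#'   weight multiplier.
#' @return an object of class `generative_params`.
#' @export
generative_params <- function(model = c("ideal_observer",
                                        "causal_inference",
                                        "independent_flanker", "null"),
                              reliability = data.frame(
                                target_aspect = c(1.4, 2.8),
                                sigma_t = c(13.2, 10.0),
                                sigma_f = c(10.0, 13.2)),
                              rho = 0.665, alpha = 0.7,
                              beta = 0.71, gamma = 1.51,
                              motor_noise = 0, lapse_rate = 0,
                              rt_meanlog = log(1.2), rt_sdlog = 0.25,
                              rt_outlier_rate = 0.159,
                              gross_error_rate = 0.069,
                              spacing_falloff = default_spacing_falloff) {
  model <- match.arg(model)
  stopifnot(all(c("target_aspect", "sigma_t", "sigma_f") %in%
                  names(reliability)),
            all(reliability$sigma_t >= 0), all(reliability$sigma_f >= 0),
            rho > 0, rho <= 1, alpha >= 0, beta >= 0, gamma > 0,
            motor_noise >= 0,
            lapse_rate >= 0, lapse_rate <= 1,
            rt_outlier_rate >= 0, rt_outlier_rate <= 1,
            gross_error_rate >= 0, gross_error_rate <= 1,
            is.function(spacing_falloff))
  structure(list(model = model, reliability = reliability, rho = rho,
                 alpha = alpha, beta = beta, gamma = gamma,
                 motor_noise = motor_noise, lapse_rate = lapse_rate,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_outlier_rate = rt_outlier_rate,
                 gross_error_rate = gross_error_rate,
                 spacing_falloff = spacing_falloff),
            class = "generative_params")
}

#' Default spacing fall-off of flanker integration
#'
#' Multiplier on the flanker weight as a function of normalized
#' target-flanker distance (spacing / eccentricity): full integration up to
#' 0.21 (the main experiment's geometry), a smooth monotone drop to zero at
#' 0.40, a slight repulsive dip to -0.1 around 0.42, and no interaction
#' beyond 0.5 -- the qualitative critical-spacing pattern of crowding.
#'
#' @param nd normalized distance(s); NA returns 1 (geometry unknown).
#' @return multiplier(s) in \[-0.1, 1\].
#' @export
default_spacing_falloff <- function(nd) {
  out <- numeric(length(nd))
  na <- is.na(nd)
  x <- ifelse(na, 0, nd)
  out[x <= 0.21] <- 1
  ramp <- x > 0.21 & x <= 0.40
  out[ramp] <- cos((x[ramp] - 0.21) / (0.40 - 0.21) * pi / 2)
  dip1 <- x > 0.40 & x <= 0.42
  out[dip1] <- -0.1 * (x[dip1] - 0.40) / 0.02
  dip2 <- x > 0.42 & x <= 0.50
  out[dip2] <- -0.1 * (0.50 - x[dip2]) / 0.08
  out[x > 0.50] <- 0
  out[na] <- 1
  out
}

#' Build the full factorial stimulus sequence of a design
#'
#' Expands the design cells (observer x condition x target x offset x
#' spacing x repetition), derives absolute flanker orientations, and
#' shuffles the trial order independently per observer under the design
#' seed (each observer gets its own sub-stream). The locked-flanker design
#' assigns the locked position (top/bottom, coded 1/2) at random per trial
#' and sets that flanker's offset to `locked_offset`.
#'
#' @param spec a [design_spec()] object.
#' @return a stimulus data.frame (one row per upcoming trial) with the
#'   canonical trial columns except the response fields.
#' @export
make_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  base <- switch(
    spec$experiment,
    yoked = ,
    spacing = expand.grid(offset = spec$offsets, target = spec$targets,
                          cond = seq_len(nrow(spec$conditions)),
                          spacing = spec$spacings,
                          KEEP.OUT.ATTRS = FALSE),
    locked_flanker = expand.grid(offset = spec$offsets,
                                 target = spec$targets,
                                 cond = seq_len(nrow(spec$conditions)),
                                 spacing = spec$spacings[1],
                                 KEEP.OUT.ATTRS = FALSE),
    control = expand.grid(offset = NA_real_, target = spec$targets,
                          cond = seq_len(nrow(spec$conditions)),
                          spacing = spec$spacings[1],
                          kind = spec$flanker_kinds,
                          KEEP.OUT.ATTRS = FALSE)
  )
  base <- base[rep(seq_len(nrow(base)), each = spec$n_trials_per_cell), ,
               drop = FALSE]

  set.seed(spec$seed)
  obs_seeds <- sample.int(2147483646L, spec$n_observers)

  one_observer <- function(i) {
    set.seed(obs_seeds[i])
    d <- base[sample.int(nrow(base)), , drop = FALSE]
    n <- nrow(d)
    kind <- if (spec$experiment == "control") as.character(d$kind)
      else if (spec$experiment == "locked_flanker") "locked_plus_variable"
      else "parallel_pair"
    kind <- rep_len(kind, n)
    locked <- rep(NA_real_, n)
    off1 <- d$offset
    off2 <- d$offset
    if (spec$experiment == "locked_flanker") {
      locked <- sample(c(1, 2), n, replace = TRUE)
      off1 <- ifelse(locked == 1, spec$locked_offset, d$offset)
      off2 <- ifelse(locked == 2, spec$locked_offset, d$offset)
    }
    if (spec$experiment == "control") {
      off1 <- ifelse(kind == "orthogonal", 90, NA_real_)
      off2 <- off1
    }
    data.frame(
      observer_id = sprintf("obs%02d", i),
      experiment_id = spec$experiment,
      target_ori = d$target,
      flanker1_ori = d$target + off1,
      flanker2_ori = d$target + off2,
      flanker_offset1 = off1,
      flanker_offset2 = off2,
      target_aspect = spec$conditions$target_aspect[d$cond],
      flanker_aspect = spec$conditions$flanker_aspect[d$cond],
      spacing = ifelse(kind == "absent", NA_real_, d$spacing),
      eccentricity = spec$eccentricity,
      flanker_kind = kind,
      locked_flanker = locked,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(seq_len(spec$n_observers), one_observer))
  rownames(out) <- NULL
  out
}

# sigma_t / sigma_f per stimulus row, matched on target_aspect
.match_reliability <- function(params, target_aspect) {
  rel <- params$reliability
  idx <- match(target_aspect, rel$target_aspect)
  idx[is.na(idx)] <- 1L
  list(sigma_t = rel$sigma_t[idx], sigma_f = rel$sigma_f[idx])
}

#' Simulate reproduction responses for stimulus records
#'
#' Draws internal representations (target `T ~ N(target, sigma_t)`, each
#' flanker `F_i ~ N(flanker_i, sigma_f)`, compound `C ~ N(mean flanker,
#' sigma_f/sqrt(2))`) and combines them according to `params$model`. The
#' deterministic mean is `rho*target + (1-rho)*45` plus the model's
#' flanker-induced bias; weights are computed from the true stimulus
#' offsets (not the noisy representations), which keeps per-cell bias
#' closed-form. Orthogonal or absent flankers contribute nothing. Lapse
#' trials are replaced with Uniform(0, 90) responses; response times come
#' from a log-normal, with artifact trials forced outside the 0.5-3 s
#' analysis window and gross-error trials forced beyond 35 deg error.
#'
#' @param stimuli stimulus records from [make_design()] (one or more
#'   rows).
#' @param params a [generative_params()] object.
#' @param seed optional integer seed for this batch.
#' @return `stimuli` with `response_ori` and `response_time` columns added,
#'   ordered as the input.
#' @export
simulate_response <- function(stimuli, params, seed = NULL) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(stimuli)
  rel <- .match_reliability(params, stimuli$target_aspect)
  st <- rel$sigma_t
  sf <- rel$sigma_f
  rho <- params$rho
  off1 <- stimuli$flanker_offset1
  off2 <- stimuli$flanker_offset2
  kind <- as.character(stimuli$flanker_kind)
  has_fl <- kind %in% c("parallel_pair", "locked_plus_variable") &
    !is.na(off1) & !is.na(off2)
  nd <- ifelse(is.na(stimuli$spacing) | is.na(stimuli$eccentricity),
               NA_real_, stimuli$spacing / stimuli$eccentricity)
  fall <- params$spacing_falloff(nd)

  e_t <- stats::rnorm(n, 0, st)
  base <- rho * stimuli$target_ori + (1 - rho) * 45

  if (params$model == "ideal_observer") {
    d <- ifelse(has_fl, (off1 + off2) / 2, 0)
    w <- ifelse(has_fl, fall * optimal_weight(st, sf, d), 0)
    e_f1 <- stats::rnorm(n, 0, sf)
    e_f2 <- stats::rnorm(n, 0, sf)
    mu <- base + params$alpha * rho * 2 * w * d
    noise <- w * (e_f1 + e_f2) + (1 - 2 * w) * e_t
  } else if (params$model == "independent_flanker") {
    w1 <- ifelse(has_fl, fall * optimal_weight(st, sf, off1), 0)
    w2 <- ifelse(has_fl, fall * optimal_weight(st, sf, off2), 0)
    e_f1 <- stats::rnorm(n, 0, sf)
    e_f2 <- stats::rnorm(n, 0, sf)
    mu <- base + params$alpha * rho *
      (w1 * ifelse(has_fl, off1, 0) + w2 * ifelse(has_fl, off2, 0))
    noise <- w1 * e_f1 + w2 * e_f2 + (1 - w1 - w2) * e_t
  } else if (params$model == "causal_inference") {
    th <- ifelse(has_fl, (off1 + off2) / 2, 0)
    sc <- sf / sqrt(2)
    w_max <- st^2 / (sc^2 + st^2)
    gate <- exp(-th^2 / (2 * params$gamma^2 * (sc^2 + st^2)))
    w <- ifelse(has_fl, fall * params$beta * rho * w_max * gate, 0)
    e_c <- stats::rnorm(n, 0, sc)
    mu <- base + w * th
    noise <- w * e_c + (1 - w) * e_t
  } else {
    mu <- base
    noise <- e_t
  }
  resp <- mu + noise
  if (params$motor_noise > 0) {
    resp <- resp + stats::rnorm(n, 0, params$motor_noise)
  }

  lapse <- stats::runif(n) < params$lapse_rate
  if (any(lapse)) resp[lapse] <- stats::runif(sum(lapse), 0, 90)
  gross <- !lapse & stats::runif(n) < params$gross_error_rate
  if (any(gross)) {
    sign_g <- sample(c(-1, 1), sum(gross), replace = TRUE)
    resp[gross] <- stimuli$target_ori[gross] +
      sign_g * stats::runif(sum(gross), 36, 60)
  }

  rt <- stats::rlnorm(n, params$rt_meanlog, params$rt_sdlog)
  art <- stats::runif(n) < params$rt_outlier_rate
  if (any(art)) {
    early <- stats::runif(sum(art)) < 0.5
    rt[art] <- ifelse(early, stats::runif(sum(art), 0.05, 0.45),
                      stats::runif(sum(art), 3.05, 6))
  }

  stimuli$response_ori <- resp
  stimuli$response_time <- rt
  stimuli
}

#' Simulate a full experiment
#'
#' Applies [simulate_response()] over [make_design()], with per-observer
#' response sub-streams derived from the design seed: the whole trial
#' table is reproducible from `(spec, params)` alone.
#'
#' @param spec a [design_spec()] object (its `seed` drives everything).
#' @param params a [generative_params()] object.
#' @return a canonical trial data.frame.
#' @export
simulate_experiment <- function(spec, params) {
  design <- make_design(spec)
  set.seed(spec$seed)
  sample.int(2147483646L, spec$n_observers)          # design sub-streams
  resp_seeds <- sample.int(2147483646L, spec$n_observers)
  obs <- unique(design$observer_id)
  out <- lapply(seq_along(obs), function(i) {
    rows <- design$observer_id == obs[i]
    simulate_response(design[rows, , drop = FALSE], params,
                      seed = resp_seeds[i])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  as_trials(out)
}
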
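# Descriptive derivative-of-Gaussian fits, reliability calibration, and
# mechanistic parameter fitting (alpha; beta/gamma).

# DoG bias curve: a Gaussian of width s times a line of slope a through
# (m, 0), plus offset b. a is also the slope at theta = m, i.e. the
# maximal slope of the curve -- the weight given to the flankers.
dog_curve <- function(theta, a, m, s, b) {
  a * (theta - m) * exp(-(theta - m)^2 / s^2) + b
}

gauss_curve <- function(theta, a, m, s, b) {
  a * exp(-(theta - m)^2 / s^2) + b
}

.dog_par_names <- c("a", "m", "s", "b", "scatter_a", "scatter_m",
                    "scatter_b")
.dog_lower <- c(a = -5, m = -45, s = 5, b = -30,
                scatter_a = -40, scatter_m = -45, scatter_b = 0)
.dog_upper <- c(a = 5, m = 45, s = 90, b = 30,
                scatter_a = 40, scatter_m = 45, scatter_b = 90)

# Levenberg-Marquardt with box bounds and multiple starts; returns the
# best solution by residual sum of squares.
.lm_multistart <- function(residual_fun, starts, lower, upper) {
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper, fn = residual_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(fit$fvec^2)
    if (is.null(best) || dev < best$dev) {
      # info 4 arises at exact zero residual (gradient orthogonality)
      best <- list(par = fit$par, dev = dev,
                   converged = fit$info %in% 1:4)
    }
  }
  best
}

#' Fit a derivative-of-Gaussian to bias (and a Gaussian to scatter)
#'
#' Fits the descriptive bias model
#' `B(theta) = a (theta - m) exp(-(theta - m)^2 / s^2) + b`
#' and, when scatter is included, the scatter model
#' `S(theta) = scatter_a exp(-(theta - scatter_m)^2 / s^2) + scatter_b`
#' jointly by least squares with the width `s` shared between the two
#' curves (bias and scatter are assumed to arise from one integration
#' process) and all other parameters per-curve. The exponent uses `/s^2`
#' with no factor 2, so `s` relates to a Gaussian standard deviation as
#' `s = sd * sqrt(2)`. The reported `a` is the maximal slope of the bias
#' curve (its slope at `theta = m`). Optimization is multi-start
#' Levenberg-Marquardt with centres seeded at -15, 0 and +15 deg.
#'
#' @param summaries data.frame with columns `theta`, `bias` and (if used)
#'   `scatter`, e.g. one condition from [summarize_conditions()].
#' @param include_scatter fit the scatter curve jointly (default) or bias
#'   only.
#' @param fixed optional named list pinning parameters (e.g.
#'   `list(m = 0)`).
#' @param centre_starts starting values for the bias centre.
#' @param s_range optional length-2 bounds on the shared width `s`
#'   (degrees), overriding the default (5, 90). Narrower bounds keep the
#'   fit inside the crowding-signature family on weak-effect data, where
#'   an unconstrained width can collapse onto single-point noise.
#' @return an object of class `dog_fit` with elements `a`, `m`, `s`, `b`,
#'   `scatter_a`, `scatter_m`, `scatter_b`, `sse_bias`, `sse_scatter`,
#'   `converged`.
#' @export
fit_dog <- function(summaries, include_scatter = TRUE, fixed = NULL,
                    centre_starts = c(-15, 0, 15), s_range = NULL) {
  theta <- summaries$theta
  bias <- summaries$bias
  keep <- is.finite(theta) & is.finite(bias)
  scatter <- if (include_scatter) summaries$scatter else NULL
  if (include_scatter) {
    if (is.null(scatter)) stop("summaries lack a scatter column",
                               call. = FALSE)
    keep <- keep & is.finite(scatter)
    scatter <- scatter[keep]
  }
  theta <- theta[keep]
  bias <- bias[keep]
  if (length(unique(theta)) < 6L) {
    stop("fit_dog() needs at least 6 distinct offsets with finite values",
         call. = FALSE)
  }

  par_names <- if (include_scatter) .dog_par_names else .dog_par_names[1:4]
  fixed <- fixed[names(fixed) %in% par_names]
  free <- setdiff(par_names, names(fixed))
  lower <- .dog_lower
  upper <- .dog_upper
  if (!is.null(s_range)) {
    stopifnot(length(s_range) == 2L, s_range[1] < s_range[2])
    lower["s"] <- s_range[1]
    upper["s"] <- s_range[2]
  }

  full_par <- function(p) {
    out <- numeric(length(par_names))
    names(out) <- par_names
    out[free] <- p
    for (nm in names(fixed)) out[nm] <- fixed[[nm]]
    out
  }
  residual_fun <- function(p) {
    q <- full_par(p)
    r <- bias - dog_curve(theta, q["a"], q["m"], q["s"], q["b"])
    if (include_scatter) {
      r <- c(r, scatter - gauss_curve(theta, q["scatter_a"], q["scatter_m"],
                                      q["s"], q["scatter_b"]))
    }
    r
  }

  # data-driven rough starts
  slope0 <- tryCatch(
    unname(stats::coef(stats::lm(bias ~ theta))[2]), error = function(e) 0.2)
  if (!is.finite(slope0)) slope0 <- 0.2
  starts <- list()
  for (m0 in centre_starts) {
    for (s0 in c(15, 30)) {
      st <- c(a = slope0, m = m0, s = s0, b = mean(bias))
      if (include_scatter) {
        sb0 <- max(scatter)
        st <- c(st, scatter_a = min(scatter) - sb0, scatter_m = m0,
                scatter_b = sb0)
      }
      st <- pmin(pmax(st[free], lower[free]), upper[free])
      starts[[length(starts) + 1L]] <- st
    }
  }

  best <- .lm_multistart(residual_fun, starts, lower[free], upper[free])
  if (is.null(best)) {
    stop("fit_dog(): no start converged", call. = FALSE)
  }
  q <- full_par(best$par)
  sse_bias <- sum((bias - dog_curve(theta, q["a"], q["m"], q["s"],
                                    q["b"]))^2)
  sse_scatter <- if (include_scatter) {
    sum((scatter - gauss_curve(theta, q["scatter_a"], q["scatter_m"],
                               q["s"], q["scatter_b"]))^2)
  } else NA_real_
  structure(list(
    a = unname(q["a"]), m = unname(q["m"]), s = unname(q["s"]),
    b = unname(q["b"]),
    scatter_a = if (include_scatter) unname(q["scatter_a"]) else NA_real_,
    scatter_m = if (include_scatter) unname(q["scatter_m"]) else NA_real_,
    scatter_b = if (include_scatter) unname(q["scatter_b"]) else NA_real_,
    sse_bias = sse_bias, sse_scatter = sse_scatter,
    include_scatter = include_scatter,
    converged = best$converged
  ), class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  cat(sprintf(
    "DoG fit: a = %.4f, m = %.2f deg, s = %.2f deg, b = %.3f deg (SSE %.4g)\n",
    x$a, x$m, x$s, x$b, x$sse_bias))
  if (x$include_scatter) {
    cat(sprintf(
      "scatter:  a = %.3f, m = %.2f deg, b = %.2f deg (shared s; SSE %.4g)\n",
      x$scatter_a, x$scatter_m, x$scatter_b, x$sse_scatter))
  }
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' Calibrate sensory reliability from extreme flanker offsets
#'
#' At large target-flanker differences the integration gate is shut, so
#' the measured scatter there is taken as the baseline sensory scatter of
#' the target representation: the mean scatter over all offsets with
#' `|theta| >= extreme_threshold` (default 30 deg, i.e. the +/-30, +/-35,
#' +/-40 and +/-45 deg points of the standard grid).
#'
#' @param summaries one condition's summaries (columns `theta`,
#'   `scatter`).
#' @param extreme_threshold minimum absolute offset, degrees.
#' @return estimated scatter sigma, degrees.
#' @export
estimate_reliability <- function(summaries, extreme_threshold = 30) {
  sel <- is.finite(summaries$theta) &
    abs(summaries$theta) >= extreme_threshold &
    is.finite(summaries$scatter)
  if (!any(sel)) {
    stop("no offsets at |theta| >= ", extreme_threshold, call. = FALSE)
  }
  mean(summaries$scatter[sel])
}

#' Regression-to-the-mean factor from the two target means
#'
#' The two targets are 20 deg apart (35 and 55 deg); shrinkage toward the
#' 45 deg set mean compresses the mean reproductions, so the factor is the
#' reproduced separation over the true separation:
#' `(mean_55 - mean_35) / 20`. 1 means no regression, 0 full collapse.
#'
#' @param mean_55 mean reproduction of the 55 deg target, degrees.
#' @param mean_35 mean reproduction of the 35 deg target, degrees.
#' @return the factor rho.
#' @export
regression_to_mean <- function(mean_55, mean_35) {
  stopifnot(is.finite(mean_55), is.finite(mean_35))
  (mean_55 - mean_35) / 20
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares about the observed
#' mean. Can be negative for predictions worse than the mean; `NA` (with a
#' warning) when the observations have zero variance.
#'
#' @param predicted,observed numeric vectors of equal length >= 3.
#' @return R-squared, or NA if undefined.
#' @export
r_squared <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 3L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("zero total variance: R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit the ideal-observer scaling factor alpha
#'
#' With reliabilities and the regression factor fixed from the data, the
#' ideal-observer bias prediction has a single free scaling constant
#' `alpha` (allowing sub-optimal weighting), estimated by least squares
#' against the observed bias curve (linear in `alpha`, so the solution is
#' closed-form). The scatter prediction has no free parameter; its
#' R-squared is reported as-is.
#'
#' @param summaries one condition's summaries (columns `theta`, `bias`,
#'   optionally `scatter`).
#' @param sigma_t,sigma_f calibrated scatters, degrees.
#' @param rho regression-to-the-mean factor.
#' @return an object of class `model_fit` with elements `model`, `alpha`,
#'   `sigma_t`, `sigma_f`, `rho`, `r2_bias`, `r2_scatter`, `converged`.
#' @export
fit_alpha <- function(summaries, sigma_t, sigma_f, rho) {
  keep <- is.finite(summaries$theta) & is.finite(summaries$bias)
  theta <- summaries$theta[keep]
  bias <- summaries$bias[keep]
  base <- ideal_observer_params(sigma_t, sigma_f, rho = rho, alpha = 1)
  pred1 <- predicted_bias(theta, base)
  denom <- sum(pred1^2)
  if (denom == 0 || !any(bias != 0)) {
    warning("degenerate bias data: alpha not identifiable", call. = FALSE)
    return(structure(list(model = "ideal_observer", alpha = 0,
                          sigma_t = sigma_t, sigma_f = sigma_f, rho = rho,
                          r2_bias = NA_real_, r2_scatter = NA_real_,
                          converged = FALSE), class = "model_fit"))
  }
  alpha <- sum(bias * pred1) / denom
  r2_bias <- r_squared(alpha * pred1, bias)
  r2_scatter <- NA_real_
  if ("scatter" %in% names(summaries)) {
    ks <- keep & is.finite(summaries$scatter)
    if (sum(ks) >= 3L) {
      r2_scatter <- r_squared(predicted_scatter(summaries$theta[ks], base),
                              summaries$scatter[ks])
    }
  }
  structure(list(model = "ideal_observer", alpha = alpha,
                 sigma_t = sigma_t, sigma_f = sigma_f, rho = rho,
                 r2_bias = r2_bias, r2_scatter = r2_scatter,
                 converged = TRUE), class = "model_fit")
}

#' Fit the causal-inference amplitude and width scalings
#'
#' Joint least squares of `beta` (amplitude) and `gamma` (width stretch)
#' over the bias and scatter curves simultaneously, with the two sums of
#' squared errors weighted equally (both in squared degrees; the weight is
#' configurable). Bounds: beta in \[0, 2\], gamma in \[0.2, 5\];
#' multi-start Levenberg-Marquardt. Data with no flanker effect leave
#' gamma unidentifiable; such fits are flagged unconverged.
#'
#' @inheritParams fit_alpha
#' @param scatter_weight weight of the scatter SSE relative to the bias
#'   SSE.
#' @return an object of class `model_fit` with elements `model`, `beta`,
#'   `gamma`, `sigma_t`, `sigma_f`, `rho`, `r2_bias`, `r2_scatter`,
#'   `converged`.
#' @export
fit_beta_gamma <- function(summaries, sigma_t, sigma_f, rho,
                           scatter_weight = 1) {
  keep <- is.finite(summaries$theta) & is.finite(summaries$bias)
  has_scatter <- "scatter" %in% names(summaries) &&
    any(is.finite(summaries$scatter))
  if (has_scatter) keep <- keep & is.finite(summaries$scatter)
  theta <- summaries$theta[keep]
  bias <- summaries$bias[keep]
  scatter <- if (has_scatter) summaries$scatter[keep] else NULL

  make_params <- function(beta, gamma) {
    causal_inference_params(sigma_t, sigma_f, rho = rho, beta = beta,
                            gamma = gamma)
  }
  residual_fun <- function(p) {
    pars <- make_params(p[1], p[2])
    r <- bias - ci_bias(theta, pars)
    if (has_scatter) {
      r <- c(r, sqrt(scatter_weight) * (scatter - ci_scatter(theta, pars)))
    }
    r
  }
  starts <- list(c(0.3, 0.7), c(0.7, 1.5), c(1.2, 3), c(1, 1))
  best <- .lm_multistart(residual_fun, starts, lower = c(0, 0.2),
                         upper = c(2, 5))
  if (is.null(best)) stop("fit_beta_gamma(): no start converged",
                          call. = FALSE)
  beta <- best$par[1]
  gamma <- best$par[2]
  identifiable <- beta > 1e-6 && any(abs(bias) > 1e-10)
  if (!identifiable) {
    warning("beta ~ 0: gamma not identifiable", call. = FALSE)
  }
  pars <- make_params(beta, gamma)
  r2_bias <- if (any(bias != 0)) r_squared(ci_bias(theta, pars), bias)
    else NA_real_
  r2_scatter <- if (has_scatter && length(scatter) >= 3L &&
                    stats::var(scatter) > 0) {
    r_squared(ci_scatter(theta, pars), scatter)
  } else NA_real_
  structure(list(model = "causal_inference", beta = beta, gamma = gamma,
                 sigma_t = sigma_t, sigma_f = sigma_f, rho = rho,
                 r2_bias = r2_bias, r2_scatter = r2_scatter,
                 converged = best$converged && identifiable),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  if (x$model == "ideal_observer") {
    cat(sprintf("ideal-observer fit: alpha = %.4f", x$alpha))
  } else {
    cat(sprintf("causal-inference fit: beta = %.4f, gamma = %.4f",
                x$beta, x$gamma))
  }
  cat(sprintf("  (sigma_t = %.2f, sigma_f = %.2f, rho = %.3f)\n",
              x$sigma_t, x$sigma_f, x$rho))
  cat(sprintf("R^2 bias = %.3f, R^2 scatter = %.3f\n",
              x$r2_bias, x$r2_scatter))
  invisible(x)
}
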
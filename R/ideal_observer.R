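# Ideal-observer cue-combination model: closed-form optimal flanker weight,
# bias, scatter and RMSE as functions of flanker offset.

#' Parameters of the ideal-observer model
#'
#' `sigma_t` and `sigma_f` are the response-scale standard deviations of the
#' internal target and single-flanker representations (degrees), calibrated
#' from reproduction scatter at extreme flanker offsets. `rho` is the
#' regression-to-the-mean factor (shrinkage of responses toward the 45 deg
#' stimulus-set mean); `alpha` is a global scaling of the flanker-induced
#' bias allowing sub-optimal weighting.
#'
#' @param sigma_t target representation scatter, degrees (> 0).
#' @param sigma_f single-flanker representation scatter, degrees (>= 0; 0 is
#'   the perfectly-reliable-flanker limit).
#' @param rho regression-to-the-mean factor in (0, 1].
#' @param alpha bias scaling factor in \[0, 1.5\].
#' @return an object of class `ideal_observer_params`.
#' @export
ideal_observer_params <- function(sigma_t, sigma_f, rho = 1, alpha = 1) {
  stopifnot(is.numeric(sigma_t), sigma_t > 0,
            is.numeric(sigma_f), sigma_f >= 0,
            rho > 0, rho <= 1, alpha >= 0, alpha <= 1.5)
  structure(list(sigma_t = sigma_t, sigma_f = sigma_f,
                 rho = rho, alpha = alpha),
            class = "ideal_observer_params")
}

#' Optimal per-flanker weight
#'
#' The weight that minimizes total squared reproduction error (squared bias
#' plus response variance) when the response is a linear combination
#' `w*F1 + w*F2 + (1-2w)*T` of the target and two equally reliable
#' flankers whose mean orientation lies `d` degrees from the target:
#' \deqn{w_{opt} = \sigma_T^2 / (2\sigma_T^2 + \sigma_F^2 + 2 d^2)}
#' Unreliable targets and reliable, similarly-oriented flankers increase
#' the weight; it always stays below 0.5 (the target is never fully
#' overridden) and falls off quadratically with target-flanker difference.
#'
#' @param sigma_t target scatter, degrees (> 0).
#' @param sigma_f single-flanker scatter, degrees (>= 0).
#' @param d distance between mean flanker orientation and target, degrees;
#'   vectorized.
#' @return per-flanker weight(s) in (0, 0.5\].
#' @export
optimal_weight <- function(sigma_t, sigma_f, d) {
  if (any(!is.finite(sigma_t)) || any(sigma_t <= 0)) {
    stop("sigma_t must be positive", call. = FALSE)
  }
  if (any(!is.finite(sigma_f)) || any(sigma_f < 0)) {
    stop("sigma_f must be non-negative", call. = FALSE)
  }
  sigma_t^2 / (2 * sigma_t^2 + sigma_f^2 + 2 * d^2)
}

#' Predicted reproduction bias of the ideal observer
#'
#' For yoked flankers at offset `theta` the mean-flanker distance is
#' `d = theta`, giving bias `alpha * rho * 2 * w_opt(theta) * theta`
#' (degrees, positive = clockwise). This is the bias after averaging over
#' the two target orientations, which cancels the regression-to-the-mean
#' constant.
#'
#' @param theta flanker offset(s) relative to the target, degrees.
#' @param params an [ideal_observer_params()] object.
#' @return predicted bias in degrees, vectorized over `theta`.
#' @export
predicted_bias <- function(theta, params) {
  w <- optimal_weight(params$sigma_t, params$sigma_f, theta)
  params$alpha * params$rho * 2 * w * theta
}

#' Predicted reproduction scatter of the ideal observer
#'
#' Root variance of the weighted combination,
#' `sqrt(2 w^2 sigma_f^2 + (1 - 2w)^2 sigma_t^2)` with `w = w_opt(theta)`.
#' Not scaled by `alpha` or `rho`: the sigmas are calibrated in response
#' space, so scaling would contradict the baseline scatter they came from.
#'
#' @inheritParams predicted_bias
#' @return predicted scatter in degrees, vectorized over `theta`.
#' @export
predicted_scatter <- function(theta, params) {
  w <- optimal_weight(params$sigma_t, params$sigma_f, theta)
  sqrt(2 * w^2 * params$sigma_f^2 + (1 - 2 * w)^2 * params$sigma_t^2)
}

#' Predicted total RMS error of the ideal observer
#'
#' Pythagorean sum of [predicted_bias()] and [predicted_scatter()]. The
#' weight was derived by minimizing this quantity squared, so at every
#' offset it is no larger than the error of an observer ignoring the
#' flankers (w = 0), producing the characteristic U-shaped error profile
#' with its minimum where target and flankers coincide.
#'
#' @inheritParams predicted_bias
#' @return predicted RMSE in degrees, vectorized over `theta`.
#' @export
predicted_rmse <- function(theta, params) {
  sqrt(predicted_bias(theta, params)^2 + predicted_scatter(theta, params)^2)
}
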
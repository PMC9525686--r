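# Causal-inference model: reliability weighting gated by the probability
# that target and flanker compound share a common cause.

#' A Gaussian cue
#'
#' Internal representation of an orientation cue: a Gaussian with mean `mu`
#' (degrees) and standard deviation `sigma` (degrees).
#'
#' @param mu cue mean, degrees.
#' @param sigma cue standard deviation, degrees (> 0).
#' @return an object of class `gaussian_cue`.
#' @export
gaussian_cue <- function(mu, sigma) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma > 0)
  structure(list(mu = mu, sigma = sigma), class = "gaussian_cue")
}

#' Parameters of the causal-inference model
#'
#' The two flankers are first pooled into a compound cue with variance
#' `sigma_f^2 / 2`; the compound is fused with the target with the maximal
#' reliability weight, gated by the probability of a common cause. `beta`
#' scales the amplitude of the flanker dependency and `gamma` stretches the
#' width of the interaction region (as `gamma^2` inside the gating
#' exponent). An optional Gaussian prior on the common cause (`prior_mu`,
#' `prior_sigma`) feeds the full common-cause probability; omitted, the
#' flat-prior limit is used.
#'
#' @param sigma_t target scatter, degrees (> 0).
#' @param sigma_f single-flanker scatter, degrees (> 0); the compound cue
#'   scatter is `sigma_f / sqrt(2)`.
#' @param rho regression-to-the-mean factor in (0, 1].
#' @param beta amplitude scale (>= 0).
#' @param gamma width scale (> 0).
#' @param prior_mu,prior_sigma optional common-cause prior (degrees).
#' @return an object of class `causal_inference_params`.
#' @export
causal_inference_params <- function(sigma_t, sigma_f, rho = 1, beta = 1,
                                    gamma = 1, prior_mu = NULL,
                                    prior_sigma = NULL) {
  stopifnot(sigma_t > 0, sigma_f > 0, rho > 0, rho <= 1,
            beta >= 0, gamma > 0)
  if (!is.null(prior_sigma) && prior_sigma <= 0) {
    stop("prior_sigma must be positive", call. = FALSE)
  }
  structure(list(sigma_t = sigma_t, sigma_f = sigma_f,
                 sigma_c = sigma_f / sqrt(2), rho = rho,
                 beta = beta, gamma = gamma,
                 prior_mu = prior_mu, prior_sigma = prior_sigma),
            class = "causal_inference_params")
}

#' Maximal reliability weight of the flanker compound
#'
#' The classical two-cue fusion weight assigned to cue B when estimating
#' with cues of variances `sigma_a^2` (here the compound flanker) and
#' `sigma_b^2` (here the target): the weight given to the flanker compound
#' is `sigma_t^2 / (sigma_c^2 + sigma_t^2)`, attained when the two cues
#' coincide.
#'
#' @param sigma_t target scatter, degrees (> 0).
#' @param sigma_c compound-flanker scatter, degrees (> 0); for two yoked
#'   flankers of individual scatter `sigma_f` this is `sigma_f / sqrt(2)`.
#' @return weight in (0, 1).
#' @export
compound_weight <- function(sigma_t, sigma_c) {
  if (any(sigma_t <= 0) || any(sigma_c <= 0)) {
    stop("sigmas must be positive", call. = FALSE)
  }
  sigma_t^2 / (sigma_c^2 + sigma_t^2)
}

.cue <- function(x) {
  if (inherits(x, "gaussian_cue")) x else gaussian_cue(x$mu, x$sigma)
}

#' Probability that two cues share a common cause
#'
#' Unnormalized Bayesian posterior probability (up to a constant) that two
#' Gaussian cues arise from a single cause. With a Gaussian prior (mean
#' `mu_p`, sd `sigma_p`) on the cause location:
#' \deqn{p \propto \exp\left(-\frac{1}{2}
#'   \frac{(\mu_A-\mu_B)^2\sigma_P^2 + (\mu_A-\mu_P)^2\sigma_B^2 +
#'         (\mu_B-\mu_P)^2\sigma_A^2}
#'        {\sigma_A^2\sigma_B^2 + \sigma_A^2\sigma_P^2 +
#'         \sigma_B^2\sigma_P^2}\right)}
#' In the flat-prior limit (`prior = NULL`, i.e. `sigma_p` to infinity) this
#' reduces to `exp(-0.5 (mu_a - mu_b)^2 / (sigma_a^2 + sigma_b^2))`, a
#' Gaussian in the cue separation, equal to 1 for coincident cues.
#'
#' @param cue_a,cue_b [gaussian_cue()] objects (or lists with `mu`,
#'   `sigma`).
#' @param prior optional [gaussian_cue()] describing the common-cause
#'   prior.
#' @return unnormalized probability in (0, 1].
#' @export
common_cause_prob <- function(cue_a, cue_b, prior = NULL) {
  a <- .cue(cue_a); b <- .cue(cue_b)
  va <- a$sigma^2; vb <- b$sigma^2
  if (is.null(prior)) {
    return(exp(-0.5 * (a$mu - b$mu)^2 / (va + vb)))
  }
  p <- .cue(prior)
  vp <- p$sigma^2
  num <- (a$mu - b$mu)^2 * vp + (a$mu - p$mu)^2 * vb + (b$mu - p$mu)^2 * va
  den <- va * vb + va * vp + vb * vp
  exp(-0.5 * num / den)
}

# effective flanker-compound weight at offset theta: reliability weight
# gated by the (stretched, scaled) common-cause probability
ci_effective_weight <- function(theta, params) {
  w_max <- compound_weight(params$sigma_t, params$sigma_c)
  gate <- exp(-theta^2 /
                (2 * params$gamma^2 * (params$sigma_c^2 + params$sigma_t^2)))
  params$beta * params$rho * w_max * gate
}

#' Causal-inference predicted bias
#'
#' Bias toward the flanker compound at offset `theta`:
#' `beta * rho * w_max * exp(-theta^2 / (2 gamma^2 (sigma_c^2 + sigma_t^2)))
#' * theta`, a derivative-of-Gaussian in `theta` peaking at
#' `gamma * sqrt(sigma_c^2 + sigma_t^2)`. With `beta = rho = gamma = 1`
#' this is the parameter-free gated-fusion prediction.
#'
#' @param theta flanker-compound offset(s) from the target, degrees (for
#'   the locked-flanker design, the mean of the two flanker offsets).
#' @param params a [causal_inference_params()] object.
#' @return predicted bias in degrees, vectorized over `theta`.
#' @export
ci_bias <- function(theta, params) {
  ci_effective_weight(theta, params) * theta
}

#' Causal-inference predicted scatter
#'
#' Root variance of the gated combination,
#' `sqrt(w_eff^2 sigma_c^2 + (1 - w_eff)^2 sigma_t^2)` with the effective
#' weight `w_eff(theta) = beta * rho * w_max * gate(theta)`. U-shaped:
#' minimal where target and flanker compound coincide, tending to
#' `sigma_t` for large offsets where the gate shuts integration off.
#'
#' @inheritParams ci_bias
#' @return predicted scatter in degrees, vectorized over `theta`.
#' @export
ci_scatter <- function(theta, params) {
  w <- ci_effective_weight(theta, params)
  sqrt(w^2 * params$sigma_c^2 + (1 - w)^2 * params$sigma_t^2)
}

#' Peak, mean and variance of a product of two Gaussian densities
#'
#' The pointwise product of two Gaussian densities is an (unnormalized)
#' Gaussian with mean `(mu_b sigma_a^2 + mu_a sigma_b^2) /
#' (sigma_a^2 + sigma_b^2)`, variance `sigma_a^2 sigma_b^2 /
#' (sigma_a^2 + sigma_b^2)` and peak height
#' \deqn{\frac{1}{2\pi\sigma_A\sigma_B}
#'   \exp\left(-\frac{(\mu_A-\mu_B)^2}{2(\sigma_A^2+\sigma_B^2)}\right)}
#' As a function of cue separation the peak carries the same Gaussian
#' dependence as the flat-prior common-cause probability, so a system
#' measuring cue similarity by the product's peak (or area, which is the
#' peak times a fixed width factor) behaves like the causal-inference gate.
#'
#' @param cue_a,cue_b [gaussian_cue()] objects.
#' @return a list with `peak`, `mean`, `variance`.
#' @export
gaussian_product_peak <- function(cue_a, cue_b) {
  a <- .cue(cue_a); b <- .cue(cue_b)
  va <- a$sigma^2; vb <- b$sigma^2
  list(
    peak = exp(-(a$mu - b$mu)^2 / (2 * (va + vb))) /
      (2 * pi * a$sigma * b$sigma),
    mean = (b$mu * va + a$mu * vb) / (va + vb),
    variance = va * vb / (va + vb)
  )
}
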
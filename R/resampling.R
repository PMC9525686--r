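# Bootstrap distribution of the DoG centre (global vs. local integration
# test) and the spacing-weight analysis.

# resample trial indices with replacement within (observer, offset) cells,
# preserving the design balance
.cell_indices <- function(trials) {
  theta <- trial_theta(trials)
  split(seq_len(nrow(trials)), paste(trials$observer_id, theta, sep = "\r"))
}

.resample_within_cells <- function(cells) {
  unlist(lapply(cells, function(i) {
    if (length(i) == 1L) i else i[sample.int(length(i), length(i),
                                             replace = TRUE)]
  }), use.names = FALSE)
}

#' Ratio of bootstrap counts as a likelihood ratio
#'
#' Given the number of bootstrap centres closer to the reference
#' hypothesis (`n_ref`) and closer to the null location (`n_zero`), the
#' evidence ratio is `n_ref / n_zero`. A zero denominator is reported as a
#' capped bound (`> n_ref`) rather than a division.
#'
#' @param n_ref count of iterations favouring the reference centre.
#' @param n_zero count of iterations favouring the null centre.
#' @return an object of class `bayes_factor`: list with `bf` (numeric, NA
#'   when capped), `n_ref`, `n_zero`, `capped`.
#' @export
bayes_factor <- function(n_ref, n_zero) {
  stopifnot(n_ref >= 0, n_zero >= 0)
  if (n_ref + n_zero == 0) {
    stop("no counts: Bayes factor undefined", call. = FALSE)
  }
  if (n_zero == 0) {
    return(structure(list(bf = NA_real_, n_ref = n_ref, n_zero = 0,
                          capped = TRUE), class = "bayes_factor"))
  }
  structure(list(bf = n_ref / n_zero, n_ref = n_ref, n_zero = n_zero,
                 capped = FALSE), class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  if (x$capped) {
    cat(sprintf("Bayes factor > %d (no iterations on the null side)\n",
                x$n_ref))
  } else {
    cat(sprintf("Bayes factor = %d/%d = %.3g\n", x$n_ref, x$n_zero, x$bf))
  }
  invisible(x)
}

#' Bootstrap the DoG centre of the locked-flanker bias curve
#'
#' Resamples trials with replacement within each (observer, offset) cell,
#' re-summarizes, refits the derivative-of-Gaussian bias curve with all
#' parameters free, and records the centre `m` on each iteration. Centres
#' are then classified by proximity to the null location (0 deg,
#' independent-flanker integration) versus the reference location (-15
#' deg, joint-flanker integration, i.e. where the mean of the two flankers
#' equals the target when one is locked at +15 deg): with the default
#' locations, a centre counts toward the null side when m > -7.5 deg;
#' exact midpoint ties go to the reference side. The count ratio is the
#' bootstrap likelihood ratio for joint over independent integration.
#'
#' Iterations whose fit fails are retried with a fresh resample (up to 3
#' times) and otherwise recorded as missing and excluded from the counts.
#'
#' @param trials a filtered locked-flanker trial table (one condition).
#' @param n_iter number of bootstrap iterations.
#' @param seed integer seed; identical (data, seed, n_iter) reproduce the
#'   centre list exactly.
#' @param ref_centre reference-hypothesis centre, degrees.
#' @param null_centre null-hypothesis centre, degrees.
#' @return an object of class `bootstrap_result`: `centres` (length
#'   `n_iter`, NA for failed iterations), `n_closer_to_zero`,
#'   `n_closer_to_ref`, `bayes_factor`, `n_failed`, `seed`, `n_iter`.
#' @export
bootstrap_centres <- function(trials, n_iter = 1000, seed = 1,
                              ref_centre = -15, null_centre = 0) {
  stopifnot(n_iter >= 1)
  cells <- .cell_indices(trials)
  midpoint <- (ref_centre + null_centre) / 2
  set.seed(seed)
  centres <- rep(NA_real_, n_iter)
  n_failed <- 0L
  for (it in seq_len(n_iter)) {
    m <- NA_real_
    for (try in 1:3) {
      idx <- .resample_within_cells(cells)
      fit <- tryCatch(suppressWarnings(
        fit_dog(summarize_conditions(trials[idx, , drop = FALSE]),
                include_scatter = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$converged) {
        m <- fit$m
        break
      }
    }
    if (is.na(m)) n_failed <- n_failed + 1L
    centres[it] <- m
  }
  ok <- centres[!is.na(centres)]
  # ties at the exact midpoint are assigned to the reference side
  to_zero <- if (ref_centre < null_centre) sum(ok > midpoint) else
    sum(ok < midpoint)
  to_ref <- length(ok) - to_zero
  bf <- bayes_factor(to_ref, to_zero)
  structure(list(centres = centres, n_closer_to_zero = to_zero,
                 n_closer_to_ref = to_ref, bayes_factor = bf,
                 n_failed = n_failed, seed = seed, n_iter = n_iter,
                 ref_centre = ref_centre, null_centre = null_centre),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap of the DoG centre: %d iterations (%d failed), median centre %.2f deg\n",
    x$n_iter, x$n_failed, stats::median(x$centres, na.rm = TRUE)))
  cat(sprintf("closer to %g deg: %d; closer to %g deg: %d\n",
              x$ref_centre, x$n_closer_to_ref, x$null_centre,
              x$n_closer_to_zero))
  print(x$bayes_factor)
  invisible(x)
}

#' Flanker weight as a function of target-flanker spacing
#'
#' For each spacing in a spacing-experiment trial table: summarize,
#' fit the derivative-of-Gaussian bias curve with all parameters free, and
#' report the fitted maximal slope `a` (the flanker weight) together with
#' the normalized target-flanker distance. The standard error of the
#' weight comes from a trial-level bootstrap (resampling within
#' (observer, offset) cells).
#'
#' The width is constrained to `s_range` (default 15-60 deg): at spacings
#' beyond the critical range the bias curve is flat, and an unconstrained
#' width can collapse onto single-point noise, turning the slope
#' parameter into an artifact. The crowding signature's width is set by
#' the summed cue variances (roughly 20-30 deg here), so the band is
#' generous in both directions.
#'
#' @param trials a filtered spacing-experiment trial table (one
#'   reliability condition).
#' @param eccentricity degrees of visual angle; taken from the trials if
#'   NULL.
#' @param n_boot bootstrap iterations for the standard error.
#' @param seed integer seed.
#' @param s_range bounds on the DoG width passed to [fit_dog()].
#' @return a data.frame with one row per spacing: `spacing`,
#'   `normalized_distance`, `weight`, `weight_se`, `converged`.
#' @export
spacing_weights <- function(trials, eccentricity = NULL, n_boot = 200,
                            seed = 1, s_range = c(15, 60)) {
  if (is.null(eccentricity)) {
    eccentricity <- stats::median(trials$eccentricity, na.rm = TRUE)
  }
  spacings <- sort(unique(trials$spacing))
  set.seed(seed)
  rows <- lapply(spacings, function(sp) {
    sub <- trials[trials$spacing == sp, , drop = FALSE]
    fit <- tryCatch(suppressWarnings(
      fit_dog(summarize_conditions(sub), include_scatter = FALSE,
              s_range = s_range)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(spacing = sp,
                        normalized_distance = sp / eccentricity,
                        weight = NA_real_, weight_se = NA_real_,
                        converged = FALSE))
    }
    cells <- .cell_indices(sub)
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- .resample_within_cells(cells)
      f <- tryCatch(suppressWarnings(
        fit_dog(summarize_conditions(sub[idx, , drop = FALSE]),
                include_scatter = FALSE, s_range = s_range)),
        error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$a
    }, numeric(1))
    data.frame(spacing = sp, normalized_distance = sp / eccentricity,
               weight = fit$a,
               weight_se = stats::sd(boots, na.rm = TRUE),
               converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
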
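# Trial-table data model, delimited-text I/O, exclusion filters and
# bias/scatter condition summaries.

# Canonical column set of a trial table. `flanker_offset1/2` are always
# re-derived as flanker orientation minus target orientation.
.trial_columns <- c(
  "observer_id", "experiment_id", "target_ori",
  "flanker1_ori", "flanker2_ori", "flanker_offset1", "flanker_offset2",
  "target_aspect", "flanker_aspect", "spacing", "eccentricity",
  "response_ori", "response_time", "flanker_kind", "locked_flanker"
)

.required_columns <- c("observer_id", "target_ori", "response_ori")

.numeric_columns <- c(
  "target_ori", "flanker1_ori", "flanker2_ori",
  "flanker_offset1", "flanker_offset2", "target_aspect", "flanker_aspect",
  "spacing", "eccentricity", "response_ori", "response_time",
  "locked_flanker"
)

#' Read a trial table from delimited text
#'
#' Reads one reproduction trial per row. External files (e.g. a public data
#' deposit with its own column names) are adapted through `dialect`, a named
#' character vector mapping canonical column names to the file's column
#' names, e.g. `c(observer_id = "subj", response_ori = "resp")`.
#'
#' Flanker offsets are always re-derived as flanker orientation minus target
#' orientation, so all stimuli live on a linear degree scale (the designs
#' supported here keep flankers within +/-45 deg of the target; no circular
#' wrapping is applied).
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect optional named character vector renaming file columns to
#'   canonical names (names = canonical, values = file column).
#' @param sep field separator, comma by default.
#' @return a data.frame with the canonical trial columns; rows whose numeric
#'   fields fail to parse are dropped with a warning naming the row indices.
#' @seealso [write_trials()], [filter_trials()], [summarize_conditions()]
#' @export
read_trials <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) {
    stop("trial table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (nrow(df) == 0L) {
    stop("empty trial table: ", path, call. = FALSE)
  }
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || any(names(dialect) == "")) {
      stop("`dialect` must be a fully named character vector", call. = FALSE)
    }
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(df)) {
        stop("dialect column not present in file: ", file_col, call. = FALSE)
      }
      names(df)[names(df) == file_col] <- canon
    }
  }
  missing <- setdiff(.required_columns, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as_trials(df)
}

#' Coerce a data.frame to the canonical trial schema
#'
#' Fills absent optional columns with defaults, coerces numeric fields
#' (dropping unparseable rows with a warning), and derives flanker offsets.
#'
#' @param df a data.frame containing at least observer_id, target_ori and
#'   response_ori.
#' @return a canonical trial data.frame.
#' @export
as_trials <- function(df) {
  if (!"experiment_id" %in% names(df)) df$experiment_id <- "yoked"
  if (!"flanker_kind" %in% names(df)) df$flanker_kind <- "parallel_pair"
  for (col in setdiff(.trial_columns, names(df))) {
    df[[col]] <- NA_real_
  }
  bad <- rep(FALSE, nrow(df))
  for (col in .numeric_columns) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- bad | (!is.na(raw) & raw != "" & is.na(num))
    df[[col]] <- num
  }
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with unparseable numerics: rows ",
            paste(utils::head(which(bad), 20L), collapse = ", "),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df$observer_id <- as.character(df$observer_id)
  df$experiment_id <- as.character(df$experiment_id)
  df$flanker_kind <- as.character(df$flanker_kind)
  df$flanker_offset1 <- df$flanker1_ori - df$target_ori
  df$flanker_offset2 <- df$flanker2_ori - df$target_ori
  rownames(df) <- NULL
  df[, .trial_columns]
}

#' Write a trial table to delimited text
#'
#' @param trials a trial data.frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, sep = ",") {
  out <- trials
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # 17 significant digits: the write/read round trip is bit-exact
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Apply the standard trial exclusion filters
#'
#' Two sequential filters: first, responses outside the response-time window
#' (default 0.5-3 s after stimulus offset) are removed; then, among the
#' survivors, gross errors (absolute reproduction error above
#' `max_abs_error`, default 35 deg) are removed. Boundary values (exactly
#' 0.5 s, 3 s, or 35 deg) are retained; removal uses strict inequalities.
#' The sequential order makes the two reported fractions a clean partition:
#' the RT fraction is relative to all input trials, the error fraction
#' relative to RT survivors.
#'
#' @param trials a trial data.frame with `response_time` and `response_ori`
#'   populated.
#' @param rt_window numeric length-2, retained response-time window in
#'   seconds.
#' @param max_abs_error maximum retained absolute error in degrees.
#' @return a list with elements `trials` (the retained rows) and `report`
#'   (a `filter_report`: counts, fractions, and a per-experiment breakdown).
#' @export
filter_trials <- function(trials, rt_window = c(0.5, 3.0),
                          max_abs_error = 35) {
  stopifnot(is.numeric(rt_window), length(rt_window) == 2L,
            rt_window[1] < rt_window[2], max_abs_error > 0)
  if (!"response_time" %in% names(trials) ||
      all(is.na(trials$response_time))) {
    stop("filter_trials() requires a populated `response_time` column",
         call. = FALSE)
  }
  n_input <- nrow(trials)
  rt <- trials$response_time
  rt_out <- !is.na(rt) & (rt < rt_window[1] | rt > rt_window[2])
  surv <- trials[!rt_out, , drop = FALSE]
  err <- surv$response_ori - surv$target_ori
  err_out <- !is.na(err) & abs(err) > max_abs_error
  kept <- surv[!err_out, , drop = FALSE]

  mk_report <- function(n_in, n_rt, n_err) {
    n_ret <- n_in - n_rt - n_err
    structure(list(
      n_input = n_in, n_rt_removed = n_rt, n_error_removed = n_err,
      n_retained = n_ret,
      fraction_rt_removed = if (n_in > 0) n_rt / n_in else 0,
      fraction_error_removed = if (n_in - n_rt > 0) n_err / (n_in - n_rt) else 0
    ), class = "filter_report")
  }
  report <- mk_report(n_input, sum(rt_out), sum(err_out))

  # pooled vs per-experiment fractions are both of interest when several
  # experiments share one table
  if (length(unique(trials$experiment_id)) > 1L) {
    exps <- sort(unique(trials$experiment_id))
    report$by_experiment <- do.call(rbind, lapply(exps, function(e) {
      in_e <- trials$experiment_id == e
      rt_e <- sum(rt_out & in_e)
      err_e <- sum(err_out & surv$experiment_id == e)
      r <- mk_report(sum(in_e), rt_e, err_e)
      data.frame(experiment_id = e, n_input = r$n_input,
                 n_rt_removed = r$n_rt_removed,
                 n_error_removed = r$n_error_removed,
                 n_retained = r$n_retained,
                 fraction_rt_removed = r$fraction_rt_removed,
                 fraction_error_removed = r$fraction_error_removed)
    }))
  }
  list(trials = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter report: %d trials in, %d RT-removed (%.1f%%), %d error-removed (%.1f%% of survivors), %d retained\n",
    x$n_input, x$n_rt_removed, 100 * x$fraction_rt_removed,
    x$n_error_removed, 100 * x$fraction_error_removed, x$n_retained))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(n_input = x$n_input, n_rt_removed = x$n_rt_removed,
             n_error_removed = x$n_error_removed, n_retained = x$n_retained,
             fraction_rt_removed = x$fraction_rt_removed,
             fraction_error_removed = x$fraction_error_removed)
}

# Flanker offset entering the condition summaries: for yoked designs the
# common offset, for the locked-flanker design the VARIABLE flanker's
# offset, NA for orthogonal/absent control flankers.
trial_theta <- function(trials) {
  off1 <- trials$flanker_offset1
  off2 <- trials$flanker_offset2
  kind <- as.character(trials$flanker_kind)
  theta <- ifelse(!is.na(off1) & !is.na(off2), (off1 + off2) / 2,
                  ifelse(!is.na(off1), off1, off2))
  locked <- trials$locked_flanker
  sel <- kind == "locked_plus_variable" & !is.na(locked)
  theta[sel] <- ifelse(locked[sel] == 1, off2[sel], off1[sel])
  theta[kind %in% c("orthogonal", "absent")] <- NA_real_
  theta
}

#' Summarize bias and scatter per condition and flanker offset
#'
#' For every combination of the grouping columns, flanker offset and target
#' orientation, and separately per observer, the reproduction errors
#' (response minus target) yield a cell mean and a cell standard deviation
#' (sample variance, i.e. n-1 denominator). Bias is the equal-weight average
#' of cell means over observers; scatter is the equal-weight average of the
#' root variance of each observer's residuals. Both are then averaged over
#' the two target orientations with equal weight, which cancels the
#' regression-to-the-mean constant. Cells with fewer than 2 trials
#' contribute to bias but are excluded from scatter (flagged via
#' `scatter_ok` and a warning).
#'
#' For the locked-flanker experiment the offset axis is the variable
#' flanker's offset; which physical flanker was locked is ignored in
#' grouping (the design randomizes it).
#'
#' @param trials a filtered trial data.frame.
#' @param grouping character vector of trial columns defining a condition.
#' @return a data.frame with the grouping columns plus `theta`, `bias`,
#'   `scatter`, `n_trials`, `n_observers`, `scatter_ok`.
#' @export
summarize_conditions <- function(trials,
                                 grouping = c("experiment_id",
                                              "target_aspect", "spacing",
                                              "flanker_kind")) {
  unknown <- setdiff(grouping, names(trials))
  if (length(unknown)) {
    stop("unknown grouping key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("no trials to summarize", call. = FALSE)
  err <- trials$response_ori - trials$target_ori
  theta <- trial_theta(trials)

  gvals <- lapply(grouping, function(g) trials[[g]])
  names(gvals) <- grouping
  cond_key <- do.call(paste, c(gvals, list(sep = "\r")))
  cell_key <- paste(cond_key, theta, trials$target_ori, trials$observer_id,
                    sep = "\r")
  idx <- split(seq_len(nrow(trials)), cell_key)

  first <- vapply(idx, `[`, integer(1), 1L)
  cell <- data.frame(
    cond = cond_key[first],
    theta = theta[first],
    target = trials$target_ori[first],
    observer = trials$observer_id[first],
    n = lengths(idx),
    mean_err = vapply(idx, function(i) mean(err[i]), numeric(1)),
    sd_err = vapply(idx, function(i)
      if (length(i) >= 2L) stats::sd(err[i]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
  n_small <- sum(cell$n < 2L)
  if (n_small > 0L) {
    warning(n_small,
            " cell(s) with fewer than 2 trials excluded from scatter",
            call. = FALSE)
  }

  # per (condition, theta, target): average over observers
  tkey <- paste(cell$cond, cell$theta, cell$target, sep = "\r")
  tidx <- split(seq_len(nrow(cell)), tkey)
  tfirst <- vapply(tidx, `[`, integer(1), 1L)
  lvl_t <- data.frame(
    cond = cell$cond[tfirst],
    theta = cell$theta[tfirst],
    target = cell$target[tfirst],
    bias = vapply(tidx, function(i) mean(cell$mean_err[i]), numeric(1)),
    scatter = vapply(tidx, function(i) {
      s <- cell$sd_err[i]
      if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
    }, numeric(1)),
    n_trials = vapply(tidx, function(i) sum(cell$n[i]), numeric(1)),
    ok = vapply(tidx, function(i) all(cell$n[i] >= 2L), logical(1)),
    stringsAsFactors = FALSE
  )

  # average over the two targets with equal weight
  ckey <- paste(lvl_t$cond, lvl_t$theta, sep = "\r")
  cidx <- split(seq_len(nrow(lvl_t)), ckey)
  cfirst <- vapply(cidx, `[`, integer(1), 1L)
  obs_by_ct <- split(cell$observer, paste(cell$cond, cell$theta, sep = "\r"))

  out_cond <- lvl_t$cond[cfirst]
  out <- data.frame(
    theta = lvl_t$theta[cfirst],
    bias = vapply(cidx, function(i) mean(lvl_t$bias[i]), numeric(1)),
    scatter = vapply(cidx, function(i) mean(lvl_t$scatter[i]), numeric(1)),
    n_trials = vapply(cidx, function(i) sum(lvl_t$n_trials[i]), numeric(1)),
    stringsAsFactors = FALSE
  )
  ct <- paste(out_cond, out$theta, sep = "\r")
  out$n_observers <- vapply(ct, function(k)
    length(unique(obs_by_ct[[k]])), numeric(1))
  out$scatter_ok <- vapply(cidx, function(i) all(lvl_t$ok[i]), logical(1))

  parts <- strsplit(out_cond, "\r", fixed = TRUE)
  for (j in seq_along(grouping)) {
    vals <- vapply(parts, `[`, character(1), j)
    tmpl <- trials[[grouping[j]]]
    out[[grouping[j]]] <- if (is.numeric(tmpl))
      suppressWarnings(as.numeric(vals)) else vals
  }
  out <- out[, c(grouping, "theta", "bias", "scatter", "n_trials",
                 "n_observers", "scatter_ok")]
  ord <- do.call(order, c(out[grouping], list(out$theta)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pythagorean total-error decomposition
#'
#' Total root-mean-square error per condition cell is the Pythagorean sum of
#' bias B and scatter S: E = sqrt(B^2 + S^2).
#'
#' @param summaries output of [summarize_conditions()] (needs finite `bias`
#'   and `scatter`).
#' @return the input data.frame with an added `rmse` column.
#' @export
rmse_by_condition <- function(summaries) {
  stopifnot(all(c("bias", "scatter") %in% names(summaries)))
  if (any(!is.finite(summaries$bias))) {
    stop("non-finite bias in summaries", call. = FALSE)
  }
  summaries$rmse <- sqrt(summaries$bias^2 + summaries$scatter^2)
  summaries
}

#' Normalized target-flanker distance (Bouma ratio)
#'
#' Centre-to-centre target-flanker spacing divided by eccentricity, the
#' scale on which critical crowding distance is roughly constant.
#'
#' @param spacing centre-to-centre distance, degrees of visual angle.
#' @param eccentricity target eccentricity, degrees of visual angle (> 0).
#' @return `spacing / eccentricity`.
#' @export
normalized_distance <- function(spacing, eccentricity) {
  if (any(!is.finite(eccentricity)) || any(eccentricity <= 0)) {
    stop("eccentricity must be positive", call. = FALSE)
  }
  spacing / eccentricity
}
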
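#' Specify an exposure-history functional
#'
#' An exposure-history functional g maps a subject's exposure trajectory up to
#' an occasion to a scalar summary X(t): the cumulative average since the
#' first occasion, a b-unit moving average, or a b-unit cumulative sum.
#' Absent exposure records (missingness indicator `present = FALSE`) never
#' contribute.
#'
#' The cumulative average at occasion j weights each earlier exposure by the
#' forward gap to the next occasion and divides by the elapsed time
#' `t_j - t_1`; the value at `t_j` never uses the exposure at `t_j` itself.
#' At the first occasion the functional is not defined by that formula;
#' `baseline = "single"` uses the single exposure value at the first occasion
#' (the continuity limit), `baseline = "exclude"` drops the first occasion
#' from downstream outcome fitting. Moving-average and cumulative-sum windows
#' are closed, `[t - window, t]`.
#'
#' @param kind `"cumavg"`, `"movavg"` or `"cumsum"`.
#' @param window Positive window length b, in the units of the outcome time
#'   scale; required for `"movavg"` and `"cumsum"`, ignored for `"cumavg"`.
#' @param baseline `"single"` or `"exclude"`; first-occasion rule for
#'   `"cumavg"`.
#' @return An object of class `history_spec`.
#' @examples
#' history_spec("cumavg")
#' history_spec("movavg", window = 3)
#' @export
history_spec <- function(kind = c("cumavg", "movavg", "cumsum"),
                         window = NULL, baseline = c("single", "exclude")) {
  kind <- match.arg(kind)
  baseline <- match.arg(baseline)
  if (kind %in% c("movavg", "cumsum")) {
    if (is.null(window) || !is.numeric(window) || window <= 0) {
      stop("`window` must be a positive number for kind = '", kind, "'",
           call. = FALSE)
    }
  } else {
    window <- NULL
  }
  structure(list(kind = kind, window = window, baseline = baseline),
            class = "history_spec")
}

#' @export
print.history_spec <- function(x, ...) {
  cat("<history_spec>", x$kind,
      if (!is.null(x$window)) paste0("window=", x$window),
      paste0("baseline=", x$baseline), "\n")
  invisible(x)
}

#' Cumulative-average exposure history at one occasion
#'
#' Evaluates X(t_j) = sum_{k=1}^{j-1} v_k (t_{k+1} - t_k) / (t_j - t_1) over
#' the present records of one subject, where the forward gap of the last
#' contributing record extends to `t_j`.
#'
#' @param times Strictly increasing occasion times.
#' @param values Exposure values at those occasions (the value at the target
#'   occasion itself is never used).
#' @param j Target occasion index (into `times`).
#' @param present Logical missingness indicator per occasion; absent records
#'   are skipped entirely.
#' @param baseline First-occasion rule, `"single"` or `"exclude"`.
#' @return A one-row tibble with `t_outcome`, `value`, `n_contributing`
#'   (`value` is `NA` for an excluded baseline occasion).
#' @examples
#' cumulative_average(c(1, 2, 3), c(2, 4, NA), j = 3) # 3
#' @export
cumulative_average <- function(times, values, j, present = NULL,
                               baseline = c("single", "exclude")) {
  baseline <- match.arg(baseline)
  if (is.null(present)) present <- rep(TRUE, length(times))
  stopifnot(length(times) == length(values), length(present) == length(times))
  if (j < 1 || j > length(times)) stop("`j` out of range", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  t_target <- times[j]
  s <- times[present]
  v <- values[present]
  before <- s < t_target
  K <- sum(before)
  if (K == 0) {
    if (baseline == "exclude") {
      stop("cumulative average is not defined at the first occasion under ",
           "baseline = 'exclude'", call. = FALSE)
    }
    at_or_before <- which(s <= t_target)
    if (length(at_or_before) == 0) {
      stop("no present exposure record at or before the target occasion",
           call. = FALSE)
    }
    return(tibble::tibble(t_outcome = t_target, value = v[at_or_before[1]],
                          n_contributing = 1L))
  }
  if (t_target <= s[1]) {
    stop("degenerate spacing: target time does not exceed the first ",
         "contributing time", call. = FALSE)
  }
  sb <- s[seq_len(K)]
  vb <- v[seq_len(K)]
  gaps <- c(diff(sb), t_target - sb[K])
  tibble::tibble(t_outcome = t_target,
                 value = sum(vb * gaps) / (t_target - sb[1]),
                 n_contributing = K)
}

window_values <- function(times, values, present, t, window) {
  if (is.null(window) || window <= 0) {
    stop("a positive `window` is required", call. = FALSE)
  }
  idx <- present & !is.na(values) & times >= t - window & times <= t
  if (!any(idx)) {
    stop("no present exposure record in the window [", t - window, ", ", t,
         "]", call. = FALSE)
  }
  values[idx]
}

#' Moving-average exposure history at a time point
#'
#' Indicator-weighted mean of the present exposure records in the closed
#' window `[t - window, t]`.
#'
#' @inheritParams cumulative_average
#' @param t Target time point.
#' @param window Positive window length.
#' @examples
#' moving_average(0:2, c(2, NA, 4), t = 2, window = 3,
#'                present = c(TRUE, FALSE, TRUE)) # 3
#' @return A one-row tibble with `t_outcome`, `value`, `n_contributing`.
#' @export
moving_average <- function(times, values, t, window, present = NULL) {
  if (is.null(present)) present <- rep(TRUE, length(times))
  v <- window_values(times, values, present, t, window)
  tibble::tibble(t_outcome = t, value = mean(v), n_contributing = length(v))
}

#' Cumulative-sum exposure history at a time point
#'
#' Indicator-weighted sum of the present exposure records in the closed
#' window `[t - window, t]`.
#'
#' @inheritParams moving_average
#' @return A one-row tibble with `t_outcome`, `value`, `n_contributing`.
#' @export
cumulative_sum <- function(times, values, t, window, present = NULL) {
  if (is.null(present)) present <- rep(TRUE, length(times))
  v <- window_values(times, values, present, t, window)
  tibble::tibble(t_outcome = t, value = sum(v), n_contributing = length(v))
}

#' Calibrated exposure history at one occasion
#'
#' Applies the history functional to pointwise calibrated exposures
#' f(C_k, t_mem_k, W_k; alpha) instead of the (unobserved) true exposures:
#' each surrogate record is first mapped through the fitted measurement error
#' model on the MEM time scale, then g is evaluated with weights on the
#' outcome time scale.
#'
#' @param times Outcome-scale occasion times, strictly increasing.
#' @param surrogate Surrogate exposure values C at those occasions.
#' @param j Target occasion index (for `"cumavg"`) .
#' @param spec A [history_spec()].
#' @param mem A fitted measurement error model ([fit_mem()]) or a
#'   `mem_params` object.
#' @param t_mem MEM-scale times; defaults to `times`.
#' @param W Optional covariate matrix (rows = occasions) matching the MEM's
#'   covariate terms.
#' @param present Logical indicator per occasion.
#' @return A one-row tibble with `t_outcome`, `value`, `n_contributing`.
#' @examples
#' mem <- mem_params(c(1.2, 0.7), c("intercept", "C"))
#' calibrated_history(c(1, 2, 3), c(2, 4, NA), j = 3,
#'                    spec = history_spec("cumavg"), mem = mem) # 3.3
#' @export
calibrated_history <- function(times, surrogate, j, spec, mem,
                               t_mem = NULL, W = NULL, present = NULL) {
  if (is.null(t_mem)) t_mem <- times
  fhat <- mem_predict(mem, C = surrogate, t_mem = t_mem, W = W)
  switch(spec$kind,
    cumavg = cumulative_average(times, fhat, j, present = present,
                                baseline = spec$baseline),
    movavg = moving_average(times, fhat, t = times[j], window = spec$window,
                            present = present),
    cumsum = cumulative_sum(times, fhat, t = times[j], window = spec$window,
                            present = present)
  )
}

# ---- vectorised per-study evaluation -------------------------------------

# Fast path: cumulative average over fully-present, sorted study rows.
# id must be an integer grouping vector with contiguous runs.
cumavg_vec <- function(gid, t, v, baseline) {
  n <- length(t)
  first <- !duplicated(gid)
  last <- !duplicated(gid, fromLast = TRUE)
  gap <- c(t[-1] - t[-n], 0)
  gap[last] <- 0
  wv <- v * gap
  cs <- cumsum(wv)
  base <- cs[first]            # cumsum at each group's first row
  offset <- rep(base - wv[first], times = tabulate(gid)[unique(gid)])
  gcs <- cs - offset           # grouped cumsum of wv
  num <- c(0, gcs[-n])
  num[first] <- 0
  t1 <- rep(t[first], times = tabulate(gid)[unique(gid)])
  den <- t - t1
  val <- ifelse(den > 0, num / den, NA_real_)
  if (baseline == "single") val[first] <- v[first]
  ncontrib <- stats::ave(rep(1, n), gid, FUN = cumsum) - 1
  ncontrib[first] <- if (baseline == "single") 1 else 0
  list(value = val, n_contributing = as.integer(ncontrib))
}

#' Exposure-history values for every occasion of a study
#'
#' Evaluates the history functional for each subject-occasion of a study, on
#' the observed surrogate exposures, the true exposures (validation data), or
#' the calibrated exposures f(C, t_mem, W; alpha) from a fitted measurement
#' error model.
#'
#' @param study A [study_data()] tibble.
#' @param spec A [history_spec()].
#' @param source `"surrogate"`, `"true"`, or `"calibrated"` (requires `mem`).
#' @param mem A [fit_mem()] result or [mem_params()], for
#'   `source = "calibrated"`.
#' @return A tibble with one row per study row: `.id`, `.t_out`, `value`,
#'   `n_contributing`. `value` is `NA` at occasions where the functional is
#'   excluded (`baseline = "exclude"`); such rows are dropped by the outcome
#'   fitters.
#' @export
exposure_history <- function(study, spec,
                             source = c("surrogate", "true", "calibrated"),
                             mem = NULL) {
  source <- match.arg(source)
  vals <- switch(source,
    surrogate = study$.C,
    true = study$.c,
    calibrated = {
      if (is.null(mem)) stop("`mem` is required for source = 'calibrated'",
                             call. = FALSE)
      W <- covariate_matrix(study, mem_covariates(mem))
      mem_predict(mem, C = study$.C, t_mem = study$.t_mem, W = W)
    })
  gid <- match(study$.id, unique(study$.id))
  if (spec$kind == "cumavg" && all(study$.present) && !anyNA(vals)) {
    fast <- cumavg_vec(gid, study$.t_out, vals, spec$baseline)
    return(tibble::tibble(.id = study$.id, .t_out = study$.t_out,
                          value = fast$value,
                          n_contributing = fast$n_contributing))
  }
  res <- lapply(split(seq_len(nrow(study)), gid), function(rows) {
    t_i <- study$.t_out[rows]
    v_i <- vals[rows]
    p_i <- study$.present[rows] & !is.na(v_i)
    out <- lapply(seq_along(rows), function(j) {
      switch(spec$kind,
        cumavg = {
          if (spec$baseline == "exclude" &&
              !any(p_i & t_i < t_i[j])) {
            tibble::tibble(t_outcome = t_i[j], value = NA_real_,
                           n_contributing = 0L)
          } else {
            cumulative_average(t_i, v_i, j, present = p_i,
                               baseline = spec$baseline)
          }
        },
        movavg = moving_average(t_i, v_i, t = t_i[j], window = spec$window,
                                present = p_i),
        cumsum = cumulative_sum(t_i, v_i, t = t_i[j], window = spec$window,
                                present = p_i))
    })
    dplyr::bind_rows(out)
  })
  res <- dplyr::bind_rows(res)
  tibble::tibble(.id = study$.id, .t_out = study$.t_out,
                 value = res$value, n_contributing = res$n_contributing)
}
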
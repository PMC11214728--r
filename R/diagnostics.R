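wald_joint <- function(est, V, idx, kind, terms) {
  b <- est[idx]
  Vb <- V[idx, idx, drop = FALSE]
  stat <- drop(crossprod(b, solve(Vb, b)))
  tibble::tibble(test_kind = kind, statistic = stat, df = length(idx),
                 p.value = stats::pchisq(stat, df = length(idx),
                                         lower.tail = FALSE),
                 terms_tested = paste(terms, collapse = ","))
}

lagged_averages <- function(d, lag, covs) {
  # per subject (ordered by MEM time): mean of the `lag` previous surrogates
  # (and covariates); rows with fewer than `lag` previous occasions -> NA
  lag_mean <- function(v) {
    n <- length(v)
    out <- rep(NA_real_, n)
    if (n > lag) {
      cs <- cumsum(v)
      j <- (lag + 1):n
      out[j] <- (cs[j - 1] - c(0, cs)[j - lag]) / lag
    }
    out
  }
  gid <- match(d$.id, unique(d$.id))
  out <- tibble::tibble(
    lagC = unlist(lapply(split(d$.C, gid), lag_mean), use.names = FALSE))
  for (w in covs) {
    out[[paste0("lag", w)]] <-
      unlist(lapply(split(d[[w]], gid), lag_mean), use.names = FALSE)
  }
  out
}

#' Test the localized-error assumption in a validation study
#'
#' The localized-error assumption states that the true exposure at an
#' occasion depends only on the current surrogate, time and covariates, not
#' on past surrogates. With repeated validation measurements it is testable:
#' the two-step variant first fits the MEM with current-time terms only, then
#' regresses its residuals on the cumulative average of the `lag` previous
#' surrogates (and of previous covariates, if any) and jointly tests those
#' coefficients against zero with a cluster-robust Wald test. The one-step
#' variant adds the lagged-average terms directly to the MEM; it is more
#' prone to collinearity in small validation studies.
#'
#' @param vs Validation [study_data()] with repeated measurements.
#' @param lag Positive number of previous occasions averaged.
#' @param terms Current-time MEM terms for step 1.
#' @param variant `"two_step"` (default) or `"one_step"`.
#' @return A one-row tibble: `test_kind`, `statistic`, `df`, `p.value`,
#'   `terms_tested`.
#' @export
localized_error_test <- function(vs, lag = 1,
                                 terms = c("intercept", "C", "t"),
                                 variant = c("two_step", "one_step")) {
  variant <- match.arg(variant)
  if (!is.numeric(lag) || lag < 1) {
    stop("`lag` must be a positive integer", call. = FALSE)
  }
  lag <- as.integer(lag)
  use <- vs$.present & !is.na(vs$.c) & !is.na(vs$.C)
  d <- restudy(vs[use, ], vs)
  d <- d[order(d$.id, d$.t_mem), ]
  covs <- term_covariates(terms, "C")
  lagged <- lagged_averages(d, lag, covs)
  ok <- stats::complete.cases(lagged)
  if (!any(ok)) {
    stop("no validation rows with ", lag, " previous occasion(s) available",
         call. = FALSE)
  }
  lag_names <- names(lagged)

  if (variant == "one_step") {
    W <- cbind(covariate_matrix(d, covs), as.matrix(lagged))[ok, , drop = FALSE]
    X <- build_terms_matrix(c(terms, lag_names), d$.C[ok], d$.t_mem[ok],
                            W, xname = "C")
    fit <- gee_solve(X, d$.c[ok], d$.id[ok], structure = "independence")
    idx <- match(lag_names, names(fit$coefficients))
    return(wald_joint(fit$coefficients, fit$vcov, idx,
                      "localized_error/one_step", lag_names))
  }
  step1 <- fit_mem(d, terms = terms, working = "independence")
  resid <- step1$residuals
  X2 <- cbind(intercept = 1, as.matrix(lagged)[ok, , drop = FALSE])
  fit2 <- gee_solve(X2, resid[ok], d$.id[ok], structure = "independence")
  idx <- match(lag_names, names(fit2$coefficients))
  wald_joint(fit2$coefficients, fit2$vcov, idx,
             "localized_error/two_step", lag_names)
}

#' Test the surrogacy assumption in an internal validation design
#'
#' Given the true exposure history, the surrogate history should carry no
#' further information about the outcome. On subjects with observed true
#' exposures (an internal validation subsample with outcomes), the outcome
#' model is fitted with both the true-history functional X and the
#' surrogate-history functional Z (and its time interaction), and the Z-term
#' coefficients are jointly tested against zero with a cluster-robust Wald
#' test.
#'
#' @param ms_ivs Main-study [study_data()] in which at least some subjects
#'   have the true exposure recorded (an IVS).
#' @param history A [history_spec()].
#' @param outcome_terms Terms for the outcome model (X side).
#' @param working Working correlation for the GEE.
#' @return A one-row tibble as in [localized_error_test()].
#' @export
surrogacy_test <- function(ms_ivs, history = history_spec("cumavg"),
                           outcome_terms = NULL,
                           working = "independence") {
  has_true <- !is.na(ms_ivs$.c)
  ids_ok <- names(which(tapply(has_true, ms_ivs$.id, all)))
  if (length(ids_ok) == 0) {
    stop("no subjects with complete true-exposure records; the surrogacy ",
         "test requires an internal validation design", call. = FALSE)
  }
  d <- restudy(ms_ivs[ms_ivs$.id %in% ids_ok, ], ms_ivs)
  outcome_terms <- outcome_terms %||%
    c("intercept", "X", "t", "X:t", study_covariates(d))
  xh <- exposure_history(d, history, source = "true")
  zh <- exposure_history(d, history, source = "surrogate")
  des <- build_design(d, xh, outcome_terms)
  z <- zh$value[des$kept]
  X <- cbind(des$X, Z = z, `Z:t` = z * des$t)
  keep <- !is.na(des$y)
  fit <- gee_solve(X[keep, , drop = FALSE], des$y[keep], des$id[keep],
                   structure = working, occasion = des$occasion[keep],
                   grid_size = length(des$grid))
  idx <- match(c("Z", "Z:t"), names(fit$coefficients))
  wald_joint(fit$coefficients, fit$vcov, idx, "surrogacy", c("Z", "Z:t"))
}

#' Compare measurement-error-model fits from two validation sources
#'
#' Wald test of equality of the MEM coefficient vectors fitted independently
#' in two validation datasets (a transportability-style comparison), using
#' the sum of the two sandwich variances.
#'
#' @param vs_a,vs_b Validation [study_data()] objects.
#' @param terms Common MEM term list.
#' @param working Working-correlation structure for both fits.
#' @return A one-row tibble as in [localized_error_test()].
#' @export
mem_equality_test <- function(vs_a, vs_b, terms = c("intercept", "C"),
                              working = "independence") {
  fa <- fit_mem(vs_a, terms = terms, working = working)
  fb <- fit_mem(vs_b, terms = terms, working = working)
  delta <- fa$params$alpha - fb$params$alpha
  V <- fa$vcov + fb$vcov
  stat <- drop(crossprod(delta, solve(V, delta)))
  tibble::tibble(test_kind = "mem_equality", statistic = stat,
                 df = length(delta),
                 p.value = stats::pchisq(stat, df = length(delta),
                                         lower.tail = FALSE),
                 terms_tested = paste(terms, collapse = ","))
}

#' Change-in-estimate confounder screen
#'
#' Refits the uncorrected outcome model without each candidate covariate set
#' and reports the relative change in the exposure-by-time coefficient; sets
#' whose removal changes it by more than `threshold` (default 10%) are
#' flagged as likely confounders.
#'
#' @param ms Main-study [study_data()].
#' @param candidate_sets Named list of character vectors of covariate names.
#' @param history A [history_spec()].
#' @param outcome_terms Full-model terms (defaults to all study covariates).
#' @param working Working-correlation structure.
#' @param threshold Flagging threshold as a fraction (0.1 = 10%).
#' @param target Coefficient monitored, default `"X:t"`.
#' @return A tibble with one row per candidate set: estimates from the full
#'   and reduced models, the relative change, and a `flagged` indicator.
#' @export
confounder_screen <- function(ms, candidate_sets,
                              history = history_spec("cumavg"),
                              outcome_terms = NULL, working = "ar1",
                              threshold = 0.1, target = "X:t") {
  outcome_terms <- outcome_terms %||%
    c("intercept", "X", "t", "X:t", study_covariates(ms))
  if (!is.list(candidate_sets)) candidate_sets <- list(candidate_sets)
  if (is.null(names(candidate_sets))) {
    names(candidate_sets) <- vapply(candidate_sets, paste, "", collapse = "+")
  }
  bad <- setdiff(unlist(candidate_sets), outcome_terms)
  if (length(bad) > 0) {
    stop("candidate covariates not in the full model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- fit_naive(ms, history, outcome_terms, working = working)
  b_full <- full$coefficients[[target]]
  rows <- purrr::imap(candidate_sets, function(set, nm) {
    reduced_terms <- setdiff(outcome_terms, set)
    red <- fit_naive(ms, history, reduced_terms, working = working)
    b_red <- red$coefficients[[target]]
    rel <- (b_red - b_full) / b_full
    tibble::tibble(set = nm, dropped = paste(set, collapse = ","),
                   estimate_full = b_full, estimate_reduced = b_red,
                   rel_change = rel, flagged = abs(rel) > threshold)
  })
  dplyr::bind_rows(rows)
}
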
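#' Per-replication substream seed
#'
#' Deterministic rule deriving the seed of replication `r` from the master
#' seed: `(master * 1009 + r * 7919) mod (2^31 - 1)`. The rule is part of
#' the public contract so that any single replication of a study can be
#' regenerated in isolation.
#'
#' @param master Integer master seed.
#' @param r Replication index (1-based).
#' @return An integer seed.
#' @export
substream_seed <- function(master, r) {
  as.integer((as.double(master) * 1009 + as.double(r) * 7919) %% 2147483647)
}

#' Monte-Carlo acceptance band for empirical coverage
#'
#' Two-standard-error band around the nominal level:
#' `100 * level +/- 2 * 100 * sqrt(level * (1 - level) / replications)`,
#' each endpoint rounded to one decimal.
#'
#' @param replications Number of Monte-Carlo replications.
#' @param level Nominal coverage level in (0, 1).
#' @return Named numeric `c(lower, upper)`, in percent.
#' @examples
#' coverage_bounds(1000, 0.95) # 93.6 96.4
#' @export
coverage_bounds <- function(replications, level = 0.95) {
  stopifnot(replications >= 1, level > 0, level < 1)
  margin <- 2 * 100 * sqrt(level * (1 - level) / replications)
  c(lower = round(100 * level - margin, 1),
    upper = round(100 * level + margin, 1))
}

fit_one_estimator <- function(dat, estimator, cfg, mem_terms, working,
                              mem_working, history) {
  if (estimator == "uncorrected") {
    fit <- fit_naive(dat$ms, history, cfg$outcome_terms, working = working)
    b <- fit$coefficients[["X:t"]]
    se <- sqrt(fit$vcov["X:t", "X:t"])
  } else {
    fit <- fit_corrected(dat$ms, dat$vs, design = cfg$design,
                         history = history, mem_terms = mem_terms,
                         outcome_terms = cfg$outcome_terms,
                         working = working, mem_working = mem_working)
    b <- fit$beta[["X:t"]]
    se <- sqrt(fit$vcov["beta:X:t", "beta:X:t"])
  }
  c(estimate = b, se = se)
}

#' Run a Monte-Carlo study of the corrected and uncorrected estimators
#'
#' Generates `replications` datasets from a scenario (replication `r` uses
#' [substream_seed()] of the scenario seed), fits the requested estimators,
#' and summarises the exposure-by-time coefficient: relative bias in percent
#' `100 * (mean(est) - beta3) / beta3`, empirical standard error (SD of the
#' estimates), mean sandwich standard error, and empirical coverage of
#' nominal 95% Wald intervals. Replications where an estimator fails to
#' converge are excluded and counted.
#'
#' @param cfg A [scenario_config()].
#' @param replications Number of replications (>= 2 for an ESE).
#' @param estimators Subset of `c("corrected", "uncorrected")`.
#' @param mem_terms MEM terms fitted by the corrected estimator; defaults to
#'   the scenario's generating terms (a reduced list expresses deliberate
#'   MEM misspecification).
#' @param working Outcome working-correlation structure.
#' @param mem_working Validation-stage working correlation.
#' @param history Exposure-history functional (default cumulative average,
#'   matching the generator).
#' @param keep_draws Also return the per-replication estimates.
#' @return A tibble of class `memlong_simsummary`, one row per estimator:
#'   `estimator`, `relative_bias_pct`, `ese`, `mean_se`, `coverage`,
#'   `replications`, `excluded`. With `keep_draws = TRUE` the per-replication
#'   tibble is attached as attribute `"draws"`.
#' @export
run_sim_study <- function(cfg, replications = 500,
                          estimators = c("corrected", "uncorrected"),
                          mem_terms = NULL, working = "ar1",
                          mem_working = "independence",
                          history = history_spec("cumavg"),
                          keep_draws = FALSE) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  stopifnot(replications >= 1)
  mem_terms <- mem_terms %||% cfg$mem_terms
  beta3 <- cfg$beta_true[["X:t"]]

  draws <- vector("list", replications)
  for (r in seq_len(replications)) {
    dat <- generate_scenario(cfg, seed = substream_seed(cfg$seed, r))
    rows <- lapply(estimators, function(est) {
      res <- tryCatch(
        fit_one_estimator(dat, est, cfg, mem_terms, working, mem_working,
                          history),
        error = function(e) c(estimate = NA_real_, se = NA_real_))
      tibble::tibble(rep = r, estimator = est,
                     estimate = res[["estimate"]], se = res[["se"]])
    })
    draws[[r]] <- dplyr::bind_rows(rows)
  }
  draws <- dplyr::bind_rows(draws)

  summ <- draws |>
    dplyr::group_by(.data$estimator) |>
    dplyr::summarise(
      relative_bias_pct = 100 * (mean(.data$estimate[!is.na(.data$estimate)]) -
                                   beta3) / beta3,
      ese = if (sum(!is.na(.data$estimate)) >= 2)
        stats::sd(.data$estimate, na.rm = TRUE) else NA_real_,
      mean_se = mean(.data$se, na.rm = TRUE),
      coverage = mean(abs(.data$estimate - beta3) <=
                        stats::qnorm(0.975) * .data$se, na.rm = TRUE),
      replications = sum(!is.na(.data$estimate)),
      excluded = sum(is.na(.data$estimate)),
      .groups = "drop")
  summ <- summ[match(estimators, summ$estimator), ]
  attr(summ, "config") <- cfg
  attr(summ, "beta3") <- beta3
  if (keep_draws) attr(summ, "draws") <- draws
  class(summ) <- c("memlong_simsummary", class(summ))
  summ
}

#' Coverage plot for a simulation summary
#'
#' Empirical coverage per estimator with the Monte-Carlo acceptance band
#' around the nominal 95% level.
#'
#' @param object A [run_sim_study()] summary.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.memlong_simsummary <- function(object, ...) {
  reps <- max(object$replications)
  band <- coverage_bounds(reps, 0.95) / 100
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimator, y = .data$coverage)) +
    ggplot2::geom_hline(yintercept = 0.95, linetype = 2) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band[["lower"]], ymax = band[["upper"]],
                      alpha = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "empirical coverage of nominal 95% CIs", x = NULL)
}
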
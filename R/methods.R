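#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

wald_tibble <- function(stage, term, estimate, se, conf.int = TRUE,
                        conf.level = 0.95) {
  out <- tibble::tibble(stage = stage, term = term, estimate = estimate,
                        std.error = se,
                        statistic = estimate / se,
                        p.value = 2 * stats::pnorm(-abs(estimate / se)))
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- estimate - z * se
    out$conf.high <- estimate + z * se
  }
  out
}

#' Tidy a corrected fit into a coefficient table
#'
#' One row per coefficient of the stacked parameter `theta = (alpha, beta)`,
#' with sandwich standard errors and Wald confidence intervals.
#'
#' @param x A `memlong_fit` object.
#' @param conf.int,conf.level Confidence-interval controls.
#' @param ... Unused.
#' @return A tibble with columns `stage` (`"mem"` / `"outcome"`), `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value` and optionally
#'   `conf.low`, `conf.high`.
#' @export
tidy.memlong_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  stage <- ifelse(startsWith(names(x$theta), "alpha:"), "mem", "outcome")
  term <- sub("^(alpha|beta):", "", names(x$theta))
  wald_tibble(stage, term, unname(x$theta), unname(se), conf.int, conf.level)
}

#' @rdname tidy.memlong_fit
#' @export
tidy.memlong_gee <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  wald_tibble("outcome", names(x$coefficients), unname(x$coefficients),
              unname(se), conf.int, conf.level)
}

#' @rdname tidy.memlong_fit
#' @export
tidy.memlong_mem <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  wald_tibble("mem", names(x$params$alpha), unname(x$params$alpha),
              unname(se), conf.int, conf.level)
}

#' @rdname glance.memlong_fit
#' @export
glance.memlong_gee <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_obs = x$n_obs,
                 working = x$working$structure, phi = x$working$phi,
                 rho = if (is.matrix(x$working$rho)) NA_real_ else
                   x$working$rho %||% NA_real_,
                 n_iter = x$n_iter, converged = x$converged)
}

#' One-row model summaries
#'
#' @param x A fitted memlong object.
#' @param ... Unused.
#' @return A one-row tibble of fit-level quantities.
#' @export
glance.memlong_fit <- function(x, ...) {
  tibble::tibble(design = x$design, n_main = x$n_main,
                 n_validation = x$n_validation,
                 p_alpha = length(x$alpha), p_beta = length(x$beta),
                 working = x$outcome_fit$working$structure,
                 converged = x$converged)
}

#' @rdname glance.memlong_fit
#' @export
glance.memlong_mem <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_obs = x$n_obs,
                 working = x$working$structure,
                 n_iter = x$n_iter, converged = x$converged)
}

#' Coefficient plot for a fitted model
#'
#' Dot-and-interval plot of the estimates and 95% Wald intervals, faceted by
#' estimation stage for corrected fits.
#'
#' @param object A `memlong_fit`, `memlong_gee` or `memlong_mem` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.memlong_fit <- function(object, ...) {
  d <- generics::tidy(object, conf.int = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~stage, scales = "free") +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL)
}

#' @rdname autoplot.memlong_fit
#' @export
autoplot.memlong_gee <- autoplot.memlong_fit

#' @rdname autoplot.memlong_fit
#' @export
autoplot.memlong_mem <- autoplot.memlong_fit
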
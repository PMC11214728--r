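scenario_levels <- c("NI-NW", "NI-WP", "NI-WC", "IP-NW", "IP-WP", "IP-WC")

#' Configure a factorial measurement-error simulation scenario
#'
#' Scenarios cross two factors of the true measurement error model: whether a
#' surrogate-by-time interaction is present (NI / IP) and whether a covariate
#' W is present and correlated with the surrogate (NW / WP uncorrelated / WC
#' correlated at 0.4). The MEM coefficients are
#' `alpha = (1.2, 0.7, 0.6, 0.5, 0.4)` for (intercept, C, t, C:t, W) as
#' applicable; the outcome model has `beta0 = 0.5`, `beta2 = 3`, `beta4 = 1`
#' when W is present, and user-chosen `(beta1, beta3)` (default `(3, 3)`).
#' Outcomes are multivariate normal with AR(1) errors (`sigma2_Y = 1`,
#' `rho_Y = 0.1`) over five occasions at times 1..5; the exposure-history
#' functional is the cumulative average of the exposures. The MEM noise
#' variance is calibrated so that the model-implied Corr(c, C) matches the
#' scenario target (0.60, 0.65, 0.57, 0.84, 0.85, 0.84 respectively).
#'
#' @param scenario One of `"NI-NW"`, `"NI-WP"`, `"NI-WC"`, `"IP-NW"`,
#'   `"IP-WP"`, `"IP-WC"`.
#' @param design `"evs"` or `"ivs"`.
#' @param n1,n2 Main-study and validation-study sample sizes.
#' @param li Validation measurements per subject: 1 (one occasion retained,
#'   chosen uniformly) or 5 (all occasions).
#' @param beta1,beta3 Exposure main-effect and exposure-by-time coefficients.
#' @param seed Integer seed; [generate_scenario()] is a deterministic
#'   function of the configuration including this seed.
#' @return An object of class `memlong_scenario`.
#' @examples
#' cfg <- scenario_config("NI-NW", n1 = 200, n2 = 50, seed = 1)
#' @export
scenario_config <- function(scenario = scenario_levels,
                            design = c("evs", "ivs"),
                            n1 = 1000, n2 = 100, li = 5,
                            beta1 = 3, beta3 = 3, seed = 1) {
  scenario <- match.arg(scenario)
  design <- match.arg(design)
  if (!li %in% c(1, 5)) stop("`li` must be 1 or 5", call. = FALSE)
  if (design == "ivs" && n2 > n1) {
    stop("IVS design requires n2 <= n1", call. = FALSE)
  }
  interaction <- startsWith(scenario, "IP")
  wlevel <- sub("^..-", "", scenario)
  has_w <- wlevel != "NW"
  corr_cw <- if (wlevel == "WC") 0.4 else 0
  mem_terms <- c("intercept", "C",
                 if (interaction) c("t", "C:t"),
                 if (has_w) "W")
  alpha_all <- c(intercept = 1.2, C = 0.7, t = 0.6, `C:t` = 0.5, W = 0.4)
  alpha <- alpha_all[mem_terms]
  target <- c("NI-NW" = 0.60, "NI-WP" = 0.65, "NI-WC" = 0.57,
              "IP-NW" = 0.84, "IP-WP" = 0.85, "IP-WC" = 0.84)[[scenario]]
  beta_terms <- c("intercept", "X", "t", "X:t", if (has_w) "W")
  beta <- stats::setNames(c(0.5, beta1, 3, beta3, if (has_w) 1), beta_terms)
  cfg <- structure(list(scenario = scenario, design = design,
                        n1 = as.integer(n1), n2 = as.integer(n2),
                        li = as.integer(li),
                        occasions = 1:5,
                        interaction = interaction, has_w = has_w,
                        corr_cw = corr_cw, corr_target = target,
                        mem_terms = mem_terms, alpha_true = alpha,
                        outcome_terms = beta_terms, beta_true = beta,
                        sigma2_Y = 1, rho_Y = 0.1,
                        seed = as.integer(seed)),
                   class = "memlong_scenario")
  cfg$sigma2_eps <- calibrate_noise(cfg)
  cfg
}

#' @export
print.memlong_scenario <- function(x, ...) {
  cat("<memlong_scenario>", x$scenario, toupper(x$design),
      sprintf("n1=%d n2=%d li=%d (beta1,beta3)=(%g,%g)",
              x$n1, x$n2, x$li, x$beta_true[["X"]], x$beta_true[["X:t"]]),
      sprintf("sigma2_eps=%.4f seed=%d", x$sigma2_eps, x$seed), "\n")
  invisible(x)
}

# Model-implied Corr(c, C) over a (subject, occasion) pair drawn with C, W
# standard normal (Corr(C, W) = corr_cw) and t uniform on the occasion grid.
implied_corr <- function(cfg, sigma2_eps) {
  a <- cfg$alpha_true
  a1 <- a[["C"]]
  a2 <- if (cfg$interaction) a[["t"]] else 0
  a3 <- if (cfg$interaction) a[["C:t"]] else 0
  a4 <- if (cfg$has_w) a[["W"]] else 0
  tg <- cfg$occasions
  Et <- mean(tg); Et2 <- mean(tg^2); Vt <- Et2 - Et^2
  cov_cC <- a1 + a3 * Et + a4 * cfg$corr_cw
  v0 <- (a1^2 + 2 * a1 * a3 * Et + a3^2 * Et2) +  # (a1 + a3 t) C
    a2^2 * Vt +                                    # a2 t
    a4^2 +                                         # a4 W
    2 * a4 * cfg$corr_cw * (a1 + a3 * Et)          # cross (C-part, W)
  cov_cC / sqrt(v0 + sigma2_eps)
}

#' Calibrate the measurement-error noise variance to a target correlation
#'
#' Returns the noise variance `sigma2_eps` for which the model-implied
#' Corr(c, C) -- over subject-occasion pairs with standard-normal surrogate,
#' W paired at the scenario's Corr(C, W) and occasion time uniform on the
#' grid -- equals the scenario's printed target. Closed-form inversion of
#' the correlation formula for the no-interaction scenarios; one-dimensional
#' root-finding over the grid moments for the interaction scenarios.
#'
#' @param cfg A [scenario_config()] (the `sigma2_eps` field is ignored).
#' @return Positive noise variance.
#' @export
calibrate_noise <- function(cfg) {
  upper <- implied_corr(cfg, 0)
  if (cfg$corr_target >= upper) {
    stop(sprintf(paste0("target Corr(c,C) = %.3f is unattainable: the ",
                        "noise-free bound is %.4f"),
                 cfg$corr_target, upper), call. = FALSE)
  }
  if (!cfg$interaction) {
    a <- cfg$alpha_true
    cov_cC <- a[["C"]] + (if (cfg$has_w) a[["W"]] * cfg$corr_cw else 0)
    v0 <- (cov_cC / upper)^2  # Var(c) - sigma2_eps, recovered from the bound
    return((cov_cC / cfg$corr_target)^2 - v0)
  }
  f <- function(s2) implied_corr(cfg, s2) - cfg$corr_target
  stats::uniroot(f, lower = 1e-10, upper = 1e4, tol = 1e-12)$root
}

ar1_chol <- function(m, rho, sigma2) {
  S <- sigma2 * rho^abs(outer(seq_len(m), seq_len(m), "-"))
  chol(S)
}

#' Generate one main-study/validation-study dataset pair
#'
#' Draws, for every subject at the five occasion times, a standard-normal
#' surrogate exposure (and covariate W at the scenario's correlation), the
#' true exposure from the scenario's measurement error model with calibrated
#' noise, the cumulative-average exposure history of the true exposures, and
#' multivariate-normal outcomes with AR(1) errors around the outcome-model
#' mean. Under an external design the validation subjects are a separate
#' group without outcomes; under an internal design they are a subsample of
#' the main study. With `li = 1` a single uniformly chosen occasion is
#' retained per validation subject. The simulation uses the same variable
#' for the outcome-model and MEM time scales.
#'
#' @param cfg A [scenario_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A list with elements `ms` and `vs` ([study_data()] tibbles) and
#'   `config`.
#' @export
generate_scenario <- function(cfg, seed = NULL) {
  set.seed(seed %||% cfg$seed)
  tg <- cfg$occasions
  m <- length(tg)
  n_subj <- cfg$n1 + if (cfg$design == "evs") cfg$n2 else 0L
  a <- cfg$alpha_true
  b <- cfg$beta_true

  C <- matrix(stats::rnorm(n_subj * m), n_subj, m)
  W <- if (cfg$has_w) {
    cfg$corr_cw * C + sqrt(1 - cfg$corr_cw^2) *
      matrix(stats::rnorm(n_subj * m), n_subj, m)
  }
  eps <- sqrt(cfg$sigma2_eps) * matrix(stats::rnorm(n_subj * m), n_subj, m)
  tmat <- matrix(tg, n_subj, m, byrow = TRUE)
  ctrue <- a[["intercept"]] + a[["C"]] * C + eps
  if (cfg$interaction) {
    ctrue <- ctrue + a[["t"]] * tmat + a[["C:t"]] * C * tmat
  }
  if (cfg$has_w) ctrue <- ctrue + a[["W"]] * W

  # cumulative-average history of the true exposures (baseline = c at t1)
  gaps <- diff(tg)
  G <- sweep(ctrue[, -m, drop = FALSE], 2, gaps, "*")
  Tmat <- 1 * upper.tri(matrix(0, m - 1, m - 1), diag = TRUE)
  num <- cbind(0, G %*% Tmat)
  den <- matrix(tg - tg[1], n_subj, m, byrow = TRUE)
  X <- num / ifelse(den > 0, den, 1)
  X[, 1] <- ctrue[, 1]

  mu <- b[["intercept"]] + b[["X"]] * X + b[["t"]] * tmat +
    b[["X:t"]] * X * tmat
  if (cfg$has_w) mu <- mu + b[["W"]] * W
  E <- matrix(stats::rnorm(n_subj * m), n_subj, m) %*%
    ar1_chol(m, cfg$rho_Y, cfg$sigma2_Y)
  Y <- mu + E

  ids <- sprintf("s%06d", seq_len(n_subj))
  long <- function(rows) {
    tibble::tibble(id = rep(ids[rows], each = m),
                   t = rep(tg, length(rows)),
                   C = as.vector(t(C[rows, , drop = FALSE])),
                   c_true = as.vector(t(ctrue[rows, , drop = FALSE])),
                   y = as.vector(t(Y[rows, , drop = FALSE])),
                   W = if (cfg$has_w)
                     as.vector(t(W[rows, , drop = FALSE])) else NULL)
  }
  covs <- if (cfg$has_w) "W" else character()

  ms_rows <- seq_len(cfg$n1)
  ms_long <- long(ms_rows)
  ms_long$c_true <- NULL
  ms <- study_data(ms_long, role = "main", id = "id", t_outcome = "t",
                   t_mem = "t", surrogate = "C", outcome = "y",
                   covariates = covs)

  vs_rows <- if (cfg$design == "evs") cfg$n1 + seq_len(cfg$n2)
             else sort(sample(cfg$n1, cfg$n2))
  vs_long <- long(vs_rows)
  vs_long$y <- NULL
  if (cfg$li == 1) {
    pick <- sample.int(m, length(vs_rows), replace = TRUE)
    keep <- rep(seq_along(vs_rows) - 1L, each = 1L) * m + pick
    vs_long <- vs_long[keep, ]
  }
  vs <- study_data(vs_long, role = "validation", id = "id", t_outcome = "t",
                   t_mem = "t", surrogate = "C", true_exposure = "c_true",
                   covariates = covs)
  list(ms = ms, vs = vs, config = cfg)
}
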
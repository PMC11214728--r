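#' Measurement-error-model parameters
#'
#' A coefficient vector for the calibration-type measurement error model
#' `E[c | C, t, W] = alpha0 + alpha1*C + alpha2*t + alpha3*C*t + alpha4'W`,
#' paired with its ordered term list. Time here is always the MEM time scale
#' (e.g. age), which need not equal the outcome-model time scale.
#'
#' @param alpha Numeric coefficient vector.
#' @param terms Character vector of the same length: a subset of
#'   `"intercept"`, `"C"`, `"t"`, `"C:t"` plus covariate names, in the order
#'   of `alpha`.
#' @return An object of class `mem_params`.
#' @examples
#' mem_params(c(1.2, 0.7), c("intercept", "C"))
#' @export
mem_params <- function(alpha, terms) {
  if (length(alpha) != length(terms)) {
    stop("`alpha` and `terms` must have equal length", call. = FALSE)
  }
  alpha <- stats::setNames(as.numeric(alpha), terms)
  structure(list(alpha = alpha, terms = terms, p_alpha = length(alpha)),
            class = "mem_params")
}

mem_alpha <- function(mem) {
  if (inherits(mem, "memlong_mem")) mem$params$alpha
  else if (inherits(mem, "mem_params")) mem$alpha
  else stop("`mem` must be a mem_params or memlong_mem object", call. = FALSE)
}

mem_terms_of <- function(mem) names(mem_alpha(mem))

mem_covariates <- function(mem) term_covariates(mem_terms_of(mem), "C")

#' Linear predictor of the measurement error model
#'
#' @param mem A [mem_params()] or fitted [fit_mem()] object.
#' @param C Surrogate exposure value(s).
#' @param t_mem Time on the MEM time scale.
#' @param W Covariate matrix (rows matching `C`) with columns named as in the
#'   MEM terms; may be `NULL` when the MEM has no covariate terms.
#' @return Numeric vector of calibrated exposure values f(C, t, W; alpha).
#' @examples
#' mem_predict(mem_params(c(1.2, 0.7, 0.6, 0.5, 0.4),
#'                        c("intercept", "C", "t", "C:t", "W")),
#'             C = 1, t_mem = 1, W = cbind(W = 1)) # 3.4
#' @export
mem_predict <- function(mem, C, t_mem, W = NULL) {
  alpha <- mem_alpha(mem)
  covs <- mem_covariates(mem)
  n <- max(length(C), length(t_mem))
  C <- rep_len(C, n)
  t_mem <- rep_len(t_mem, n)
  if (length(covs) > 0) {
    if (is.null(W)) {
      stop("the MEM has covariate terms (", paste(covs, collapse = ", "),
           ") but no `W` was supplied", call. = FALSE)
    }
    W <- as.matrix(W)
    if (is.null(colnames(W)) && ncol(W) == length(covs)) colnames(W) <- covs
    if (!all(covs %in% colnames(W))) {
      stop("`W` lacks columns ", paste(setdiff(covs, colnames(W)),
                                       collapse = ", "), call. = FALSE)
    }
    if (nrow(W) != n) stop("`W` has ", nrow(W), " rows; expected ", n,
                           call. = FALSE)
  } else {
    W <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  X <- build_terms_matrix(names(alpha), C, t_mem, W, xname = "C")
  unname(drop(X %*% alpha))
}

#' Fit the measurement error model in a validation study
#'
#' Regresses the true exposure on the surrogate, MEM-scale time, their
#' interaction, and covariates, over the validation records. With a single
#' measurement per subject this reduces exactly to ordinary least squares;
#' with repeated measurements a GEE with the requested working correlation is
#' used. Per-subject estimating-function contributions
#' `psi_alpha_i = D_i' V_i^-1 (c_i - f_i)` and the bread block are retained
#' for the stacked sandwich.
#'
#' @param vs Validation [study_data()] (role `"validation"`).
#' @param terms MEM terms, default `c("intercept", "C")`; add `"t"`, `"C:t"`
#'   and covariate names as needed. Fitting a reduced term list is how a
#'   deliberately misspecified MEM is expressed.
#' @param working Working-correlation structure for repeated measurements.
#' @param occasion_grid Optional common MEM-time grid for
#'   `working = "unstructured"`; defaults to the sorted distinct MEM times.
#' @return An object of class `memlong_mem` with elements `params`
#'   ([mem_params()]), `psi` (per-subject score matrix), `bread`
#'   (`d sum(psi_alpha) / d alpha`), `vcov` (robust), `working`, `converged`.
#' @export
fit_mem <- function(vs, terms = c("intercept", "C"),
                    working = c("independence", "ar1", "exchangeable",
                                "unstructured"),
                    occasion_grid = NULL) {
  working <- match.arg(working)
  if (study_role(vs) != "validation") {
    stop("`vs` must have role 'validation'", call. = FALSE)
  }
  use <- vs$.present & !is.na(vs$.c) & !is.na(vs$.C)
  d <- restudy(vs[use, ], vs)
  d <- d[order(d$.id, d$.t_mem), ]
  W <- covariate_matrix(d, term_covariates(terms, "C"))
  X <- build_terms_matrix(terms, d$.C, d$.t_mem, W, xname = "C")
  grid <- occasion_grid %||% sort(unique(d$.t_mem))
  occ <- match(d$.t_mem, grid)
  if (working == "unstructured" && anyNA(occ)) {
    stop("MEM times do not all lie on the declared occasion grid",
         call. = FALSE)
  }
  fit <- gee_solve(X, d$.c, d$.id, structure = working, occasion = occ,
                   grid_size = length(grid))
  if (!fit$converged) {
    stop("MEM GEE did not converge in 50 iterations", call. = FALSE)
  }
  structure(list(params = mem_params(fit$coefficients, terms),
                 psi = fit$psi, bread = fit$bread, vcov = fit$vcov,
                 working = fit$working, n_iter = fit$n_iter,
                 converged = fit$converged,
                 n_subjects = fit$n_subjects, n_obs = fit$n_obs,
                 residuals = fit$residuals),
            class = "memlong_mem")
}

#' @export
print.memlong_mem <- function(x, ...) {
  cat("<memlong_mem> measurement error model fit\n")
  cat("  subjects:", x$n_subjects, " records:", x$n_obs,
      " working:", x$working$structure, "\n")
  print(round(rbind(estimate = x$params$alpha,
                    std.error = sqrt(diag(x$vcov))), 4))
  invisible(x)
}
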
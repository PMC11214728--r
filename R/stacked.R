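#' Uncorrected (naive) outcome fit
#'
#' Fits the outcome GEE using the surrogate exposure-history functional
#' Z = g(surrogate history) in place of the unobserved true-history
#' functional, ignoring measurement error. Its robust variance is the
#' ordinary GEE sandwich.
#'
#' @param ms Main-study [study_data()].
#' @param history A [history_spec()].
#' @param outcome_terms Outcome-model terms, default
#'   `c("intercept", "X", "t", "X:t")` plus any study covariates.
#' @param working Outcome working-correlation structure.
#' @return A `memlong_gee` fit (coefficients named by term).
#' @export
fit_naive <- function(ms, history = history_spec("cumavg"),
                      outcome_terms = NULL,
                      working = c("ar1", "independence", "exchangeable",
                                  "unstructured")) {
  working <- match.arg(working)
  outcome_terms <- outcome_terms %||%
    c("intercept", "X", "t", "X:t", study_covariates(ms))
  z <- exposure_history(ms, history, source = "surrogate")
  d <- build_design(ms, z, outcome_terms)
  keep <- !is.na(d$y)
  fit <- gee_solve(d$X[keep, , drop = FALSE], d$y[keep], d$id[keep],
                   structure = working, occasion = d$occasion[keep],
                   grid_size = length(d$grid))
  fit$history <- history
  fit$terms <- outcome_terms
  fit
}

#' Numeric cross-Jacobian of the outcome estimating function in alpha
#'
#' Differentiates the summed outcome estimating function
#' `sum_i X_i(alpha)' V_i^-1 (y_i - X_i(alpha) beta)` with respect to the MEM
#' coefficients alpha by central differences with step
#' `1e-6 * (1 + |alpha_k|)`, holding beta and the working covariance fixed at
#' their fitted values. This is the lower-left bread block that propagates
#' validation-stage uncertainty into the outcome stage.
#'
#' @param outcome_fit A `memlong_gee` outcome fit.
#' @param ms The main-study data the outcome was fitted on.
#' @param mem The fitted [fit_mem()] object.
#' @param history The [history_spec()] used for calibration.
#' @param outcome_terms Outcome-model terms.
#' @return A `p_beta` x `p_alpha` matrix `d sum(psi_beta) / d alpha`.
#' @export
cross_jacobian <- function(outcome_fit, ms, mem, history, outcome_terms) {
  alpha0 <- mem_alpha(mem)
  terms_a <- names(alpha0)
  beta <- outcome_fit$coefficients
  psi_of_alpha <- function(a) {
    mp <- mem_params(a, terms_a)
    xh <- exposure_history(ms, history, source = "calibrated", mem = mp)
    d <- build_design(ms, xh, outcome_terms)
    keep <- !is.na(d$y)
    sum_psi_at(outcome_fit, d$X[keep, , drop = FALSE], beta)
  }
  J <- numeric_jacobian(psi_of_alpha, alpha0)
  dimnames(J) <- list(names(beta), terms_a)
  J
}

#' Assemble the stacked sandwich variance
#'
#' Stacks per-subject estimating-function contributions from the validation
#' stage (`psi_alpha`) and the outcome stage (`psi_beta`) and computes
#' `Var(theta_hat) = B^-1 A (B^-1)'`, with `A = sum_i psi_i psi_i'` the
#' empirical outer product of the stacked scores and `B` the block
#' lower-triangular Jacobian `[[B_alpha, 0], [B_beta_alpha, B_beta]]`.
#'
#' Under an external design the two stages share no subjects, so each subject
#' contributes either `(psi_alpha_i, 0)` or `(0, psi_beta_i)` and the
#' off-diagonal block of `A` is zero. Under an internal design, subjects in
#' both stages contribute the concatenated `(psi_alpha_i, psi_beta_i)`,
#' which is where the correlation between the two stages enters `A`.
#'
#' @param psi_alpha Per-subject MEM score matrix (rownames = subject ids).
#' @param psi_beta Per-subject outcome score matrix (rownames = subject ids).
#' @param bread_alpha `d sum(psi_alpha) / d alpha` (`p_alpha` square).
#' @param bread_beta `d sum(psi_beta) / d beta` (`p_beta` square).
#' @param cross `d sum(psi_beta) / d alpha` (`p_beta` x `p_alpha`).
#' @param design `"evs"` or `"ivs"`.
#' @return A list with `A`, `B`, and the sandwich `vcov` (symmetrised), all
#'   of dimension `p_alpha + p_beta`.
#' @export
assemble_sandwich <- function(psi_alpha, psi_beta, bread_alpha, bread_beta,
                              cross, design = c("evs", "ivs")) {
  design <- match.arg(design)
  pa <- ncol(psi_alpha)
  pb <- ncol(psi_beta)
  ids_a <- rownames(psi_alpha)
  ids_b <- rownames(psi_beta)
  if ((nrow(psi_alpha) > 0 && is.null(ids_a)) ||
      (nrow(psi_beta) > 0 && is.null(ids_b))) {
    stop("score matrices must carry subject ids as rownames", call. = FALSE)
  }
  ids_a <- ids_a %||% character()
  ids_b <- ids_b %||% character()
  overlap <- intersect(ids_a, ids_b)
  if (design == "evs" && length(overlap) > 0) {
    stop("EVS assembly found ", length(overlap),
         " subjects with scores in both stages", call. = FALSE)
  }
  ids <- union(ids_b, ids_a)
  Psi <- matrix(0, length(ids), pa + pb)
  rownames(Psi) <- ids
  Psi[ids_a, seq_len(pa)] <- psi_alpha
  Psi[ids_b, pa + seq_len(pb)] <- psi_beta
  A <- crossprod(Psi)
  B <- rbind(cbind(bread_alpha, matrix(0, pa, pb)),
             cbind(cross, bread_beta))
  Bi <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(Bi)) {
    warning("singular bread matrix B; point estimates remain valid but the ",
            "sandwich variance is unavailable", call. = FALSE)
    vcov <- matrix(NA_real_, pa + pb, pa + pb)
  } else {
    vcov <- Bi %*% A %*% t(Bi)
    vcov <- (vcov + t(vcov)) / 2
  }
  nm <- c(colnames(psi_alpha), colnames(psi_beta))
  dimnames(A) <- dimnames(B) <- dimnames(vcov) <- list(nm, nm)
  list(A = A, B = B, vcov = vcov)
}

#' Measurement-error-corrected outcome fit with stacked sandwich variance
#'
#' The two-stage corrected estimator: stage 1 fits the measurement error
#' model in the validation study; stage 2 replaces the unobserved
#' exposure-history functional by its calibrated conditional expectation
#' (pointwise calibration of each surrogate record through the fitted MEM,
#' then the history functional) for every main-study subject and solves the
#' outcome GEE. Because the stacked estimating system is block-triangular in
#' (alpha, beta), the two-stage solution solves the full system exactly. The
#' sandwich variance propagates the stage-1 uncertainty; under an internal
#' validation design the validation subjects' outcome rows are included in
#' the outcome stage by default (they contribute both score pieces), and
#' their calibrated history is used rather than the observed true exposure.
#'
#' @param ms Main-study [study_data()].
#' @param vs Validation-study [study_data()].
#' @param design `"evs"` (disjoint subjects) or `"ivs"` (validation subjects
#'   are a subsample of the main study).
#' @param history A [history_spec()].
#' @param mem_terms Terms for the measurement error model.
#' @param outcome_terms Terms for the outcome model; default
#'   `c("intercept", "X", "t", "X:t")` plus the main-study covariates.
#' @param working Outcome working-correlation structure.
#' @param mem_working Validation-stage working correlation (repeated
#'   measurements only; with one record per subject any choice reduces to
#'   least squares).
#' @param include_validation_outcomes Under `"ivs"`, whether validation
#'   subjects' outcome rows enter the outcome stage (default `TRUE`).
#' @param naive Also compute the uncorrected companion fit ([fit_naive()]).
#' @return An object of class `memlong_fit` with `theta = c(alpha, beta)`,
#'   sandwich `vcov`, blocks `A` and `B`, the stage fits, and convergence
#'   information. Use [tidy()][generics::tidy] to extract a coefficient
#'   table.
#' @export
fit_corrected <- function(ms, vs, design = c("evs", "ivs"),
                          history = history_spec("cumavg"),
                          mem_terms = c("intercept", "C"),
                          outcome_terms = NULL,
                          working = c("ar1", "independence", "exchangeable",
                                      "unstructured"),
                          mem_working = "independence",
                          include_validation_outcomes = TRUE,
                          naive = FALSE) {
  design <- match.arg(design)
  working <- match.arg(working)
  check_design(ms, vs, design)
  outcome_terms <- outcome_terms %||%
    c("intercept", "X", "t", "X:t", study_covariates(ms))

  mem <- fit_mem(vs, terms = mem_terms, working = mem_working)

  ms_fit <- ms
  if (design == "ivs" && !include_validation_outcomes) {
    ms_fit <- restudy(ms[!(ms$.id %in% unique(vs$.id)), ], ms)
  }
  xhat <- exposure_history(ms_fit, history, source = "calibrated", mem = mem)
  d <- build_design(ms_fit, xhat, outcome_terms)
  keep <- !is.na(d$y)
  outcome <- gee_solve(d$X[keep, , drop = FALSE], d$y[keep], d$id[keep],
                       structure = working, occasion = d$occasion[keep],
                       grid_size = length(d$grid))
  if (!outcome$converged) {
    stop("outcome GEE did not converge in 50 iterations", call. = FALSE)
  }

  cross <- cross_jacobian(outcome, ms_fit, mem, history, outcome_terms)
  assembly_design <- if (design == "ivs" && include_validation_outcomes)
    "ivs" else "evs"
  names_a <- paste0("alpha:", names(mem$params$alpha))
  names_b <- paste0("beta:", names(outcome$coefficients))
  psi_a <- mem$psi; colnames(psi_a) <- names_a
  psi_b <- outcome$psi; colnames(psi_b) <- names_b
  sw <- assemble_sandwich(psi_a, psi_b, mem$bread, outcome$bread, cross,
                          design = assembly_design)

  theta <- c(stats::setNames(mem$params$alpha, names_a),
             stats::setNames(outcome$coefficients, names_b))
  naive_fit <- if (naive) {
    fit_naive(ms, history, outcome_terms, working = working)
  }
  structure(list(theta = theta,
                 alpha = mem$params$alpha, beta = outcome$coefficients,
                 vcov = sw$vcov, A = sw$A, B = sw$B,
                 design = design, history = history,
                 mem_terms = mem_terms, outcome_terms = outcome_terms,
                 mem_fit = mem, outcome_fit = outcome,
                 naive_companion = naive_fit,
                 n_main = dplyr::n_distinct(ms_fit$.id),
                 n_validation = dplyr::n_distinct(vs$.id),
                 converged = mem$converged && outcome$converged),
            class = "memlong_fit")
}

#' @export
print.memlong_fit <- function(x, ...) {
  cat("<memlong_fit> measurement-error-corrected outcome fit (",
      toupper(x$design), ")\n", sep = "")
  cat("  main subjects:", x$n_main, " validation subjects:", x$n_validation,
      "\n")
  se <- sqrt(diag(x$vcov))
  print(round(rbind(estimate = x$theta, std.error = se), 4))
  invisible(x)
}
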
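# Small in-code fixtures shared across test files.

# Validation study: c = alpha0 + alpha1 * C + eps, li occasions per subject.
make_vs <- function(n, li = 1, alpha = c(1.2, 0.7), sigma = 0.9, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(
    id = rep(sprintf("v%04d", seq_len(n)), each = li),
    t = rep(seq_len(li), n),
    C = stats::rnorm(n * li))
  d$c_true <- alpha[1] + alpha[2] * d$C + stats::rnorm(n * li, sd = sigma)
  study_data(d, role = "validation", id = "id", t_outcome = "t", t_mem = "t",
             surrogate = "C", true_exposure = "c_true")
}

# Longitudinal outcome data with NO measurement error: the surrogate equals
# the true exposure, X is its cumulative average, outcomes have AR(1) errors.
make_ldd_ms <- function(n, m = 5, beta = c(0.5, 3, 3, 3), rho_y = 0.1,
                        seed = 1) {
  set.seed(seed)
  tg <- seq_len(m)
  C <- matrix(stats::rnorm(n * m), n, m)
  gaps <- diff(tg)
  G <- sweep(C[, -m, drop = FALSE], 2, gaps, "*")
  Tm <- 1 * upper.tri(matrix(0, m - 1, m - 1), diag = TRUE)
  X <- cbind(0, G %*% Tm) / matrix(pmax(tg - tg[1], 1), n, m, byrow = TRUE)
  X[, 1] <- C[, 1]
  tmat <- matrix(tg, n, m, byrow = TRUE)
  mu <- beta[1] + beta[2] * X + beta[3] * tmat + beta[4] * X * tmat
  S <- rho_y^abs(outer(seq_len(m), seq_len(m), "-"))
  Y <- mu + matrix(stats::rnorm(n * m), n, m) %*% chol(S)
  d <- tibble::tibble(id = rep(sprintf("m%05d", seq_len(n)), each = m),
                      t = rep(tg, n),
                      C = as.vector(t(C)),
                      y = as.vector(t(Y)))
  study_data(d, role = "main", id = "id", t_outcome = "t", t_mem = "t",
             surrogate = "C", outcome = "y")
}

# Validation data where the true exposure depends on the lag-1 surrogate
# with coefficient `lag_coef` (zero satisfies the localized-error assumption).
make_vs_lagged <- function(n, li = 5, lag_coef = 0, sigma = 0.9, seed = 1) {
  set.seed(seed)
  C <- matrix(stats::rnorm(n * li), n, li)
  Clag <- cbind(0, C[, -li, drop = FALSE])
  ctrue <- 1.2 + 0.7 * C + lag_coef * Clag +
    matrix(stats::rnorm(n * li, sd = sigma), n, li)
  d <- tibble::tibble(id = rep(sprintf("v%04d", seq_len(n)), each = li),
                      t = rep(seq_len(li), n),
                      C = as.vector(t(C)), c_true = as.vector(t(ctrue)))
  study_data(d, role = "validation", id = "id", t_outcome = "t", t_mem = "t",
             surrogate = "C", true_exposure = "c_true")
}

num_jac <- function(f, x, h = NULL) memlong:::numeric_jacobian(f, x, h)

expect_rel_equal <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected)) /
                        max(abs(expected), 1e-12), tol)
}
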
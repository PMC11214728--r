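test_that("the sandwich reproduces the hand-worked scalar mean example", {
  # psi_i = y_i - mu, data (0, 2): mu_hat = 1, A = 2, B = -2, vcov = 0.5
  psi_b <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "mu"))
  psi_a <- matrix(numeric(0), 0, 0)
  sw <- assemble_sandwich(psi_a, psi_b,
                          bread_alpha = matrix(numeric(0), 0, 0),
                          bread_beta = matrix(-2, 1, 1),
                          cross = matrix(numeric(0), 1, 0),
                          design = "evs")
  expect_equal(drop(sw$A), 2)
  expect_equal(drop(sw$B), -2)
  expect_equal(drop(sw$vcov), 0.5)
})

test_that("with no MEM stage the sandwich collapses to the GEE robust
           variance", {
  ms <- make_ldd_ms(n = 60, seed = 61)
  fit <- fit_naive(ms, working = "ar1")
  sw <- assemble_sandwich(matrix(numeric(0), 0, 0), fit$psi,
                          matrix(numeric(0), 0, 0), fit$bread,
                          matrix(numeric(0), ncol(fit$psi), 0),
                          design = "evs")
  expect_equal(sw$vcov, fit$vcov, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("external-design stacking zeroes the cross block of A", {
  d <- generate_scenario(scenario_config("NI-NW", n1 = 80, n2 = 40, li = 5,
                                         seed = 63))
  fit <- fit_corrected(d$ms, d$vs, design = "evs",
                       mem_terms = c("intercept", "C"))
  pa <- length(fit$alpha)
  cross_A <- fit$A[seq_len(pa), pa + seq_along(fit$beta)]
  expect_true(all(cross_A == 0))
  # and scores in both stages would be rejected
  expect_error(assemble_sandwich(fit$mem_fit$psi, fit$mem_fit$psi,
                                 fit$mem_fit$bread, fit$mem_fit$bread,
                                 fit$mem_fit$bread, design = "evs"),
               "both stages")
})

test_that("internal-design stacking concatenates overlapping subjects and
           only the variance changes", {
  d <- generate_scenario(scenario_config("NI-NW", design = "ivs", n1 = 150,
                                         n2 = 60, li = 5, seed = 65))
  ivs <- fit_corrected(d$ms, d$vs, design = "ivs",
                       mem_terms = c("intercept", "C"))
  # relabel validation subjects so the same numbers assemble as an EVS
  vs2 <- d$vs
  vs2$.id <- paste0("x", vs2$.id)
  attr(vs2, "role") <- "validation"; attr(vs2, "covariates") <- character()
  class(vs2) <- class(d$vs)
  evs <- fit_corrected(d$ms, vs2, design = "evs",
                       mem_terms = c("intercept", "C"))
  expect_equal(ivs$theta, evs$theta, tolerance = 1e-12)
  pa <- length(ivs$alpha)
  expect_true(all(evs$A[seq_len(pa), -seq_len(pa)] == 0))
  expect_gt(max(abs(ivs$A[seq_len(pa), -seq_len(pa)])), 0)
  expect_false(isTRUE(all.equal(diag(ivs$vcov), diag(evs$vcov),
                                tolerance = 1e-8)))
})

test_that("with no measurement error the corrected fit equals the naive
           fit", {
  d <- generate_scenario(scenario_config("NI-NW", n1 = 200, n2 = 80, li = 5,
                                         seed = 67))
  vs <- d$vs
  vs$.c <- vs$.C  # surrogate is exact
  f_corr <- suppressWarnings(
    fit_corrected(d$ms, vs, mem_terms = c("intercept", "C")))
  f_naive <- fit_naive(d$ms)
  expect_equal(unname(f_corr$alpha), c(0, 1), tolerance = 1e-8)
  expect_equal(unname(f_corr$beta), unname(f_naive$coefficients),
               tolerance = 1e-8)
})

test_that("the stacked estimating system is solved exactly by the two-stage
           procedure", {
  d <- generate_scenario(scenario_config("NI-NW", n1 = 120, n2 = 60, li = 5,
                                         seed = 69))
  fit <- fit_corrected(d$ms, d$vs, mem_terms = c("intercept", "C"))
  expect_lt(max(abs(colSums(fit$mem_fit$psi))), 1e-6)
  expect_lt(max(abs(colSums(fit$outcome_fit$psi))), 1e-6)
})

test_that("the numeric cross-Jacobian matches the closed form for a linear
           no-interaction MEM", {
  d <- generate_scenario(scenario_config("NI-NW", n1 = 60, n2 = 30, li = 5,
                                         seed = 71))
  fit <- fit_corrected(d$ms, d$vs, mem_terms = c("intercept", "C"))
  of <- fit$outcome_fit
  # X_hat = a0 + a1 Z, so dX_hat/da = (1, Z) row-wise; differentiate
  # sum_i X_i' V_i^-1 (y_i - X_i beta) analytically in alpha.
  z <- exposure_history(d$ms, history_spec("cumavg"), source = "surrogate")
  des <- build_design(d$ms, z, c("intercept", "X", "t", "X:t"))
  beta <- of$coefficients
  xhat <- fit$alpha[["intercept"]] + fit$alpha[["C"]] * z$value
  Xb <- des$X; Xb[, 2] <- xhat; Xb[, 4] <- xhat * d$ms$.t_out
  r <- des$y - drop(Xb %*% beta)
  J_analytic <- matrix(0, 4, 2)
  for (k in 1:2) {
    dxhat_da <- if (k == 1) rep(1, length(xhat)) else z$value
    dX <- matrix(0, nrow(des$X), 4)
    dX[, 2] <- dxhat_da
    dX[, 4] <- dxhat_da * d$ms$.t_out
    # d psi / d alpha_k = sum dX' V^-1 r - sum X' V^-1 (dX beta)
    J_analytic[, k] <- memlong:::sum_wprod(of, dX, r) -
      memlong:::sum_wprod(of, Xb, drop(dX %*% beta))
  }
  J_num <- cross_jacobian(of, d$ms, fit$mem_fit, history_spec("cumavg"),
                          c("intercept", "X", "t", "X:t"))
  expect_rel_equal(J_num, J_analytic, 1e-5)
})

test_that("doubling every subject doubles the cross-Jacobian", {
  d <- generate_scenario(scenario_config("NI-NW", n1 = 40, n2 = 20, li = 5,
                                         seed = 73))
  fit <- fit_corrected(d$ms, d$vs, mem_terms = c("intercept", "C"))
  ms2_raw <- tibble::tibble(id = c(d$ms$.id, paste0("d", d$ms$.id)),
                            t = rep(d$ms$.t_out, 2),
                            C = rep(d$ms$.C, 2), y = rep(d$ms$.y, 2))
  ms2 <- study_data(ms2_raw, role = "main", id = "id", t_outcome = "t",
                    t_mem = "t", surrogate = "C", outcome = "y")
  z2 <- exposure_history(ms2, history_spec("cumavg"), source = "calibrated",
                         mem = fit$mem_fit)
  des2 <- build_design(ms2, z2, c("intercept", "X", "t", "X:t"))
  of2 <- gee_solve(des2$X, des2$y, des2$id, structure = "ar1")
  # impose the original beta and working covariance so only N doubles
  of2$coefficients <- fit$outcome_fit$coefficients
  of2$Vis <- rep(fit$outcome_fit$Vis, length.out = length(of2$Vis))
  of1 <- fit$outcome_fit
  J1 <- cross_jacobian(of1, d$ms, fit$mem_fit, history_spec("cumavg"),
                       c("intercept", "X", "t", "X:t"))
  J2 <- cross_jacobian(of2, ms2, fit$mem_fit, history_spec("cumavg"),
                       c("intercept", "X", "t", "X:t"))
  expect_equal(J2, 2 * J1, tolerance = 1e-4)
})
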
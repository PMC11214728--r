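test_that("scenario configuration encodes the factorial design", {
  cfg <- scenario_config("IP-WC", n1 = 100, n2 = 50, seed = 1)
  expect_equal(cfg$mem_terms, c("intercept", "C", "t", "C:t", "W"))
  expect_equal(unname(cfg$alpha_true), c(1.2, 0.7, 0.6, 0.5, 0.4))
  expect_equal(cfg$corr_cw, 0.4)
  expect_equal(unname(cfg$beta_true), c(0.5, 3, 3, 3, 1))
  cfg2 <- scenario_config("NI-NW", beta1 = 0.2, beta3 = 0.2, seed = 1)
  expect_equal(unname(cfg2$beta_true), c(0.5, 0.2, 3, 0.2))
  expect_error(scenario_config("NI-NW", design = "ivs", n1 = 10, n2 = 20),
               "n2 <= n1")
  expect_error(scenario_config("NI-NW", li = 3), "1 or 5")
})

test_that("noise calibration inverts the correlation formula", {
  cfg <- scenario_config("NI-NW", seed = 1)
  # closed form: (0.7 / 0.60)^2 - 0.49
  expect_equal(cfg$sigma2_eps, (0.7 / 0.6)^2 - 0.49, tolerance = 1e-10)
  # interaction scenarios: the root solves the implied-correlation equation
  for (sc in c("IP-NW", "IP-WP", "IP-WC")) {
    cfgi <- scenario_config(sc, seed = 1)
    expect_equal(memlong:::implied_corr(cfgi, cfgi$sigma2_eps),
                 cfgi$corr_target, tolerance = 1e-8)
    expect_gt(cfgi$sigma2_eps, 0)
  }
  # an unattainable target is refused
  bad <- cfg
  bad$corr_target <- 1
  expect_error(calibrate_noise(bad), "unattainable")
})

test_that("generated datasets have the declared shape and are reproducible", {
  cfg <- scenario_config("NI-NW", n1 = 100, n2 = 20, li = 5, seed = 4)
  d <- generate_scenario(cfg)
  expect_equal(nrow(d$ms), 500)
  expect_equal(nrow(d$vs), 100)
  expect_equal(dplyr::n_distinct(d$ms$.id), 100)
  d2 <- generate_scenario(cfg)
  expect_identical(as.data.frame(d$ms), as.data.frame(d2$ms))
  expect_identical(as.data.frame(d$vs), as.data.frame(d2$vs))
  cfg1 <- scenario_config("NI-NW", n1 = 100, n2 = 20, li = 1, seed = 4)
  d1 <- generate_scenario(cfg1)
  expect_equal(nrow(d1$vs), 20)
  expect_equal(max(table(d1$vs$.id)), 1)
})

test_that("internal validation subjects are a main-study subsample with
           true exposures", {
  cfg <- scenario_config("NI-NW", design = "ivs", n1 = 50, n2 = 20,
                         li = 5, seed = 5)
  d <- generate_scenario(cfg)
  expect_true(all(unique(d$vs$.id) %in% unique(d$ms$.id)))
  expect_true(check_design(d$ms, d$vs, "ivs"))
  expect_false(anyNA(d$vs$.c))
})

test_that("generated exposures satisfy the scenario MEM and correlation
           structure", {
  cfg <- scenario_config("NI-WC", n1 = 20000, n2 = 100, seed = 6)
  d <- generate_scenario(cfg)
  expect_equal(cor(d$ms$.C, d$ms$W), 0.4, tolerance = 0.01)
  # regressing c on the generating terms recovers alpha
  cfg_ip <- scenario_config("IP-WP", design = "ivs", n1 = 20000, n2 = 20000,
                            li = 5, seed = 7)
  di <- generate_scenario(cfg_ip)
  vs <- di$vs
  co <- stats::lm.fit(cbind(1, vs$.C, vs$.t_mem, vs$.C * vs$.t_mem, vs$W),
                      vs$.c)$coefficients
  expect_equal(unname(co), c(1.2, 0.7, 0.6, 0.5, 0.4), tolerance = 0.02)
  expect_equal(cor(vs$.C, vs$W), 0, tolerance = 0.01)
})

test_that("outcome errors have unit variance and the intended serial
           correlation", {
  cfg <- scenario_config("NI-NW", design = "ivs", n1 = 5000, n2 = 5000,
                         li = 5, seed = 8)
  d <- generate_scenario(cfg)
  vs <- d$vs
  X <- exposure_history(vs, history_spec("cumavg"), source = "true")$value
  y <- d$ms$.y[match(paste(vs$.id, vs$.t_out),
                     paste(d$ms$.id, d$ms$.t_out))]
  b <- cfg$beta_true
  resid <- y - (b[["intercept"]] + b[["X"]] * X + b[["t"]] * vs$.t_out +
                  b[["X:t"]] * X * vs$.t_out)
  E <- matrix(resid, ncol = 5, byrow = TRUE)
  expect_equal(stats::var(as.vector(E)), 1, tolerance = 0.05)
  lag1 <- cor(as.vector(E[, -5]), as.vector(E[, -1]))
  expect_equal(lag1, 0.1, tolerance = 0.02)
  # exposure-outcome correlation spans weak to strong across beta settings
  expect_gt(cor(X, y), 0.6)
  cfg_w <- scenario_config("NI-NW", design = "ivs", n1 = 5000, n2 = 5000,
                           li = 5, beta1 = 0.2, beta3 = 0.2, seed = 8)
  dw <- generate_scenario(cfg_w)
  Xw <- exposure_history(dw$vs, history_spec("cumavg"), source = "true")$value
  yw <- dw$ms$.y[match(paste(dw$vs$.id, dw$vs$.t_out),
                       paste(dw$ms$.id, dw$ms$.t_out))]
  expect_lt(cor(Xw, yw), 0.25)
  expect_gt(cor(Xw, yw), 0.05)
})

test_that("coverage bounds reproduce the two-standard-error band", {
  expect_equal(coverage_bounds(1000, 0.95),
               c(lower = 93.6, upper = 96.4))
  expect_equal(coverage_bounds(500, 0.95),
               c(lower = 93.1, upper = 96.9))
  expect_equal(coverage_bounds(1e8, 0.95),
               c(lower = 95.0, upper = 95.0))
})

test_that("substream seeds are deterministic, distinct, and in integer
           range", {
  s <- vapply(1:100, function(r) substream_seed(123, r), 1L)
  expect_equal(anyDuplicated(s), 0)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(substream_seed(123, 7), substream_seed(123, 7))
})

test_that("a single replication reports no empirical standard error", {
  cfg <- scenario_config("NI-NW", n1 = 60, n2 = 30, li = 5, seed = 9)
  s <- run_sim_study(cfg, replications = 1, estimators = "uncorrected")
  expect_true(is.na(s$ese))
  expect_equal(s$replications, 1)
})

test_that("a small study summarises both estimators with the expected
           signs", {
  cfg <- scenario_config("NI-NW", n1 = 300, n2 = 100, li = 5, seed = 10)
  s <- run_sim_study(cfg, replications = 20)
  expect_setequal(s$estimator, c("corrected", "uncorrected"))
  unc <- s[s$estimator == "uncorrected", ]
  cor_ <- s[s$estimator == "corrected", ]
  expect_lt(unc$relative_bias_pct, -20)
  expect_lt(abs(cor_$relative_bias_pct), 10)
  expect_equal(s$excluded, c(0L, 0L))
})
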
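test_that("cumulative average matches hand-evaluated values", {
  # (2*1 + 4*1) / 2
  expect_equal(cumulative_average(c(1, 2, 3), c(2, 4, NA), j = 3)$value, 3.0)
  # unequal spacing: (1*1 + 4*2) / 3
  expect_equal(cumulative_average(c(0, 1, 3), c(1, 4, NA), j = 3)$value, 3.0)
  # a constant history averages to itself at any spacing
  expect_equal(cumulative_average(c(0, 0.5, 2, 7), rep(5, 4), j = 4)$value, 5)
  # the value at t_j never uses the exposure at t_j
  expect_equal(cumulative_average(c(1, 2, 3), c(2, 4, 1e6), j = 3)$value, 3.0)
})

test_that("cumulative average baseline rules behave as specified", {
  expect_equal(cumulative_average(1:3, c(7, 1, 1), j = 1)$value, 7)
  expect_error(cumulative_average(1:3, c(7, 1, 1), j = 1,
                                  baseline = "exclude"), "not defined")
  expect_error(cumulative_average(c(1, 1, 2), 1:3, j = 3),
               "strictly increasing")
})

test_that("windowed functionals use the indicator-weighted closed window", {
  pres <- c(TRUE, FALSE, TRUE)
  expect_equal(moving_average(0:2, c(2, NA, 4), t = 2, window = 3,
                              present = pres)$value, 3.0)
  expect_equal(cumulative_sum(0:2, c(2, NA, 4), t = 2, window = 3,
                              present = pres)$value, 6.0)
  expect_equal(moving_average(0:2, rep(7, 3), t = 2, window = 3)$value, 7)
  # window so short only the record at t qualifies (closed at both ends)
  ma <- moving_average(c(0, 5, 10), c(1, 2, 9), t = 10, window = 1)
  expect_equal(ma$value, 9)
  expect_equal(ma$n_contributing, 1L)
  expect_equal(cumulative_sum(c(0, 5, 10), c(1, 2, 9), t = 10,
                              window = 1)$value, 9)
  expect_error(moving_average(c(0, 1), c(1, 2), t = 10, window = 2),
               "no present exposure record")
})

test_that("moving average times count of present equals cumulative sum", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    tm <- sort(runif(n, 0, 10))
    v <- rnorm(n)
    p <- runif(n) > 0.3
    t0 <- tm[n]
    b <- runif(1, 2, 10)
    if (!any(p & tm >= t0 - b)) next
    ma <- moving_average(tm, v, t = t0, window = b, present = p)
    cs <- cumulative_sum(tm, v, t = t0, window = b, present = p)
    expect_equal(ma$value * ma$n_contributing, cs$value)
  }
})

test_that("functionals ignore absent records entirely", {
  set.seed(7)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    tm <- sort(runif(n, 0, 10))
    v <- rnorm(n)
    # insert an absent record between the first two occasions
    tm2 <- sort(c(tm, mean(tm[1:2])))
    k <- which(tm2 == mean(tm[1:2]))[1]
    v2 <- append(v, 99, after = k - 1)
    p2 <- rep(TRUE, n + 1); p2[k] <- FALSE
    expect_equal(
      cumulative_average(tm2, v2, j = n + 1, present = p2)$value,
      cumulative_average(tm, v, j = n)$value)
    expect_equal(
      moving_average(tm2, v2, t = max(tm), window = 20, present = p2)$value,
      moving_average(tm, v, t = max(tm), window = 20)$value)
    expect_equal(
      cumulative_sum(tm2, v2, t = max(tm), window = 20, present = p2)$value,
      cumulative_sum(tm, v, t = max(tm), window = 20)$value)
  }
})

test_that("equal spacing reduces the cumulative average to a plain mean", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    v <- rnorm(n)
    expect_equal(cumulative_average(seq_len(n), v, j = n)$value,
                 mean(v[-n]))
  }
})

test_that("calibrated history evaluates the MEM pointwise then applies g", {
  mem <- mem_params(c(1.2, 0.7), c("intercept", "C"))
  # ((1.2 + 0.7*2)*1 + (1.2 + 0.7*4)*1) / 2
  got <- calibrated_history(c(1, 2, 3), c(2, 4, NA), j = 3,
                            spec = history_spec("cumavg"), mem = mem)
  expect_equal(got$value, 3.3)
  # linearity: equals alpha0 + alpha1 * (surrogate cumulative average)
  z <- cumulative_average(c(1, 2, 3), c(2, 4, NA), j = 3)$value
  expect_equal(got$value, 1.2 + 0.7 * z)
})

test_that("an identity MEM leaves the history functional unchanged", {
  mem <- mem_params(c(0, 1, 0, 0, 0), c("intercept", "C", "t", "C:t", "W"))
  set.seed(3)
  tm <- sort(runif(5)); v <- rnorm(5); W <- cbind(W = rnorm(5))
  expect_equal(
    calibrated_history(tm, v, j = 5, spec = history_spec("cumavg"),
                       mem = mem, W = W)$value,
    cumulative_average(tm, v, j = 5)$value)
})

test_that("linear no-interaction calibration commutes with the cumulative
           average across a whole study", {
  d <- generate_scenario(scenario_config("NI-NW", n1 = 40, n2 = 10,
                                         seed = 2))
  mem <- mem_params(c(1.2, 0.7), c("intercept", "C"))
  xh <- exposure_history(d$ms, history_spec("cumavg"),
                         source = "calibrated", mem = mem)
  zh <- exposure_history(d$ms, history_spec("cumavg"), source = "surrogate")
  expect_equal(xh$value, 1.2 + 0.7 * zh$value)
})

test_that("vectorised and record-wise cumulative averages agree", {
  d <- generate_scenario(scenario_config("NI-NW", n1 = 25, n2 = 10,
                                         seed = 4))
  fast <- exposure_history(d$ms, history_spec("cumavg"),
                           source = "surrogate")
  slow <- purrr::map_dfr(split(seq_len(nrow(d$ms)),
                               match(d$ms$.id, unique(d$ms$.id))),
    function(rows) {
      purrr::map_dfr(seq_along(rows), function(j)
        cumulative_average(d$ms$.t_out[rows], d$ms$.C[rows], j))
    })
  expect_equal(fast$value, slow$value)
  expect_equal(fast$n_contributing, slow$n_contributing)
})

test_that("baseline exclusion drops first occasions from the design", {
  d <- generate_scenario(scenario_config("NI-NW", n1 = 10, n2 = 5,
                                         seed = 6))
  xh <- exposure_history(d$ms, history_spec("cumavg", baseline = "exclude"),
                         source = "surrogate")
  expect_true(all(is.na(xh$value[xh$.t_out == 1])))
  des <- build_design(d$ms, xh, c("intercept", "X", "t", "X:t"))
  expect_equal(nrow(des$X), 10 * 4)
})
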
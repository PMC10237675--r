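test_that("binary de Bruijn sequence has the documented slots and window property", {
  ps <- make_binary_sequence(10)
  expect_equal(ps$pulse_times, c(0, 20, 30, 50, 80, 90, 100, 110, 160, 180))
  expect_equal(ps$duration, 190L)

  neg <- make_binary_sequence(10, negated = TRUE)
  expect_equal(neg$pulse_times, c(1, 4, 6, 7, 12, 13, 14, 15, 17) * 10)

  # every 4-digit word appears exactly once in the pattern, and, jointly with
  # the negation, exactly twice
  words <- function(bits) vapply(1:16, function(i)
    paste(bits[i:(i + 3)], collapse = ""), character(1))
  bits <- pulse_digits(ps)[1 + (0:18) * 10]
  wb <- words(bits)
  expect_length(unique(wb), 16L)
  wn <- words(1L - bits)
  expect_length(unique(wn), 16L)
  expect_equal(sort(table(c(wb, wn))), sort(table(rep(wb, 2))))

  expect_error(make_binary_sequence(0))
  expect_error(make_binary_sequence(2.5))
})

test_that("binary entropy rate is one bit per clock period", {
  expect_equal(entropy_rate_binary(3) * 60, 20)   # 20 bit/h at the 3-min clock
  expect_equal(entropy_rate_binary(60), 1 / 60)
  expect_equal(entropy_rate_binary(10), 0.1)
  expect_error(entropy_rate_binary(0))
})

test_that("interval entropy rate matches the truncated-pmf oracle", {
  expect_equal(entropy_rate_interval(2, 0), 1)   # fair-coin geometric
  expect_equal(entropy_rate_interval(1, 7), 0)   # deterministic intervals
  expect_equal(entropy_rate_interval(10, 20), 0.1563319, tolerance = 1e-6)
  for (case in list(c(2, 0), c(5, 2), c(10, 20), c(36, 2), c(8, 15)))
    expect_equal(entropy_rate_interval(case[1], case[2]),
                 oracle_interval_rate(case[1], case[2]), tolerance = 1e-12)
  expect_error(entropy_rate_interval(0.5, 0))
})

test_that("interval entropy rate is positive and decreasing in the gap", {
  for (tau in c(2, 5, 10, 36)) {
    rates <- entropy_rate_interval(tau, 0:30)
    expect_true(all(rates > 0))
    expect_true(all(diff(rates) < 0))
  }
})

test_that("tau_geom optimization reproduces the protocol design optima", {
  expect_identical(optimize_tau_geom(20), 10L)
  expect_identical(optimize_tau_geom(15), 8L)
  expect_identical(optimize_tau_geom(0), 2L)
  # agreement with exhaustive search against the independent pmf oracle
  for (g in seq(0, 60, by = 12)) {
    rates <- vapply(1:120, oracle_interval_rate, numeric(1), tau_gap = g)
    expect_identical(as.integer(optimize_tau_geom(g)), which.max(rates))
  }
})

test_that("input entropy scales rate by digit count", {
  expect_equal(input_entropy(protocol_spec("binary", tau_clock = 10), 19), 19)
  p2 <- protocol_spec("interval", tau_geom = 2, tau_gap = 0)
  expect_equal(input_entropy(p2, 100), 100)
  expect_equal(input_entropy(p2, 0), 0)
})

test_that("quantile-matched interval draws hit the target mean and are reproducible", {
  s1 <- draw_interval_sequence(5, 5, 500, seed = 42)
  s2 <- draw_interval_sequence(5, 5, 500, seed = 42)
  expect_identical(s1$pulse_times, s2$pulse_times)
  expect_true(all(diff(s1$pulse_times) >= 6))  # gap + 1 lower bound

  # analytic mean of the quantile multiset by brute-force CDF inversion
  n <- 50L
  q <- (seq_len(n) - 0.5) / n
  cdf <- cumsum(0.2 * 0.8^(0:199))  # geometric(p = 1/5) on 1, 2, ...
  brute <- vapply(q, function(qq) which(cdf >= qq)[1], integer(1)) + 5L
  expect_equal(mean(pulserate:::interval_quantile_set(5, 5, n)), mean(brute))
  expect_lt(abs(mean(brute) - 10), 1)

  expect_error(draw_interval_sequence(10, 20, 25, seed = 1))
})

test_that("empirical interval entropy converges to the closed form", {
  tau <- 5
  s <- draw_interval_sequence(tau, 0, 1e5, seed = 7)
  iv <- diff(s$pulse_times)
  pr <- table(iv) / length(iv)
  emp <- -sum(pr * log2(pr))
  exact <- tau * log2(tau) - (tau - 1) * log2(tau - 1)
  expect_equal(emp, exact, tolerance = 0.02)
})

test_that("pulse sequences roundtrip through JSON and CSV", {
  ps <- draw_interval_sequence(10, 20, 480, seed = 3)
  f <- tempfile(fileext = ".json")
  write_pulse_json(ps, f)
  back <- read_pulse_json(f)
  expect_identical(back$pulse_times, ps$pulse_times)
  expect_identical(back$duration, ps$duration)
  expect_identical(back$protocol$tau_geom, ps$protocol$tau_geom)

  fc <- tempfile(fileext = ".csv")
  write_pulse_csv(ps, fc)
  df <- read.csv(fc)
  expect_equal(df$time_min[df$pulse == 1], ps$pulse_times)
  expect_equal(nrow(df), ps$duration)
})

test_that("pulse sequence invariants are enforced", {
  expect_error(pulse_sequence(100, c(5, 5)))
  expect_error(pulse_sequence(100, c(-1, 5)))
  expect_error(pulse_sequence(100, c(5, 120)))
  spec <- protocol_spec("interval_gap", tau_geom = 10, tau_gap = 20)
  expect_error(pulse_sequence(100, c(10, 20), spec))  # interval < gap + 1
})
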
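test_that("time-after-pulse labels follow the short-interval fallback rule", {
  expect_identical(assign_tap(100L, 105L), 5L)
  expect_identical(assign_tap(c(100L, 103L), 104L), 4L)  # 1 < 3 -> previous pulse
  expect_identical(assign_tap(c(100L, 103L), 106L), 3L)  # boundary: no fallback
  expect_identical(assign_tap(c(100L, 103L), 99L), NA_integer_)
  expect_identical(assign_tap(c(10L, 20L), c(9L, 12L, 21L)),
                   c(NA_integer_, 2L, 11L))  # single preceding pulse keeps short TAP
})

test_that("slicing yields T - l + 1 slices with l-fold interior coverage", {
  x <- matrix(cumsum(rnorm(50)), ncol = 1)
  set <- as_xset(x)
  sl <- make_slices(set, 6, "none")
  expect_equal(nrow(sl$features), 50 - 5)
  expect_equal(ncol(sl$features), 5)
  # an interior point t is covered by slices ending at t .. t+5: exactly 6
  t_int <- 25
  covered <- sl$end_time >= t_int & sl$end_time - 5 <= t_int
  expect_equal(sum(covered), 6)

  ramp <- as_xset(matrix(0.3 * (0:49), ncol = 1))
  slr <- make_slices(ramp, 6, "none")
  expect_true(all(abs(slr$features - 0.3) < 1e-12))  # constant differences

  expect_error(make_slices(as_xset(matrix(1:4, ncol = 1)), 6, "none"))
})

test_that("slice TAP labels match assign_tap over the whole track", {
  ps <- draw_interval_sequence(6, 4, 120, seed = 3)
  x <- as_xset(matrix(rnorm(120), ncol = 1))
  sl <- make_slices(x, 6, "interval", ps)
  expect_identical(sl$label, assign_tap(ps$pulse_times, sl$end_time))
})

test_that("detection de-duplication keeps the first of any 3-minute cluster", {
  expect_identical(dedup_detections(c(10L, 12L)), 10L)
  expect_identical(dedup_detections(c(10L, 13L)), c(10L, 13L))
  expect_identical(dedup_detections(integer(0)), integer(0))
  expect_identical(dedup_detections(c(5L, 6L, 7L, 8L)), c(5L, 8L))
  expect_error(dedup_detections(c(9L, 3L)))
})

test_that("candidate voting requires two of the three possible votes", {
  vote <- pulserate:::vote_detections
  # slices ending at 13, 14, 15 predict TAP 3, 4, 5 -> all vote for minute 10
  expect_identical(vote(c(3L, 4L, 5L), 13:15, 3:5), 10L)
  # a single vote is not enough
  expect_identical(vote(c(3L, 9L, 9L), 13:15, 3:5), integer(0))
  # two votes suffice
  expect_identical(vote(c(3L, 4L, 9L), 13:15, 3:5), 10L)
  # TAPs outside the voting set are ignored as unreliable
  expect_identical(vote(c(7L, 8L, 9L), 13:15, 3:5), integer(0))
})

test_that("binary slot voting confirms a pulse on two or three yes votes", {
  votes <- rbind(c(1, 1, 1), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_equal((rowSums(votes) >= 2) + 0L, c(1, 0, 1, 0))
  # end to end on a small noiseless binary experiment
  ps <- make_binary_sequence(10)
  neg <- make_binary_sequence(10, negated = TRUE)
  sim_a <- simulate_experiment(ps, 12, sim_params_perfect(), seed = 1, history = 122)
  sim_b <- simulate_experiment(neg, 12, sim_params_perfect(), seed = 2, history = 122)
  a <- normalize_trajectories(sim_a, 120)
  b <- normalize_trajectories(sim_b, 120)
  models <- fit_binary_classifiers(a, ps)
  det <- detect_binary(b, models, neg)
  truth <- pulse_digits(neg)[det$slots + 1L]
  expect_true(all(det$detected == truth))
})

test_that("noiseless long-gap reconstruction recovers the pulse train exactly", {
  ps <- draw_interval_sequence(10, 20, 360, seed = 6)
  sim <- simulate_experiment(ps, 30, sim_params_perfect(), seed = 3, history = 122)
  set <- normalize_trajectories(sim, 120)
  train <- pulserate:::subset_tracks(set, 1:15)
  test <- pulserate:::subset_tracks(set, 16:30)
  model <- fit_interval_classifier(train, ps)
  det <- pulserate:::detect_interval_set(test, model)
  for (d in det) expect_identical(d, ps$pulse_times)
})

test_that("decisions use no information later than t0 + t_D", {
  ps <- draw_interval_sequence(10, 20, 300, seed = 9)
  sim <- simulate_experiment(ps, 24, sim_params(), seed = 13, history = 122)
  set <- normalize_trajectories(sim, 120)
  train <- pulserate:::subset_tracks(set, 1:12)
  model <- fit_interval_classifier(train, ps)
  x <- set$x[, 20]
  t0 <- 150L
  full <- detect_interval(x, set$times, model)
  x_masked <- x
  x_masked[set$times > t0 + 5] <- 77  # garbage beyond the decision window
  masked <- detect_interval(x_masked, set$times, model)
  expect_identical(full[full <= t0], masked[masked <= t0])
})

test_that("train/test separation holds and splits induce dispersion", {
  ps <- draw_interval_sequence(10, 20, 240, seed = 4)
  sim <- simulate_experiment(ps, 40, sim_params(), seed = 17, history = 122)
  set <- select_tracks(normalize_trajectories(sim, 120), 0.2)
  est <- estimate_bitrate_reconstruction(set, ps, n_rep = 4, seed = 5)
  for (sp in est$splits) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), set$track_ids)
  }
  expect_equal(est$n_rep, 4)
  expect_true(is.finite(est$sd_bit_per_h))
})

test_that("detection fraction does not decrease with the preceding interval", {
  # alternating short/long intervals in one protocol
  pt <- cumsum(c(30, rep(c(6, 25), 7)))
  ps <- pulse_sequence(max(pt) + 10, pt)
  sim <- simulate_experiment(ps, 120, sim_params(), seed = 23, history = 122)
  set <- select_tracks(normalize_trajectories(sim, 120), 0.2)
  train <- pulserate:::subset_tracks(set, seq_len(48))
  test <- pulserate:::subset_tracks(set, 49:96)
  model <- fit_interval_classifier(train, ps)
  det <- pulserate:::detect_interval_set(test, model)
  frac <- function(iv) {
    pts <- pt[c(FALSE, diff(pt) == iv)]
    mean(vapply(det, function(d) mean(pts %in% d), numeric(1)))
  }
  expect_gte(frac(25), frac(6))
})
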
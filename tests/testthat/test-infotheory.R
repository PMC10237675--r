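test_that("confusion matrices count joint digit outcomes", {
  M <- build_confusion(c(1, 0, 1, 0), c(1, 0, 0, 0))
  expect_equal(M["1", "1"], 0.25)  # TP
  expect_equal(M["0", "0"], 0.50)  # TN
  expect_equal(M["1", "0"], 0.25)  # FN
  expect_equal(M["0", "1"], 0.00)  # FP
  expect_equal(sum(M), 1)

  perfect <- build_confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect["0", "1"] + perfect["1", "0"], 0)
  expect_error(build_confusion(c(1, 0), c(1, 0, 0)))
})

test_that("confusion conditional entropy covers the worked averaged-confidence example", {
  perfect <- build_confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(cond_entropy_confusion(perfect), 0)

  indep <- matrix(0.25, 2, 2)
  expect_equal(cond_entropy_confusion(indep), 1)

  # averaged confidence p_a = 3/4: 20 digits transmit about 3.8 bits
  pa <- matrix(c(3 / 8, 1 / 8, 1 / 8, 3 / 8), 2, 2)
  H <- cond_entropy_confusion(pa)
  expect_equal(H, 0.8112781, tolerance = 1e-6)
  expect_equal(20 * (1 - H), 3.8, tolerance = 0.05)

  # if the receiver knows which half of the digits to trust, the same channel
  # carries 10 bits: 10 perfect digits + 10 pure-noise digits
  H_split <- 10 * cond_entropy_confusion(perfect) + 10 * cond_entropy_confusion(indep)
  expect_equal(20 * 1 - H_split, 10)
})

test_that("contingency tables encode detection timing patterns", {
  S <- integer(30)
  pt <- c(5L, 15L, 25L)
  S[pt + 1L] <- 1L

  on_time <- build_contingency(S, pt)
  expect_equal(on_time["1", "(0,1,0)"] , 3 / 28)  # 28 interior digits
  expect_equal(cond_entropy_contingency(on_time), 0)

  late <- build_contingency(S, pt + 1L)  # consistently 1 min late
  expect_gt(late["1", "(0,0,1)"], 0)
  expect_equal(late["1", "(0,1,0)"], 0)
  expect_equal(cond_entropy_contingency(late), 0)  # consistent shift loses nothing

  none <- build_contingency(S, integer(0))
  expect_equal(sum(none[, "(0,0,0)"]), 1)
  # with no detections the conditional entropy equals the marginal digit entropy
  p1 <- mean(S[2:29])
  expect_equal(cond_entropy_contingency(none),
               -p1 * log2(p1) - (1 - p1) * log2(1 - p1))

  expect_error(build_contingency(S, c(5L, 7L)))  # violates 3-min spacing
})

test_that("bitrate combines entropy rates and can be negative for poor channels", {
  b <- bitrate(entropy_rate_binary(10), 0, digits_per_min = 0.1)
  expect_equal(b$bitrate_bit_per_h, 6)  # perfect 19-bit sequence over 190 min
  expect_equal(bitrate(0.2, 0.2, 1)$bitrate_bit_per_h, 0)

  # no detections at all: conditional entropy exceeds the interval entropy rate
  S <- integer(60)
  S[c(6, 36) + 1L] <- 1L
  h <- entropy_rate_interval(10, 20)
  Hc <- cond_entropy_contingency(build_contingency(S, integer(0)))
  expect_lt(60 * (h - Hc), 0)
})

test_that("error classification distinguishes inaccurate from missed plus false", {
  e <- classify_errors(c(50L), c(51L))
  expect_identical(as.integer(e$deferred), 51L)
  expect_length(e$missed, 0)
  expect_length(e$false, 0)

  e2 <- classify_errors(c(50L), integer(0))
  expect_identical(e2$missed, 50L)

  e3 <- classify_errors(c(50L), c(50L, 70L))
  expect_identical(as.integer(e3$false), 70L)

  e4 <- classify_errors(c(50L, 60L), c(49L, 60L))
  expect_identical(as.integer(e4$advanced), 49L)

  expect_error(classify_errors(c(50L, 52L), integer(0)))
})

test_that("loss decomposition conserves the total bitrate loss", {
  h <- entropy_rate_interval(10, 20)
  for (seed in 1:4) {
    pt <- random_sparse_pulses(12, seed, min_gap = 4, max_gap = 20)
    dur <- max(pt) + 10L
    S <- integer(dur)
    S[pt + 1L] <- 1L
    # perturb: drop one pulse, shift one, add a false detection, per track
    det <- lapply(1:3, function(tr) {
      d <- pt
      d <- d[-((seed + tr) %% length(d) + 1)]
      d[1] <- d[1] + 1L
      dedup_detections(sort(c(d, max(pt) + 5L)))
    })
    dec <- decompose_losses(S, det, h, "interval")
    expect_equal(dec$false + dec$missed + dec$inaccurate,
                 60 * h - dec$bitrate_bit_per_h, tolerance = 1e-9)
  }
})

test_that("single-error decompositions attribute the whole loss to that error", {
  pt <- c(20L, 40L, 60L)
  S <- integer(80)
  S[pt + 1L] <- 1L
  h <- entropy_rate_interval(10, 20)
  only_false <- decompose_losses(S, list(c(pt, 70L)), h, "interval")
  expect_equal(only_false$missed, 0)
  expect_equal(only_false$inaccurate, 0)
  expect_gt(only_false$false, 0)
})

test_that("permutation averaging equals the hand-enumerated two-error case", {
  pt <- c(20L, 40L, 60L)
  S <- integer(80)
  S[pt + 1L] <- 1L
  h <- entropy_rate_interval(10, 20)
  det <- list(c(40L, 60L, 70L))  # one miss (20), one false (70)
  dec <- decompose_losses(S, det, h, "interval")

  rate <- function(d) 60 * (h - cond_entropy_contingency(build_contingency(S, list(d))))
  r0 <- rate(c(40L, 60L, 70L))
  r_false_first <- rate(c(40L, 60L))
  r_missed_first <- rate(c(20L, 40L, 60L, 70L))
  r_full <- rate(pt)
  # orders: false->missed and missed->false (inaccurate steps are no-ops)
  false_contrib <- ((r_false_first - r0) + (r_full - r_missed_first)) / 2
  missed_contrib <- ((r_full - r_false_first) + (r_missed_first - r0)) / 2
  expect_equal(dec$false, false_contrib, tolerance = 1e-12)
  expect_equal(dec$missed, missed_contrib, tolerance = 1e-12)
  expect_equal(dec$inaccurate, 0)
})

test_that("binary-mode decomposition conserves loss with two error classes", {
  S <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  R <- cbind(c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L),
             c(0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L))
  h <- entropy_rate_binary(10)
  dec <- decompose_losses(S, R, h, "binary", digits_per_min = 0.1)
  expect_equal(dec$false + dec$missed,
               60 * h - dec$bitrate_bit_per_h, tolerance = 1e-9)
  expect_equal(dec$inaccurate, 0)
})

test_that("neighborhood entropy implements the Miller-Madow corrected formula", {
  expect_equal(neighborhood_entropy(0, 20), 0)   # pure neighborhood
  expect_equal(neighborhood_entropy(20, 20), 0)
  expect_equal(neighborhood_entropy(10, 20), 1 + 1 / (40 * log(2)),
               tolerance = 1e-9)
  expect_equal(neighborhood_entropy(5, 20),
               -0.25 * log2(0.25) - 0.75 * log2(0.75) + 1 / (40 * log(2)))
})

test_that("pure neighborhoods give zero conditional entropy and full bitrate", {
  # two well-separated clusters with consistent labels
  f <- rbind(matrix(rnorm(40 * 7, mean = 0, sd = 0.01), 40, 7),
             matrix(rnorm(40 * 7, mean = 5, sd = 0.01), 40, 7))
  lab <- rep(c(0L, 1L), each = 40)
  rf <- recfree_cond_entropy(f, lab, k = 10)
  expect_equal(rf$H_cond, 0)
  expect_length(rf$per_slice, 80)
})

test_that("conditional entropies respect their information bounds", {
  set.seed(5)
  for (i in 1:10) {
    M <- matrix(runif(4), 2, 2)
    expect_lte(cond_entropy_confusion(M / sum(M)), 1)
  }
  # contingency bound: conditioning cannot exceed the marginal digit entropy
  pt <- random_sparse_pulses(10, 2, min_gap = 5, max_gap = 15)
  S <- integer(max(pt) + 5L)
  S[pt + 1L] <- 1L
  det <- list(pt[-3], c(pt[1:5] + 1L, pt[7:10]))
  Tb <- build_contingency(S, det)
  p1 <- mean(S[2:(length(S) - 1)])
  marg <- -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
  expect_lte(cond_entropy_contingency(Tb), marg + 1e-12)
})
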
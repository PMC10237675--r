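# End-to-end bitrate estimators with resampling.
#
# Reconstruction-based: split the tracks into disjoint train/test halves,
# train the slice classifier(s) on the train half, reconstruct the pulse
# train of every test track, pool the contingency (interval) or confusion
# (binary) table over the test half, and convert to a bitrate; repeat over
# random splits and report mean +/- sd together with the permutation-averaged
# loss decomposition.
#
# Reconstruction-free: repeat the neighborhood entropy estimate on random
# 50% subsamples of the tracks.

#' Reconstruction-based bitrate estimate
#'
#' @param set selected `translocation_set` (after [select_tracks()]).
#' @param pulses the [pulse_sequence()] the cells received; its protocol
#'   determines the mode and the input entropy rate.
#' @param k neighbour count.
#' @param t_D time to decision, minutes; slice length is `t_D + 1`
#'   (interval mode). Binary mode uses slices of length `slice_len`.
#' @param slice_len slice length for binary mode (default 6).
#' @param n_rep number of random train/test splits.
#' @param seed master seed.
#' @param set_test,pulses_test binary mode only: the ensemble stimulated
#'   with the negated sequence, used as the test set (train and test cells
#'   then come from different fields of view, as in the protocol design).
#' @param per_track also compute per-track bitrates for every test track in
#'   every split (may be negative: the per-digit bound is loose for single
#'   noisy cells).
#' @return Object of class `bitrate_estimate`.
#' @export
estimate_bitrate_reconstruction <- function(set, pulses, k = 20L, t_D = 5L,
                                            slice_len = 6L, n_rep = 10L,
                                            seed = 1L, set_test = NULL,
                                            pulses_test = NULL,
                                            per_track = FALSE) {
  proto <- pulses$protocol
  if (is.null(proto)) stop("pulses must carry their protocol_spec")
  if (proto$kind == "binary")
    return(estimate_binary(set, pulses, set_test, pulses_test,
                           k, slice_len, n_rep, seed, per_track))
  estimate_interval(set, pulses, k, t_D, n_rep, seed, per_track)
}

estimate_interval <- function(set, pulses, k, t_D, n_rep, seed, per_track) {
  h <- entropy_rate(pulses$protocol)
  S <- pulse_digits(pulses)
  digit_times <- seq_len(pulses$duration) - 1L
  n <- ncol(set$x)
  n_train <- floor(n / 2)
  if (n - n_train < 1 || n_train < 1) stop("need at least 2 tracks to split")
  reps <- vector("list", n_rep)
  track_rows <- list()
  for (i in seq_len(n_rep)) {
    ord <- with_seed(derive_seed(seed, 100L + i), sample.int(n))
    tr_idx <- sort(ord[seq_len(n_train)])
    te_idx <- sort(ord[(n_train + 1L):n])
    train <- subset_tracks(set, tr_idx)
    test <- subset_tracks(set, te_idx)
    model <- fit_interval_classifier(train, pulses, k, l = t_D + 1L)
    det <- detect_interval_set(test, model, t_D)
    Tb <- build_contingency(S, det, digit_times)
    H_cond <- cond_entropy_contingency(Tb)
    losses <- decompose_losses(S, det, h, "interval", digit_times)
    reps[[i]] <- data.frame(rep = i,
                            bitrate_bit_per_h = 60 * (h - H_cond),
                            cond_bit_per_h = 60 * H_cond,
                            loss_false = losses$false,
                            loss_missed = losses$missed,
                            loss_inaccurate = losses$inaccurate,
                            n_train = n_train, n_test = n - n_train)
    if (per_track) {
      pt <- vapply(seq_along(det), function(j) {
        Tj <- contingency_counts(
          S, digits_from_times(det[[j]], length(S), digit_times))
        60 * (h - cond_entropy_joint(Tj))
      }, numeric(1))
      track_rows[[i]] <- data.frame(rep = i, track_id = test$track_ids,
                                    bitrate_bit_per_h = pt)
    }
    attr(reps[[i]], "train_ids") <- set$track_ids[tr_idx]
    attr(reps[[i]], "test_ids") <- set$track_ids[te_idx]
  }
  finish_estimate("reconstruction", pulses$protocol$kind, h, reps,
                  if (per_track) do.call(rbind, track_rows) else NULL)
}

estimate_binary <- function(set, pulses, set_test, pulses_test,
                            k, l, n_rep, seed, per_track) {
  if (is.null(set_test) || is.null(pulses_test))
    stop("binary estimation needs the negated-sequence ensemble (set_test, pulses_test)")
  tau <- pulses$protocol$tau_clock
  h <- entropy_rate_binary(tau)
  n_a <- ncol(set$x)
  n_b <- ncol(set_test$x)
  reps <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    tr_idx <- with_seed(derive_seed(seed, 200L + i),
                        sort(sample.int(n_a, max(1L, floor(n_a / 2)))))
    te_idx <- with_seed(derive_seed(seed, 300L + i),
                        sort(sample.int(n_b, max(1L, floor(n_b / 2)))))
    train <- subset_tracks(set, tr_idx)
    test <- subset_tracks(set_test, te_idx)
    models <- fit_binary_classifiers(train, pulses, k, l)
    detection <- detect_binary(test, models, pulses_test, l)
    S_slots <- pulse_digits(pulses_test)[detection$slots + 1L]
    M <- build_confusion(rep(S_slots, ncol(detection$detected)),
                         as.vector(detection$detected))
    H_cond <- cond_entropy_confusion(M)
    losses <- decompose_losses(S_slots, detection$detected, h, "binary",
                               digits_per_min = 1 / tau)
    reps[[i]] <- data.frame(rep = i,
                            bitrate_bit_per_h = 60 * (h - H_cond / tau),
                            cond_bit_per_h = 60 * H_cond / tau,
                            loss_false = losses$false,
                            loss_missed = losses$missed,
                            loss_inaccurate = 0,
                            n_train = length(tr_idx), n_test = length(te_idx))
    attr(reps[[i]], "train_ids") <- set$track_ids[tr_idx]
    attr(reps[[i]], "test_ids") <- set_test$track_ids[te_idx]
  }
  finish_estimate("reconstruction", "binary", h, reps, NULL)
}

#' Reconstruction-free bitrate estimate
#'
#' Neighborhood entropy over length-`slice_len` slices (default 8, matching
#' the 8-minute decision window of the reconstruction-based approach),
#' repeated over random 50% subsamples of the tracks.
#'
#' @param set selected `translocation_set`.
#' @param pulses the [pulse_sequence()] received (interval protocols).
#' @param k neighborhood size.
#' @param slice_len slice length in points.
#' @param label_lag the label marks a pulse `label_lag` minutes before the
#'   slice end (default 5, the time to decision).
#' @param n_rep number of subsamples.
#' @param subsample fraction of tracks per subsample.
#' @param seed master seed.
#' @return Object of class `bitrate_estimate`.
#' @export
estimate_bitrate_recfree <- function(set, pulses, k = 20L, slice_len = 8L,
                                     label_lag = 5L, n_rep = 10L,
                                     subsample = 0.5, seed = 1L) {
  proto <- pulses$protocol
  if (is.null(proto) || proto$kind == "binary")
    stop("the reconstruction-free estimator applies to interval protocols")
  h <- entropy_rate(proto)
  S <- pulse_digits(pulses)
  n <- ncol(set$x)
  n_sub <- max(1L, round(subsample * n))
  reps <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    idx <- with_seed(derive_seed(seed, 400L + i),
                     sort(sample.int(n, n_sub)))
    sub <- subset_tracks(set, idx)
    sl <- make_slices(sub, slice_len, "none")
    lab_time <- sl$end_time - label_lag
    keep <- lab_time >= 0 & lab_time < pulses$duration
    labels <- S[lab_time[keep] + 1L]
    rf <- recfree_cond_entropy(sl$features[keep, , drop = FALSE], labels, k,
                               sl$track_id[keep])
    reps[[i]] <- data.frame(rep = i,
                            bitrate_bit_per_h = 60 * (h - rf$H_cond),
                            cond_bit_per_h = 60 * rf$H_cond,
                            loss_false = NA, loss_missed = NA,
                            loss_inaccurate = NA,
                            n_train = n_sub, n_test = n_sub)
  }
  finish_estimate("reconstruction_free", proto$kind, h, reps, NULL)
}

subset_tracks <- function(set, idx) {
  structure(list(times = set$times,
                 x = set$x[, idx, drop = FALSE],
                 step1 = set$step1[, idx, drop = FALSE],
                 track_ids = set$track_ids[idx]),
            class = "translocation_set")
}

finish_estimate <- function(method, mode, h, reps, per_track) {
  tab <- do.call(rbind, reps)
  est <- list(method = method, mode = mode,
              h_S_bit_per_h = 60 * h,
              bitrate_bit_per_h = mean(tab$bitrate_bit_per_h),
              sd_bit_per_h = if (nrow(tab) > 1) sd(tab$bitrate_bit_per_h) else 0,
              cond_bit_per_h = mean(tab$cond_bit_per_h),
              losses = list(false = mean(tab$loss_false),
                            missed = mean(tab$loss_missed),
                            inaccurate = mean(tab$loss_inaccurate)),
              n_rep = nrow(tab),
              per_rep = tab,
              splits = lapply(reps, function(r)
                list(train = attr(r, "train_ids"), test = attr(r, "test_ids"))),
              per_track = per_track)
  class(est) <- "bitrate_estimate"
  est
}

#' @export
print.bitrate_estimate <- function(x, ...) {
  cat(sprintf("%s bitrate estimate (%s mode)\n", x$method, x$mode))
  cat(sprintf("  input entropy rate: %8.3f bit/h\n", x$h_S_bit_per_h))
  cat(sprintf("  bitrate:            %8.3f bit/h (sd %.3f over %d resamples)\n",
              x$bitrate_bit_per_h, x$sd_bit_per_h, x$n_rep))
  if (!is.na(x$losses$false)) {
    cat("  bitrate loss by source (bit/h):\n")
    cat(sprintf("    false detections:      %8.3f\n", x$losses$false))
    cat(sprintf("    missed pulses:         %8.3f\n", x$losses$missed))
    cat(sprintf("    inaccurate detections: %8.3f\n", x$losses$inaccurate))
  }
  invisible(x)
}

#' Serialize a bitrate estimate as a JSON report
#'
#' @param est a `bitrate_estimate`.
#' @param path output file.
#' @export
write_bitrate_json <- function(est, path) {
  obj <- list(method = est$method,
              h_S_bit_per_h = est$h_S_bit_per_h,
              cond_bit_per_h = est$cond_bit_per_h,
              bitrate_bit_per_h = est$bitrate_bit_per_h,
              losses = list(false = est$losses$false,
                            missed = est$losses$missed,
                            inaccurate = est$losses$inaccurate),
              resamples = list(mean = est$bitrate_bit_per_h,
                               sd = est$sd_bit_per_h,
                               n = est$n_rep))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
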
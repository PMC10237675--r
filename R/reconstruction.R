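# Slice-based reconstruction of the stimulus pulse train from translocation
# trajectories. Trajectories are cut into overlapping slices of l consecutive
# time points represented by their l-1 backward differences. In interval mode
# a kNN classifier predicts each slice's time-after-pulse (TAP) and slices
# predicted with TAP in the voting window accuse a candidate pulse minute;
# candidates confirmed by >= 2 of their 3 possible votes, thinned to one
# detection per 3-minute window, form the reconstruction. In binary mode
# three per-shift classifiers vote directly on each pulse slot. Either way a
# decision about a pulse at t0 uses only x values in [t0 - 2, t0 + t_D]
# (default t_D = 5).

#' Time-after-pulse label of a slice
#'
#' Minutes from the last pulse at or before `slice_end` to `slice_end`,
#' except when that time is shorter than 3 min, in which case the time from
#' the previous pulse is used (disambiguates very short, 3-4 min, intervals).
#'
#' @param pulse_times sorted integer pulse minutes.
#' @param slice_end slice end minute(s); vectorized.
#' @return Integer TAP per slice end; `NA` when no pulse precedes the slice.
#' @export
assign_tap <- function(pulse_times, slice_end) {
  i <- findInterval(slice_end, pulse_times)
  tap <- ifelse(i >= 1, slice_end - pulse_times[pmax(i, 1L)], NA_integer_)
  fall <- !is.na(tap) & tap < 3 & i >= 2
  tap[fall] <- slice_end[fall] - pulse_times[i[fall] - 1L]
  as.integer(tap)
}

# Slice one trajectory (vector x over `times`) into overlapping windows of l
# points; features are the l-1 backward differences.
slice_one <- function(x, times, l) {
  if (length(x) < l) stop("trajectory shorter than slice length")
  dx <- diff(x)
  feats <- stats::embed(dx, l - 1L)
  if (l > 2) feats <- feats[, (l - 1L):1L, drop = FALSE]
  list(features = feats, end_time = times[seq.int(l, length(x))])
}

#' Cut trajectories into labeled slices
#'
#' One slice per end time from the l-th point onward, so every non-terminal
#' interior point is covered by exactly `l` slices.
#'
#' @param set a `translocation_set`.
#' @param l slice length in time points (default 6).
#' @param mode `"interval"` labels each slice with its TAP (see
#'   [assign_tap()]); `"none"` leaves labels `NA`.
#' @param pulses a [pulse_sequence()] (required for interval labels).
#' @return List with `features` (row per slice), `end_time`, `track_id`,
#'   `label`.
#' @export
make_slices <- function(set, l = 6L, mode = c("interval", "none"),
                        pulses = NULL) {
  mode <- match.arg(mode)
  n <- ncol(set$x)
  parts <- lapply(seq_len(n), function(ci)
    slice_one(set$x[, ci], set$times, l))
  features <- do.call(rbind, lapply(parts, `[[`, "features"))
  end_time <- unlist(lapply(parts, `[[`, "end_time"))
  track_id <- rep(set$track_ids, each = nrow(set$x) - l + 1L)
  label <- if (mode == "interval") {
    if (is.null(pulses)) stop("pulses required for interval labels")
    assign_tap(pulses$pulse_times, end_time)
  } else rep(NA_integer_, length(end_time))
  list(features = features, end_time = end_time,
       track_id = track_id, label = label)
}

# Slices anchored at binary pulse slots for one shift. `shift` is the slice
# start relative to the slot: -2, -1 or 0; the slice spans
# slot+shift .. slot+shift+l-1. Slots lacking the full window are skipped.
binary_slot_slices <- function(set, slots, shift, l = 6L, digits = NULL) {
  t0 <- set$times[1]
  t1 <- set$times[length(set$times)]
  ok <- (slots - 2L) >= t0 & (slots + l - 1L) <= t1
  slots <- slots[ok]
  n <- ncol(set$x)
  idx0 <- slots + shift - t0 + 1L  # row of slice start
  rows <- as.vector(outer(0:(l - 1L), idx0, `+`))
  feats_list <- lapply(seq_len(n), function(ci) {
    m <- matrix(set$x[rows, ci], nrow = l)
    t(diff(m))
  })
  list(features = do.call(rbind, feats_list),
       slot = rep(slots, n),
       track_id = rep(set$track_ids, each = length(slots)),
       label = if (is.null(digits)) NULL else
         rep(digits[match(slots, attr(digits, "slots"))], n),
       scored_slots = slots)
}

#' Train the interval-mode TAP classifier
#'
#' All slices of all training tracks, labeled with their TAP; slices with no
#' preceding pulse are excluded from training.
#'
#' @param set training `translocation_set`.
#' @param pulses the [pulse_sequence()] the training cells received.
#' @param k neighbour count.
#' @param l slice length.
#' @return A [knn_model()].
#' @export
fit_interval_classifier <- function(set, pulses, k = 20L, l = 6L) {
  sl <- make_slices(set, l, "interval", pulses)
  keep <- !is.na(sl$label)
  knn_model(sl$features[keep, , drop = FALSE], sl$label[keep],
            sl$track_id[keep], k)
}

#' Train the three per-shift binary slot classifiers
#'
#' @param set training `translocation_set`.
#' @param pulses the binary [pulse_sequence()] the training cells received.
#' @param k neighbour count.
#' @param l slice length.
#' @return List of three [knn_model()]s for slice shifts -2, -1, 0.
#' @export
fit_binary_classifiers <- function(set, pulses, k = 20L, l = 6L) {
  slots <- binary_slots(pulses)
  digits <- pulse_digits(pulses)[slots + 1L]
  attr(digits, "slots") <- slots
  lapply(c(-2L, -1L, 0L), function(sh) {
    sl <- binary_slot_slices(set, slots, sh, l, digits)
    knn_model(sl$features, sl$label, sl$track_id, k)
  })
}

#' De-duplicate detections
#'
#' Scanning left to right, any detection within 2 min after a kept detection
#' is discarded, so no two kept detections fall within any window of three
#' consecutive minutes.
#'
#' @param times sorted detection minutes.
#' @return Thinned detection minutes.
#' @export
dedup_detections <- function(times) {
  if (!length(times)) return(integer(0))
  if (is.unsorted(times)) stop("times must be sorted")
  out <- integer(0)
  last <- -Inf
  for (t in times) {
    if (t - last > 2) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

# Turn predicted TAPs into confirmed detections for one track.
# A slice ending at e predicted with TAP v in vote_set votes for minute
# e - v; candidates need >= votes_needed of their 3 possible votes and a
# fully scoreable window.
vote_detections <- function(pred, end_time, vote_set, votes_needed = 2L) {
  in_set <- pred %in% vote_set
  if (!any(in_set)) return(integer(0))
  cand <- end_time[in_set] - pred[in_set]
  votes <- table(cand)
  cand_t <- as.integer(names(votes))
  full <- cand_t + max(vote_set) <= max(end_time) &
    cand_t + min(vote_set) >= min(end_time)
  det <- sort(cand_t[full & votes >= votes_needed])
  dedup_detections(det)
}

#' Reconstruct pulse times from one trajectory (interval mode)
#'
#' The decision window for a candidate pulse at t0 spans `t0 - 2 .. t0 + t_D`
#' and is covered by three overlapping slices of length `t_D + 1` whose
#' predicted TAPs of `t_D - 2`, `t_D - 1`, `t_D` vote for t0; two votes
#' confirm. The default `t_D = 5` gives slice length 6 and the voting TAP set
#' {3, 4, 5}.
#'
#' @param x translocation vector (or a `translocation_set` for batch use).
#' @param times minute of each point.
#' @param model the TAP [knn_model()] (trained with slice length `t_D + 1`).
#' @param t_D time to decision, minutes.
#' @param vote_set TAP values accepted as votes (default
#'   `(t_D - 2):t_D`).
#' @return Sorted detected pulse minutes.
#' @export
detect_interval <- function(x, times, model, t_D = 5L, vote_set = NULL) {
  vote_set <- vote_set %||% seq.int(t_D - 2L, t_D)
  l <- t_D + 1L
  sl <- slice_one(as.vector(x), times, l)
  pred <- knn_predict(model, sl$features)
  vote_detections(pred, sl$end_time, vote_set)
}

# Batch version over a translocation_set; returns a list of detection-time
# vectors, one per track, using a single kNN query for all slices.
detect_interval_set <- function(set, model, t_D = 5L, vote_set = NULL) {
  vote_set <- vote_set %||% seq.int(t_D - 2L, t_D)
  l <- t_D + 1L
  sl <- make_slices(set, l, "none")
  pred <- knn_predict(model, sl$features)
  lapply(set$track_ids, function(id) {
    sel <- sl$track_id == id
    vote_detections(pred[sel], sl$end_time[sel], vote_set)
  })
}

#' Per-slot pulse detection (binary mode)
#'
#' For each slot t0, the three length-`l` slices starting at t0-2, t0-1 and
#' t0 are classified 0/1 by their shift-specific models; the slot is called
#' a pulse iff at least two predictions are 1.
#'
#' @param set test `translocation_set`.
#' @param models list of three per-shift [knn_model()]s from
#'   [fit_binary_classifiers()].
#' @param pulses the binary [pulse_sequence()] defining the slot grid.
#' @param l slice length.
#' @return List with `slots` (scored slot minutes) and `detected`
#'   (slots-by-tracks 0/1 matrix).
#' @export
detect_binary <- function(set, models, pulses, l = 6L) {
  slots <- binary_slots(pulses)
  shifts <- c(-2L, -1L, 0L)
  preds <- vector("list", 3L)
  scored <- NULL
  for (i in 1:3) {
    sl <- binary_slot_slices(set, slots, shifts[i], l)
    preds[[i]] <- matrix(knn_predict(models[[i]], sl$features),
                         nrow = length(sl$scored_slots))
    scored <- sl$scored_slots
  }
  votes <- preds[[1]] + preds[[2]] + preds[[3]]
  list(slots = scored,
       detected = (votes >= 2L) + 0L,
       track_ids = set$track_ids)
}
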
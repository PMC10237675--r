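# Two-step normalization of nuclear reporter intensity into translocation
# trajectories, and rejection of the low-variability track fraction.
#
# Step 1 divides the nuclear intensity by the whole-image mean at the same
# time point (removes global intensity drift/bleaching). Step 2 divides by
# the trailing 120-min mean of the step-1 signal (removes per-cell reporter
# expression differences). The translocation is x_t = 1 - normalized value,
# so a resting cell sits at x = 0 and x rises after a pulse.

#' Normalize raw trajectories into translocation trajectories
#'
#' The trailing history window is inclusive of the current time point; the
#' first `history` minutes of each track serve as burn-in and are dropped
#' from the output, so for a track starting `history` minutes before
#' stimulation the output starts exactly at stimulation time 0.
#'
#' @param raw a `raw_trajectories` object (or a single-track list with
#'   `times`, `nuclear`, `field`).
#' @param history trailing-mean window length in minutes (default 120).
#' @return A list of class `translocation_set`: `times`, `x` (time-by-cell
#'   matrix of translocation values), `track_ids`. The step-1-only signal
#'   over the retained span is kept in the `step1` element for variability
#'   scoring.
#' @export
normalize_trajectories <- function(raw, history = 120L) {
  nuc <- raw$nuclear
  if (is.null(dim(nuc))) nuc <- matrix(nuc, ncol = 1)
  Tn <- nrow(nuc)
  if (Tn <= history)
    stop(sprintf("need more than %d minutes of track for a %d-min history window",
                 history, history))
  if (any(raw$field <= 0)) stop("field mean intensity must be positive")
  y <- nuc / raw$field                      # step 1: field normalization
  cs <- apply(rbind(0, y), 2, cumsum)       # padded cumulative sums
  keep <- seq.int(history + 1L, Tn)         # drop burn-in
  trail <- (cs[keep + 1L, , drop = FALSE] -
            cs[keep + 1L - history, , drop = FALSE]) / history
  x <- 1 - y[keep, , drop = FALSE] / trail  # step 2 + linear transform
  if (!all(is.finite(x))) stop("non-finite translocation values produced")
  structure(list(times = raw$times[keep],
                 x = x,
                 step1 = y[keep, , drop = FALSE],
                 track_ids = raw$track_ids %||% seq_len(ncol(x))),
            class = "translocation_set")
}

#' Normalize a single raw track
#'
#' @param nuclear nuclear intensity vector.
#' @param field field mean intensity vector (same length).
#' @param history trailing window, minutes.
#' @return Translocation vector (length `length(nuclear) - history`).
#' @export
normalize_trajectory <- function(nuclear, field, history = 120L) {
  set <- normalize_trajectories(list(times = seq_along(nuclear) - 1L,
                                     nuclear = matrix(nuclear, ncol = 1),
                                     field = field,
                                     track_ids = 1L), history)
  as.vector(set$x)
}

#' @export
print.translocation_set <- function(x, ...) {
  cat(sprintf("translocation trajectories: %d tracks x %d min (t = %d..%d)\n",
              ncol(x$x), nrow(x$x), min(x$times), max(x$times)))
  invisible(x)
}

#' Track variability score
#'
#' Sum of squares of the discrete derivative, computed on the signal after
#' only the first normalization step. Weakly responding cells (e.g. with a
#' poorly expressed reporter) score low.
#'
#' @param y step-1-normalized signal vector over the analyzed span.
#' @return The score `sum(diff(y)^2)`.
#' @export
variability_score <- function(y) {
  if (length(y) < 2) stop("trajectory must have at least 2 points")
  sum(diff(y)^2)
}

#' Reject the least variable fraction of tracks
#'
#' Removes the `floor(f * N)` tracks with the lowest [variability_score()]
#' (ties broken by track id); the rest keep their order.
#'
#' @param set a `translocation_set` from [normalize_trajectories()].
#' @param f fraction to reject, in `[0, 1)`.
#' @return The filtered `translocation_set`; rejected ids are recorded in the
#'   `rejected` element.
#' @export
select_tracks <- function(set, f = 0.2) {
  if (f < 0 || f >= 1) stop("f must be in [0, 1)")
  n <- ncol(set$x)
  if (n == 0) stop("empty ensemble")
  n_drop <- floor(f * n)
  if (n_drop == 0) {
    set$rejected <- integer(0)
    return(set)
  }
  scores <- apply(set$step1, 2, variability_score)
  ord <- order(scores, set$track_ids)
  drop_idx <- sort(ord[seq_len(n_drop)])
  set$rejected <- set$track_ids[drop_idx]
  set$x <- set$x[, -drop_idx, drop = FALSE]
  set$step1 <- set$step1[, -drop_idx, drop = FALSE]
  set$track_ids <- set$track_ids[-drop_idx]
  set
}
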
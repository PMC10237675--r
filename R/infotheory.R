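# Bitrate estimation: conditional-entropy bounds from confusion (binary
# encoding) and contingency (interval encoding) tables, permutation-averaged
# decomposition of information loss into false / missed / inaccurate
# detections, and a reconstruction-free neighborhood entropy estimator with
# Miller-Madow bias correction. All entropies in bits; 0*log2(0) == 0.

# H(S|R) of a joint probability (or count) matrix: rows = s, cols = r.
cond_entropy_joint <- function(P) {
  P <- P / sum(P)
  pr <- rep(colSums(P), each = nrow(P))
  pos <- P > 0
  -sum(P[pos] * log2(P[pos] / pr[pos]))
}

#' Confusion matrix of per-digit input vs reconstruction
#'
#' Empirical joint probabilities of the input digit and its reconstruction,
#' pooled over all supplied digits (time points, tracks, resamples).
#'
#' @param S 0/1 input digits (vector, or list of vectors pooled together).
#' @param R 0/1 reconstructed digits, aligned with `S`.
#' @return A 2x2 probability matrix of class `confusion_matrix` with rows
#'   `s = 1, 0` and columns `r = 1, 0` (entries TP, FN / FP, TN).
#' @export
build_confusion <- function(S, R) {
  S <- unlist(S); R <- unlist(R)
  if (length(S) != length(R)) stop("S and R must have equal pooled length")
  M <- matrix(0, 2, 2, dimnames = list(s = c("1", "0"), r = c("1", "0")))
  M["1", "1"] <- sum(S == 1 & R == 1)
  M["1", "0"] <- sum(S == 1 & R == 0)
  M["0", "1"] <- sum(S == 0 & R == 1)
  M["0", "0"] <- sum(S == 0 & R == 0)
  structure(M / length(S), class = "confusion_matrix")
}

#' Conditional entropy H(S_d | R_d) from a confusion matrix
#'
#' @param M a [build_confusion()] matrix (probabilities or counts).
#' @return Bits per digit.
#' @export
cond_entropy_confusion <- function(M) {
  cond_entropy_joint(unclass(M))
}

# Contingency counts of s against the (r-, r0, r+) reconstruction pattern.
# Full 8-pattern alphabet (column code = 4*r_prev + 2*r0 + r_next); the
# first and last digit of each track, where the pattern is truncated, are
# dropped. S and R are 0/1 digit vectors on the same grid.
contingency_counts <- function(S, R) {
  D <- length(S)
  if (length(R) != D) stop("S and R must have equal length")
  if (D < 3) return(matrix(0, 2, 8))
  d <- 2:(D - 1)
  code <- 4L * R[d - 1L] + 2L * R[d] + R[d + 1L]
  idx <- 2L * code + S[d] + 1L  # s=1 -> even slot offset
  cnt <- tabulate(idx, nbins = 16L)
  matrix(cnt, nrow = 2, ncol = 8)[2:1, , drop = FALSE] # row 1: s=1, row 2: s=0
}

pattern_names <- c("(0,0,0)", "(0,0,1)", "(0,1,0)", "(0,1,1)",
                   "(1,0,0)", "(1,0,1)", "(1,1,0)", "(1,1,1)")

#' Contingency table of input digits vs reconstruction patterns
#'
#' Joint distribution of the input digit `S_d` with the three surrounding
#' reconstruction digits `(R_(d-1), R_d, R_(d+1))`, pooled over tracks.
#' Because detections closer than 3 min apart have been eliminated, only the
#' patterns (0,0,0), (1,0,0), (0,1,0), (0,0,1) can occur; the first and last
#' digit of each track are dropped (truncated pattern).
#'
#' @param S 0/1 input digit vector, or a [pulse_sequence()].
#' @param R reconstruction: a 0/1 digit vector aligned with `S`, a vector of
#'   detection minutes, or a list of detection-minute vectors (one per
#'   track, all against the same `S`).
#' @param digit_times minute of each digit (default `0:(length(S)-1)`);
#'   used to place detection times on the digit grid.
#' @return Probability matrix of class `contingency_table`, rows `s = 1, 0`,
#'   one column per reconstruction pattern.
#' @export
build_contingency <- function(S, R, digit_times = NULL) {
  if (inherits(S, "pulse_sequence")) S <- pulse_digits(S)
  digit_times <- digit_times %||% (seq_along(S) - 1L)
  if (!is.list(R)) R <- list(R)
  counts <- matrix(0, 2, 8)
  for (r in R) {
    rd <- as_digit_vector(r, S, digit_times)
    det <- digit_times[rd == 1L]
    if (length(det) > 1 && any(diff(det) < 3))
      stop("detections closer than 3 min apart; de-duplicate first")
    counts <- counts + contingency_counts(S, rd)
  }
  P <- counts / sum(counts)
  dimnames(P) <- list(s = c("1", "0"), pattern = pattern_names)
  if (sum(P[, c(4, 6, 7, 8)]) > 0)
    stop("patterns with two or more detections present despite spacing check")
  structure(P, class = "contingency_table")
}

# 0/1 digit vector from detection minutes; detections off the digit grid
# (e.g. in the pre-stimulation lead-in) are ignored.
digits_from_times <- function(times, n_digits, digit_times) {
  rd <- integer(n_digits)
  m <- match(times, digit_times)
  rd[m[!is.na(m)]] <- 1L
  rd
}

# Interpret R as an aligned digit vector if it has the length of S and is
# 0/1-valued; otherwise as a vector of detection minutes.
as_digit_vector <- function(r, S, digit_times) {
  if (length(r) == length(S) && all(r %in% c(0, 1)))
    return(as.integer(r))
  digits_from_times(r, length(S), digit_times)
}

#' Conditional entropy H(S_d | (R_(d-1), R_d, R_(d+1)))
#'
#' @param Tb a [build_contingency()] table (probabilities or counts).
#' @return Bits per digit.
#' @export
cond_entropy_contingency <- function(Tb) {
  cond_entropy_joint(unclass(Tb))
}

#' Combine entropy rates into a bitrate
#'
#' `i(S, R) = 60 * (h(S) - H(S_d|R) * digits_per_min)` bit/h. The
#' conditional-entropy term is an upper bound on the true conditional
#' entropy rate, so the bitrate is a lower bound on the transmitted
#' information (and can be negative for single noisy cells).
#'
#' @param h_S input entropy rate, bit/min.
#' @param H_cond conditional entropy per digit, bits.
#' @param digits_per_min digit rate (1 for interval protocols on the 1-min
#'   grid, `1/tau_clock` for binary slots).
#' @return List with `h_S_bit_per_h`, `cond_bit_per_h`, `bitrate_bit_per_h`.
#' @export
bitrate <- function(h_S, H_cond, digits_per_min = 1) {
  if (h_S < 0) stop("h_S must be >= 0")
  cond_rate <- H_cond * digits_per_min
  list(h_S_bit_per_h = 60 * h_S,
       cond_bit_per_h = 60 * cond_rate,
       bitrate_bit_per_h = 60 * (h_S - cond_rate))
}

#' Classify reconstruction errors (interval mode)
#'
#' Requires the input to contain no '11' or '101' patterns (inter-pulse
#' intervals of at least 3 min), which makes the classification unambiguous:
#' a detection one minute off an otherwise undetected pulse is a single
#' inaccurate detection (deferred at +1, advanced at -1) rather than a
#' missed pulse plus a false detection.
#'
#' @param pulse_times true pulse minutes.
#' @param det_times de-duplicated detection minutes.
#' @return List of minute vectors: `missed` (pulse times), `false`
#'   (detection times), `deferred` and `advanced` (detection times, with the
#'   matching pulse in attributes `pulse`).
#' @export
classify_errors <- function(pulse_times, det_times) {
  if (length(pulse_times) > 1 && any(diff(pulse_times) < 3))
    stop("input pulses closer than 3 min violate the '11'/'101' precondition")
  exact <- intersect(pulse_times, det_times)
  pu <- setdiff(pulse_times, exact)   # unmatched pulses
  du <- setdiff(det_times, exact)     # unmatched detections
  deferred <- du[du %in% (pu + 1)]
  advanced <- du[du %in% (pu - 1)]
  missed <- pu[!(pu %in% (du - 1)) & !(pu %in% (du + 1))]
  false <- du[!(du %in% (pu + 1)) & !(du %in% (pu - 1))]
  attr(deferred, "pulse") <- deferred - 1L
  attr(advanced, "pulse") <- advanced + 1L
  list(missed = missed, false = false,
       deferred = deferred, advanced = advanced)
}

# Apply the correction for one error type to one track's detection set.
apply_correction <- function(det, errs, type) {
  if (type == "false") det <- setdiff(det, errs$false)
  if (type == "missed") det <- union(det, errs$missed)
  if (type == "inaccurate")
    det <- union(setdiff(det, c(errs$deferred, errs$advanced)),
                 c(attr(errs$deferred, "pulse"), attr(errs$advanced, "pulse")))
  sort(det)
}

#' Decompose the bitrate loss into error sources
#'
#' Sequentially corrects each error type (false detections, missed pulses
#' and, for interval protocols, inaccurate detections), recomputing the
#' contingency/confusion table and the bitrate after each step, and
#' attributes each increment to the corrected type. Because the attribution
#' depends on the correction order, contributions are averaged over all
#' permutations of the order (6 for interval, 2 for binary). Every order
#' restores exactly the input, so the contributions sum to the total loss.
#'
#' @param S the input: a [pulse_sequence()] (or 0/1 digit vector) for
#'   interval mode; 0/1 per-slot digits for binary mode.
#' @param R the reconstruction: list of per-track detection-minute vectors
#'   (interval), or a slots-by-tracks 0/1 matrix (binary).
#' @param h_S input entropy rate, bit/min.
#' @param mode `"interval"` or `"binary"`.
#' @param digit_times minute of each digit (interval mode).
#' @param digits_per_min digit rate (binary mode: `1/tau_clock`).
#' @return List with per-type losses in bit/h (`false`, `missed`,
#'   `inaccurate`), the `total` loss, and the uncorrected
#'   `bitrate_bit_per_h`.
#' @export
decompose_losses <- function(S, R, h_S, mode = c("interval", "binary"),
                             digit_times = NULL, digits_per_min = 1) {
  mode <- match.arg(mode)
  if (mode == "interval") {
    if (inherits(S, "pulse_sequence")) S <- pulse_digits(S)
    digit_times <- digit_times %||% (seq_along(S) - 1L)
    pulse_times <- digit_times[S == 1L]
    if (!is.list(R)) R <- list(R)
    types <- c("false", "missed", "inaccurate")
    errs <- lapply(R, function(d) classify_errors(pulse_times, d))
    rate_of <- function(det_list) {
      counts <- matrix(0, 2, 8)
      for (d in det_list)
        counts <- counts + contingency_counts(
          S, digits_from_times(d, length(S), digit_times))
      60 * (h_S - cond_entropy_joint(counts) * digits_per_min)
    }
    current <- R
  } else {
    if (is.null(dim(R))) R <- matrix(R, ncol = 1)
    if (nrow(R) != length(S)) stop("one reconstruction row per slot required")
    types <- c("false", "missed")
    rate_of <- function(Rm) {
      M <- build_confusion(rep(S, ncol(Rm)), as.vector(Rm))
      60 * (h_S - cond_entropy_confusion(M) * digits_per_min)
    }
    current <- R
  }

  step <- function(state, type) {
    if (mode == "interval") {
      lapply(seq_along(state), function(i)
        apply_correction(state[[i]], errs[[i]], type))
    } else {
      Rm <- state
      if (type == "false") Rm[S == 0 & Rm == 1] <- 0L
      if (type == "missed") Rm[S == 1 & Rm == 0] <- 1L
      Rm
    }
  }

  base_rate <- rate_of(current)
  perms <- perms_of(types)
  contrib <- stats::setNames(numeric(length(types)), types)
  for (perm in perms) {
    state <- current
    prev <- base_rate
    for (type in perm) {
      state <- step(state, type)
      now <- rate_of(state)
      contrib[type] <- contrib[type] + (now - prev)
      prev <- now
    }
  }
  contrib <- contrib / length(perms)
  out <- list(false = contrib[["false"]], missed = contrib[["missed"]],
              inaccurate = if (mode == "interval") contrib[["inaccurate"]] else 0,
              total = sum(contrib), bitrate_bit_per_h = base_rate)
  out
}

perms_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i]))
      out <- c(out, list(c(x[i], rest)))
  out
}

#' Per-slice neighborhood entropy with Miller-Madow correction
#'
#' `-(n0/k) log2(n0/k) - (n1/k) log2(n1/k) + 1/(2k ln 2)` when both counts
#' are non-zero (the plug-in entropy of a k-sample neighborhood plus its
#' Miller-Madow bias correction), 0 otherwise-corrected.
#'
#' @param n1 number of the k neighbours labeled 1; vectorized.
#' @param k neighborhood size.
#' @return Entropy estimate in bits per slice.
#' @export
neighborhood_entropy <- function(n1, k) {
  n0 <- k - n1
  p1 <- n1 / k
  p0 <- n0 / k
  h <- ifelse(p1 > 0, -p1 * log2(p1), 0) + ifelse(p0 > 0, -p0 * log2(p0), 0)
  h + ifelse(n0 > 0 & n1 > 0, 1 / (2 * k * log(2)), 0)
}

#' Reconstruction-free conditional entropy
#'
#' Embeds length-`l` slices (default 8) by their `l - 1` backward
#' differences, finds each slice's `k` nearest neighbours (including the
#' slice itself), counts the 0/1 labels in the neighborhood and averages the
#' bias-corrected neighborhood entropy over all slices. Labels mark whether
#' an input pulse occurred 5 min before the slice's last time point.
#'
#' @param features slice feature matrix (one slice per row).
#' @param labels 0/1 label per slice.
#' @param k neighborhood size (default 20).
#' @param track_ids optional track id per slice (tie-breaking determinism).
#' @return List with `H_cond` (mean bits per digit) and the per-slice
#'   entropies `per_slice`.
#' @export
recfree_cond_entropy <- function(features, labels, k = 20L, track_ids = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < k) stop("fewer slices than k")
  track_ids <- track_ids %||% seq_len(nrow(features))
  nb <- knn_neighbors_cpp(features, as.integer(track_ids), features, as.integer(k))
  n1 <- rowSums(matrix(as.integer(labels)[nb$idx], nrow = nrow(features)) == 1L)
  per_slice <- neighborhood_entropy(n1, k)
  list(H_cond = mean(per_slice), per_slice = per_slice, n1 = n1)
}
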
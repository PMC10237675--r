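# Stimulation protocols: pulse-train generation and exact input entropy rates.
#
# Three protocol families are supported, all on a 1-minute grid:
#   * binary       -- 19 equidistant pulse slots spaced tau_clock apart carrying
#                     a fixed de Bruijn-type 0/1 pattern (1 bit per slot);
#   * interval     -- inter-pulse intervals drawn from a geometric distribution
#                     with mean tau_geom, plus a small technical gap (2 min by
#                     default) that prevents ambiguous reconstruction;
#   * interval_gap -- geometric intervals lengthened by a minimal gap tau_gap.

# The shortest binary string containing every 4-digit word exactly once,
# used so that the stimulus statistics are balanced across slots.
DEBRUIJN_PATTERN <- "1011010011110000101"

#' Stimulation protocol specification
#'
#' @param kind one of `"binary"`, `"interval"`, `"interval_gap"`.
#' @param tau_clock clock period in minutes between pulse slots (binary only).
#' @param tau_geom mean of the geometric part of the inter-pulse interval
#'   distribution, minutes (`= 1/p`). For `interval_gap` the default is the
#'   entropy-rate-maximizing value for the given `tau_gap`
#'   (see [optimize_tau_geom()]).
#' @param tau_gap fixed minimal gap added to every interval, minutes. The
#'   plain `interval` protocol carries a technical gap of 2 min by default.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("binary", "interval", "interval_gap"),
                          tau_clock = NULL, tau_geom = NULL, tau_gap = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (is.null(tau_clock) || length(tau_clock) != 1 || !is.finite(tau_clock) ||
        tau_clock < 1 || tau_clock != round(tau_clock))
      stop("tau_clock must be a positive integer number of minutes")
    spec <- list(kind = kind, tau_clock = as.integer(tau_clock),
                 tau_geom = NULL, tau_gap = NULL)
  } else {
    tau_gap <- tau_gap %||% if (kind == "interval") 2L else
      stop("tau_gap is required for the interval_gap protocol")
    tau_geom <- tau_geom %||% optimize_tau_geom(tau_gap)
    if (tau_geom < 1 || tau_geom != round(tau_geom))
      stop("tau_geom must be an integer >= 1 minute")
    if (tau_gap < 0 || tau_gap != round(tau_gap))
      stop("tau_gap must be a non-negative integer number of minutes")
    spec <- list(kind = kind, tau_clock = NULL,
                 tau_geom = as.integer(tau_geom), tau_gap = as.integer(tau_gap))
  }
  structure(spec, class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  if (x$kind == "binary") {
    cat(sprintf("binary protocol: 19 slots every %d min, pattern %s\n",
                x$tau_clock, DEBRUIJN_PATTERN))
  } else {
    cat(sprintf("%s protocol: geometric intervals, tau_geom = %d min, tau_gap = %d min\n",
                x$kind, x$tau_geom, x$tau_gap))
  }
  cat(sprintf("input entropy rate: %.4f bit/min (%.2f bit/h)\n",
              entropy_rate(x), 60 * entropy_rate(x)))
  invisible(x)
}

#' Realized pulse sequence on the 1-minute grid
#'
#' @param duration total duration in minutes.
#' @param pulse_times strictly increasing integer pulse minutes in
#'   `[0, duration)`.
#' @param protocol the generating [protocol_spec()] (optional).
#' @return An object of class `pulse_sequence`.
#' @export
pulse_sequence <- function(duration, pulse_times, protocol = NULL) {
  pulse_times <- as.integer(pulse_times)
  duration <- as.integer(duration)
  if (any(diff(pulse_times) <= 0)) stop("pulse_times must be strictly increasing")
  if (length(pulse_times) && (min(pulse_times) < 0 || max(pulse_times) >= duration))
    stop("pulse_times must lie in [0, duration)")
  if (!is.null(protocol) && protocol$kind != "binary" &&
      length(pulse_times) > 1 &&
      any(diff(pulse_times) < protocol$tau_gap + 1L))
    stop("inter-pulse interval below tau_gap + 1")
  structure(list(duration = duration, pulse_times = pulse_times,
                 protocol = protocol), class = "pulse_sequence")
}

#' 0/1 digit vector of a pulse sequence
#'
#' @param ps a [pulse_sequence()].
#' @return Integer vector of length `ps$duration`; entry `t+1` is the digit of
#'   minute `t`.
#' @export
pulse_digits <- function(ps) {
  d <- integer(ps$duration)
  d[ps$pulse_times + 1L] <- 1L
  d
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat(sprintf("pulse sequence: %d pulses over %d min", length(x$pulse_times), x$duration))
  if (!is.null(x$protocol)) cat(sprintf(" (%s protocol)", x$protocol$kind))
  cat("\n")
  invisible(x)
}

#' Binary de Bruijn stimulation sequence
#'
#' The 19 pulse slots, spaced `tau_clock` minutes apart, carry the fixed
#' pattern `1011010011110000101` (or its logical negation), the shortest
#' binary string in which every 4-digit subsequence appears exactly once.
#'
#' @param tau_clock clock period in minutes (integer, >= 1).
#' @param negated use the logical negation of the pattern.
#' @return A [pulse_sequence()] of duration `19 * tau_clock`.
#' @export
make_binary_sequence <- function(tau_clock, negated = FALSE) {
  spec <- protocol_spec("binary", tau_clock = tau_clock)
  bits <- as.integer(strsplit(DEBRUIJN_PATTERN, "")[[1]])
  if (negated) bits <- 1L - bits
  slots <- (seq_along(bits) - 1L) * spec$tau_clock
  pulse_sequence(19L * spec$tau_clock, slots[bits == 1L], spec)
}

#' Slot times of a binary protocol sequence
#'
#' @param ps a binary-protocol [pulse_sequence()].
#' @return Integer vector of the 19 slot minutes.
#' @export
binary_slots <- function(ps) {
  stopifnot(!is.null(ps$protocol), ps$protocol$kind == "binary")
  (0:18) * ps$protocol$tau_clock
}

#' Draw a quantile-matched geometric interval sequence
#'
#' The interval multiset is chosen deterministically to best reflect the
#' target distribution: `n = floor(budget / (tau_geom + tau_gap))` intervals
#' are taken at the geometric quantiles `(i - 1/2)/n` (support 1, 2, ...),
#' each lengthened by `tau_gap`, and then randomly shuffled.
#'
#' @param tau_geom mean of the geometric part, minutes.
#' @param tau_gap fixed added gap, minutes.
#' @param budget total time budget in minutes.
#' @param seed integer seed controlling the shuffle.
#' @param protocol optional [protocol_spec()] to attach.
#' @return A [pulse_sequence()] of duration `budget`.
#' @export
draw_interval_sequence <- function(tau_geom, tau_gap, budget, seed,
                                   protocol = NULL) {
  if (tau_geom < 1) stop("tau_geom must be >= 1")
  if (tau_gap < 0) stop("tau_gap must be >= 0")
  n <- floor(budget / (tau_geom + tau_gap))
  if (n < 1) stop("budget too small for a single interval")
  intervals <- interval_quantile_set(tau_geom, tau_gap, n)
  intervals <- with_seed(seed, sample(intervals))
  times <- cumsum(intervals)
  if (is.null(protocol))
    protocol <- protocol_spec(if (tau_gap > 0) "interval_gap" else "interval",
                              tau_geom = tau_geom, tau_gap = tau_gap)
  pulse_sequence(budget, times[times < budget], protocol)
}

# Deterministic quantile-matched interval multiset (before shuffling).
interval_quantile_set <- function(tau_geom, tau_gap, n) {
  if (tau_geom == 1) return(rep(1L + as.integer(tau_gap), n))
  p <- 1 / tau_geom
  q <- (seq_len(n) - 0.5) / n
  # qgeom counts failures before the first success (support 0, 1, ...);
  # intervals live on 1, 2, ...
  as.integer(qgeom(q, p) + 1L + tau_gap)
}

#' Input entropy rate of the binary protocol
#'
#' One equiprobable bit per clock period: `1/tau_clock` bit/min.
#'
#' @param tau_clock clock period, minutes.
#' @return Entropy rate in bits per minute.
#' @export
entropy_rate_binary <- function(tau_clock) {
  if (any(tau_clock <= 0)) stop("tau_clock must be positive")
  1 / tau_clock
}

#' Input entropy rate of the interval protocols
#'
#' Entropy of the geometric interval distribution with mean `tau_geom`,
#' `tau*log2(tau) - (tau-1)*log2(tau-1)` bits per pulse, divided by the mean
#' inter-pulse interval `tau_geom + tau_gap`. Equals the entropy per 1-minute
#' digit of the resulting 0/1 pulse train.
#'
#' @param tau_geom mean of the geometric part, minutes (>= 1).
#' @param tau_gap fixed added gap, minutes (>= 0).
#' @return Entropy rate in bits per minute.
#' @export
entropy_rate_interval <- function(tau_geom, tau_gap = 0) {
  if (any(tau_geom < 1)) stop("tau_geom must be >= 1")
  if (any(tau_gap < 0)) stop("tau_gap must be >= 0")
  xlog2x <- function(v) ifelse(v <= 0, 0, v * log2(v))
  (xlog2x(tau_geom) - xlog2x(tau_geom - 1)) / (tau_geom + tau_gap)
}

#' Entropy rate of any protocol, bits per minute
#'
#' @param protocol a [protocol_spec()].
#' @return Bits per minute (for binary protocols the per-slot bit spread over
#'   the clock period).
#' @export
entropy_rate <- function(protocol) {
  if (protocol$kind == "binary") entropy_rate_binary(protocol$tau_clock)
  else entropy_rate_interval(protocol$tau_geom, protocol$tau_gap)
}

#' Entropy-rate-maximizing geometric mean interval
#'
#' Maximizes [entropy_rate_interval()] over integer `tau_geom` for a given
#' minimal gap; ties broken toward the smaller value. The search grid is the
#' 1-minute input grid, range 1..120 min.
#'
#' @param tau_gap minimal gap, minutes (>= 0).
#' @param range integer search range.
#' @return Optimal integer `tau_geom` in minutes.
#' @export
optimize_tau_geom <- function(tau_gap, range = c(1L, 120L)) {
  if (tau_gap < 0) stop("tau_gap must be >= 0")
  grid <- seq.int(range[1], range[2])
  rates <- entropy_rate_interval(grid, tau_gap)
  grid[which.max(rates)] # which.max takes the first (smallest) on ties
}

#' Total input entropy of a protocol over a digit span
#'
#' Entropy rate per digit times the number of digits: for binary protocols a
#' digit is a pulse slot (1 bit each), for interval protocols a digit is one
#' minute of the 0/1 pulse train.
#'
#' @param protocol a [protocol_spec()].
#' @param n_digits number of digits (slots or minutes).
#' @return Entropy in bits.
#' @export
input_entropy <- function(protocol, n_digits) {
  if (n_digits < 0) stop("n_digits must be >= 0")
  if (protocol$kind == "binary") return(1 * n_digits)
  entropy_rate_interval(protocol$tau_geom, protocol$tau_gap) * n_digits
}

#' Serialize a pulse sequence to JSON
#'
#' @param ps a [pulse_sequence()].
#' @param path output file.
#' @export
write_pulse_json <- function(ps, path) {
  proto <- ps$protocol
  obj <- list(duration_min = ps$duration,
              pulse_times_min = ps$pulse_times,
              protocol = if (is.null(proto)) NULL else
                list(kind = proto$kind, tau_clock = proto$tau_clock,
                     tau_geom = proto$tau_geom, tau_gap = proto$tau_gap))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read a pulse sequence from JSON
#'
#' @param path file written by [write_pulse_json()].
#' @return A [pulse_sequence()].
#' @export
read_pulse_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  proto <- NULL
  if (!is.null(obj$protocol) && length(obj$protocol))
    proto <- protocol_spec(obj$protocol$kind,
                           tau_clock = obj$protocol$tau_clock,
                           tau_geom = obj$protocol$tau_geom,
                           tau_gap = obj$protocol$tau_gap)
  pulse_sequence(obj$duration_min, obj$pulse_times_min %||% integer(0), proto)
}

#' Write a pulse sequence as a two-column CSV (time_min, pulse)
#'
#' @param ps a [pulse_sequence()].
#' @param path output file.
#' @export
write_pulse_csv <- function(ps, path) {
  write.csv(data.frame(time_min = seq_len(ps$duration) - 1L,
                       pulse = pulse_digits(ps)),
            path, row.names = FALSE)
  invisible(path)
}
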
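# Synthetic single-cell reporter trajectories with the statistical structure
# the downstream analysis assumes: a stereotyped unimodal translocation pulse
# (steepest rise between 2 and 3 min, peak at 6 min, steepest rebound near
# 11 min), refractoriness expressed as a reduced probability of responding to
# closely spaced pulses (~70% at a 10-min interval, ~90% at 15 min), a
# non-responder subpopulation, cell-to-cell amplitude/timing variability, and
# additive observation noise. Raw traces are emitted on the fluorescence
# intensity scale together with a drifting field mean so that both
# normalization steps are exercised.

#' Simulation parameters
#'
#' Defaults are calibrated to the measured response phenomenology: the
#' response kernel peaks 6 min after a pulse with its steepest rise between
#' 2 and 3 min and steepest decay near 11 min; the probability that a cell
#' responds to a pulse is logistic in the interval since the previous pulse
#' and passes through 0.70 at 10 min and 0.90 at 15 min; 20% of cells do not
#' respond at all.
#'
#' @param kernel_peak_time minutes from pulse to translocation maximum.
#' @param kernel_rise_steepest minutes from pulse to steepest rise.
#' @param kernel_fall_steepest minutes from pulse to steepest decay.
#' @param kernel_amplitude_mean mean translocation amplitude (dimensionless).
#' @param amplitude_cv coefficient of variation of per-cell amplitude
#'   (log-normal).
#' @param noise_sd additive per-minute Gaussian noise on the translocation
#'   scale.
#' @param noise_ar1 lag-1 autocorrelation of the observation noise (0 = iid).
#' @param refractory_half_interval interval at which response probability is
#'   1/2, minutes.
#' @param refractory_steepness logistic scale of the response-probability
#'   curve, minutes; `0` switches to a hard threshold at
#'   `refractory_half_interval` (used for perfect-channel validation runs).
#' @param nonresponder_fraction fraction of cells that never respond.
#' @param timing_jitter probabilities of a per-cell timing offset of
#'   -1, 0, +1 min.
#' @param baseline_level resting nuclear reporter intensity (arbitrary
#'   fluorescence units).
#' @param baseline_cv per-cell coefficient of variation of the baseline
#'   (reporter expression spread).
#' @param field_level field (whole-image) mean intensity at time zero.
#' @param bleach_fraction fractional slow multiplicative decay of all
#'   intensities over the experiment (exercises field normalization).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(kernel_peak_time = 6,
                       kernel_rise_steepest = 2.5,
                       kernel_fall_steepest = 11,
                       kernel_amplitude_mean = 0.35,
                       amplitude_cv = 0.3,
                       noise_sd = 0.02,
                       noise_ar1 = 0,
                       refractory_half_interval = NULL,
                       refractory_steepness = NULL,
                       nonresponder_fraction = 0.2,
                       timing_jitter = c(0.1, 0.8, 0.1),
                       baseline_level = 1000,
                       baseline_cv = 0.15,
                       field_level = 2000,
                       bleach_fraction = 0.05) {
  if (is.null(refractory_steepness) || is.null(refractory_half_interval)) {
    # calibrate the logistic so that p(10) = 0.70 and p(15) = 0.90
    logit <- function(p) log(p / (1 - p))
    s <- 5 / (logit(0.9) - logit(0.7))
    h <- 10 - logit(0.7) * s
    refractory_steepness <- refractory_steepness %||% s
    refractory_half_interval <- refractory_half_interval %||% h
  }
  p <- list(kernel_peak_time = kernel_peak_time,
            kernel_rise_steepest = kernel_rise_steepest,
            kernel_fall_steepest = kernel_fall_steepest,
            kernel_amplitude_mean = kernel_amplitude_mean,
            amplitude_cv = amplitude_cv,
            noise_sd = noise_sd,
            noise_ar1 = noise_ar1,
            refractory_half_interval = refractory_half_interval,
            refractory_steepness = refractory_steepness,
            nonresponder_fraction = nonresponder_fraction,
            timing_jitter = timing_jitter,
            baseline_level = baseline_level,
            baseline_cv = baseline_cv,
            field_level = field_level,
            bleach_fraction = bleach_fraction)
  if (p$nonresponder_fraction < 0 || p$nonresponder_fraction >= 1)
    stop("nonresponder_fraction must be in [0, 1)")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(p$kernel_rise_steepest < p$kernel_peak_time &&
        p$kernel_peak_time < p$kernel_fall_steepest))
    stop("kernel landmarks must satisfy rise < peak < fall")
  if (length(p$timing_jitter) != 3 || any(p$timing_jitter < 0))
    stop("timing_jitter must be 3 non-negative probabilities for offsets -1, 0, +1")
  p$timing_jitter <- p$timing_jitter / sum(p$timing_jitter)
  structure(p, class = "sim_params")
}

# Noiseless, fully deterministic parameter set: identical responder cells
# that respond to every pulse. Used for perfect-channel validation.
#' Deterministic perfect-channel simulation parameters
#'
#' All cells are identical responders (no amplitude spread, no timing jitter,
#' no observation noise) and respond to every pulse regardless of spacing.
#' Under these conditions the stimulus is perfectly decodable and the
#' estimated bitrate must recover the input entropy rate.
#'
#' @param ... overrides passed on to [sim_params()].
#' @export
sim_params_perfect <- function(...) {
  sim_params(amplitude_cv = 0, noise_sd = 0, nonresponder_fraction = 0,
             timing_jitter = c(0, 1, 0), baseline_cv = 0,
             refractory_half_interval = 0, refractory_steepness = 0, ...)
}

#' Sample per-cell phenotypes
#'
#' @param n_cells number of cells.
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return Data frame with columns `track_id`, `responder`, `amplitude`,
#'   `timing_offset`, `noise_sd`.
#' @export
sample_phenotypes <- function(n_cells, params, seed) {
  stopifnot(n_cells >= 1)
  with_seed(seed, {
    responder <- runif(n_cells) >= params$nonresponder_fraction
    cv <- params$amplitude_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      amplitude <- stats::rlnorm(n_cells,
                                 meanlog = log(params$kernel_amplitude_mean) - sdlog^2 / 2,
                                 sdlog = sdlog)
    } else amplitude <- rep(params$kernel_amplitude_mean, n_cells)
    offset <- sample(c(-1L, 0L, 1L), n_cells, replace = TRUE,
                     prob = params$timing_jitter)
    data.frame(track_id = seq_len(n_cells),
               responder = responder,
               amplitude = amplitude,
               timing_offset = offset,
               noise_sd = rep(params$noise_sd, n_cells))
  })
}

#' Stereotyped single-pulse response kernel
#'
#' Smooth unimodal curve pinned to the three response landmarks: zero at the
#' pulse, steepest discrete rise into `kernel_rise_steepest + 0.5` (between
#' minutes 2 and 3 at defaults), maximum at `kernel_peak_time`, steepest
#' discrete decay near `kernel_fall_steepest`. Built from two logistic arcs
#' (rise and decay) normalized to peak 1 and to vanish at the end of the
#' support, `kernel_fall_steepest + 4` minutes.
#'
#' @param params a [sim_params()].
#' @param offset per-cell timing offset in minutes (-1, 0, +1).
#' @param amplitude peak translocation amplitude.
#' @return Numeric vector of kernel values at minutes `0, 1, ...` after the
#'   pulse (relative minute = index - 1).
#' @export
response_kernel <- function(params, offset = 0, amplitude = 1) {
  tp <- params$kernel_peak_time
  tr <- params$kernel_rise_steepest
  tf <- params$kernel_fall_steepest
  tend <- tf + 4
  sr <- 0.9  # logistic scales: sharp rise, slower rebound
  sf <- 1.8
  tt <- 0:tend
  g <- function(t) 1 / (1 + exp(-(t - tr) / sr))
  h <- function(t) 1 / (1 + exp((t - tf) / sf))
  k <- numeric(length(tt))
  rise <- tt <= tp
  k[rise] <- (g(tt[rise]) - g(0)) / (g(tp) - g(0))
  k[!rise] <- (h(tt[!rise]) - h(tend)) / (h(tp) - h(tend))
  k <- amplitude * k
  if (offset > 0) k <- c(numeric(offset), k)
  if (offset < 0) k <- k[-seq_len(-offset)]
  k
}

#' Probability of responding to a pulse given the preceding interval
#'
#' Monotone saturating (logistic) refractoriness curve; at default
#' calibration it passes through 0.70 at a 10-min interval and 0.90 at
#' 15 min. `refractory_steepness = 0` gives a hard threshold at
#' `refractory_half_interval` (so `half = 0` means every pulse elicits a
#' response).
#'
#' @param interval minutes since the previous pulse (`Inf` for the first).
#' @param params a [sim_params()].
#' @return Response probability in `[0, 1]`.
#' @export
response_probability <- function(interval, params) {
  s <- params$refractory_steepness
  h <- params$refractory_half_interval
  if (s == 0) return(ifelse(interval >= h, 1, 0))
  ifelse(is.infinite(interval), 1, 1 / (1 + exp(-(interval - h) / s)))
}

#' Simulate a stimulation experiment
#'
#' Each responder cell responds to each pulse independently with the
#' refractoriness probability of the preceding interval; realized responses
#' superpose amplitude-scaled copies of the response kernel on the
#' translocation scale. The raw nuclear intensity is
#' `baseline * (1 - translocation - noise)`, multiplied by a slowly decaying
#' field intensity so that the first normalization step has work to do.
#' Trajectories include `history` minutes of pre-stimulation baseline.
#'
#' @param pulses a [pulse_sequence()].
#' @param n_cells number of cells.
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @param history minutes of pre-stimulation history (>= 120 for the default
#'   normalization window).
#' @param tail minutes of imaging continued after the stimulation span, so
#'   that the decision window of a pulse near the end of the protocol is
#'   still fully observed (default 8, the width of the decision window).
#' @return A list of class `raw_trajectories` with elements `times` (minutes,
#'   stimulation starts at 0), `nuclear` (time-by-cell intensity matrix),
#'   `field` (whole-image mean intensity per time point), `track_ids`,
#'   `phenotypes`, and `truth` (a list with the pulse sequence and the
#'   per-cell per-pulse `responded` table).
#' @export
simulate_experiment <- function(pulses, n_cells, params = sim_params(),
                                seed = 1L, history = 120L, tail = 8L) {
  stopifnot(inherits(pulses, "pulse_sequence"), n_cells >= 1)
  if (history < 1) stop("history must be at least 1 min")
  duration <- pulses$duration
  times <- seq.int(-history, duration + tail - 1L)
  Tn <- length(times)
  phen <- sample_phenotypes(n_cells, params, derive_seed(seed, 1L))

  pt <- pulses$pulse_times
  np <- length(pt)
  intervals <- if (np) c(Inf, diff(pt)) else numeric(0)
  presp <- response_probability(intervals, params)

  with_seed(derive_seed(seed, 2L), {
    responded <- matrix(FALSE, nrow = np, ncol = n_cells)
    if (np) {
      responded[] <- runif(np * n_cells) < rep(presp, n_cells)
      responded <- responded & rep(phen$responder, each = np)
    }

    z <- matrix(0, nrow = Tn, ncol = n_cells)
    for (ci in seq_len(n_cells)) {
      if (!phen$responder[ci] || np == 0) next
      kern <- response_kernel(params, offset = phen$timing_offset[ci],
                              amplitude = phen$amplitude[ci])
      base0 <- if (phen$timing_offset[ci] < 0) phen$timing_offset[ci] else 0L
      for (pj in which(responded[, ci])) {
        i0 <- pt[pj] + base0 + history + 1L  # row of first kernel sample
        idx <- i0:(i0 + length(kern) - 1L)
        keep <- idx >= 1L & idx <= Tn
        z[idx[keep], ci] <- z[idx[keep], ci] + kern[keep]
      }
    }

    eps <- matrix(rnorm(Tn * n_cells, sd = params$noise_sd), Tn, n_cells)
    if (params$noise_ar1 != 0 && params$noise_sd > 0) {
      rho <- params$noise_ar1
      eps <- apply(eps, 2, function(e)
        as.numeric(stats::filter(e * sqrt(1 - rho^2), rho, method = "recursive")))
    }

    baseline <- params$baseline_level *
      exp(rnorm(n_cells, sd = sqrt(log(1 + params$baseline_cv^2))))
    drift <- exp(-params$bleach_fraction * (seq_len(Tn) - 1) / (Tn - 1))
    nuclear <- sweep(pmax(1 - z - eps, 0.05), 2, baseline, `*`) * drift
    field <- params$field_level * drift
  })

  truth <- list(pulses = pulses,
                responses = if (np) data.frame(
                  track_id = rep(seq_len(n_cells), each = np),
                  pulse_time = rep(pt, n_cells),
                  preceding_interval = rep(intervals, n_cells),
                  responded = as.vector(responded)) else
                  data.frame(track_id = integer(0), pulse_time = integer(0),
                             preceding_interval = numeric(0), responded = logical(0)))

  structure(list(times = times, nuclear = nuclear, field = field,
                 track_ids = seq_len(n_cells), phenotypes = phen,
                 params = params, truth = truth),
            class = "raw_trajectories")
}

#' @export
print.raw_trajectories <- function(x, ...) {
  cat(sprintf("raw trajectories: %d cells x %d min (stimulation span %d min)\n",
              ncol(x$nuclear), length(x$times), sum(x$times >= 0)))
  invisible(x)
}

#' Write raw trajectories as long-format CSV
#'
#' Columns: `track_id`, `time_min`, `nuclear_ktr_mean`, `field_mean`.
#'
#' @param raw a `raw_trajectories` object.
#' @param path output file.
#' @export
write_trajectories_csv <- function(raw, path) {
  n <- ncol(raw$nuclear)
  Tn <- length(raw$times)
  df <- data.frame(track_id = rep(raw$track_ids, each = Tn),
                   time_min = rep(raw$times, n),
                   nuclear_ktr_mean = as.vector(raw$nuclear),
                   field_mean = rep(raw$field, n))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read raw trajectories from long-format CSV
#'
#' @param path file written by [write_trajectories_csv()].
#' @return A `raw_trajectories` object (without phenotype/truth annotation).
#' @export
read_trajectories_csv <- function(path) {
  df <- read.csv(path)
  ids <- unique(df$track_id)
  times <- sort(unique(df$time_min))
  df <- df[order(match(df$track_id, ids), df$time_min), ]
  Tn <- length(times)
  structure(list(times = times,
                 nuclear = matrix(df$nuclear_ktr_mean, nrow = Tn),
                 field = df$field_mean[seq_len(Tn)],
                 track_ids = ids, phenotypes = NULL, params = NULL,
                 truth = NULL),
            class = "raw_trajectories")
}
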
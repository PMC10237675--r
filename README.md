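# pulserate

Information transmission rate of a pulsatile cell-signaling channel,
estimated from single-cell kinase-translocation-reporter trajectories.

## What it does

Cells relaying stimuli through MAPK/ERK respond to a brief optogenetic
light pulse with a stereotyped, minutes-long pulse of ERK activity, read
out as a dip in nuclear ERK-KTR fluorescence. If the stimulus is a *random
pulse train*, the pathway becomes a communication channel: the bitrate

i(S, R) = h(S) − H(S | R)/Δt     [bit/h]

between the pulse train `S` and its reconstruction `R` from the reporter
trajectories is a lower bound on the channel capacity. `pulserate`
implements the full estimation pipeline:

* **Protocols** — binary de Bruijn slot sequences (1 bit per `τ_clock`),
  and geometric-interval encodings with an optional minimal gap, with exact
  input entropy rates `h(τ_geom, τ_gap) = [τ log₂τ − (τ−1) log₂(τ−1)]/(τ + τ_gap)`
  and the entropy-rate-maximizing `τ_geom` for a given gap.
* **Preprocessing** — two-step normalization (field mean, then trailing
  120-min history) into translocation `x_t`, and rejection of the
  low-variability track fraction (non-responders).
* **Reconstruction** — sliding slices of 6 points represented by backward
  differences, a kNN (k = 20) classifier predicting each slice's
  time-after-pulse, hard voting (2 of 3) on candidate pulse minutes, and
  de-duplication; decisions use only data up to 5 min after a pulse.
* **Information theory** — per-digit conditional-entropy bounds from
  confusion (binary) or three-digit-pattern contingency (interval) tables,
  a permutation-averaged decomposition of the bitrate loss into false,
  missed and inaccurate detections, and a reconstruction-free kNN
  neighborhood entropy estimator with Miller–Madow bias correction.
* **Synthetic data** — a generator emulating the measured response
  phenomenology (rise/peak/rebound landmarks at 2–3/6/11 min,
  refractoriness reaching 70% response at 10-min and 90% at 15-min
  intervals, 20% non-responders, cell-to-cell variability, observation
  noise), so the whole pipeline is testable end to end without microscopy
  data.

## Worked example

Simulate the strongest protocol — geometric intervals of mean 10 min on top
of a 20-min minimal gap (9.38 bit/h input entropy rate) — for 6 h over 200
cells, then estimate the bitrate both ways:

```r
library(pulserate)

cfg <- run_config(protocol = list(kind = "interval_gap", tau_geom = 10L,
                                  tau_gap = 20L, duration = 360L),
                  n_cells = 200L, mode = "both", n_rep = 5L, seed = 1L)
run <- run_pipeline(cfg)
print(run)
```

```
pipeline run
pulse sequence: 12 pulses over 360 min (interval_gap protocol)
  simulated tracks: 200; analyzed tracks: 160

reconstruction bitrate estimate (interval_gap mode)
  input entropy rate:    9.380 bit/h
  bitrate:               4.173 bit/h (sd 0.436 over 5 resamples)
  bitrate loss by source (bit/h):
    false detections:         0.336
    missed pulses:            2.364
    inaccurate detections:    2.507

reconstruction_free bitrate estimate (interval_gap mode)
  input entropy rate:    9.380 bit/h
  bitrate:               5.317 bit/h (sd 0.430 over 5 resamples)
```

Reading the numbers: of the 9.38 bit/h offered by the protocol, the
reconstruction-based decoder transmits 4.17 bit/h from these (deliberately
noisy) synthetic cells; the stacked losses say what the errors cost —
missed pulses and ±1-min timing errors dominate, false detections are
cheap. The reconstruction-free estimate is higher because it never averages
per-pulse uncertainty into a single table; the direction of that gap
mirrors the real-data analysis. On a noiseless synthetic channel both
estimates recover the input entropy rate exactly (see the vignette).

`sweep_parameter(cfg, "t_D", 1:8)` reproduces the time-to-decision
behavior (collapse below 3 min, plateau past 5 min);
`sweep_parameter(cfg, "f", seq(0, 0.3, 0.05))` the rejection-fraction
plateau.

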
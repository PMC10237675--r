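# Independent oracles and small builders shared across test files.

# Brute-force kNN prediction: full distance computation in R, ordering by
# (distance, track id, train row), majority vote with the documented
# tie-breaks. Kept deliberately naive and separate from the package path.
oracle_knn_predict <- function(train, track, labels, query, k) {
  apply(query, 1, function(q) {
    d2 <- colSums((t(train) - q)^2)
    ord <- order(d2, track, seq_along(d2))[seq_len(k)]
    labs <- labels[ord]
    dd <- sqrt(d2[ord])
    tab <- sort(table(labs), decreasing = TRUE)
    top <- as.integer(names(tab[tab == tab[1]]))
    if (length(top) == 1) return(top)
    means <- vapply(top, function(L) mean(dd[labs == L]), numeric(1))
    best <- top[means == min(means)]
    min(best)
  })
}

# Entropy rate of the geometric-interval protocol from the explicit pmf,
# truncated at machine precision: independent check of the closed form.
oracle_interval_rate <- function(tau_geom, tau_gap) {
  if (tau_geom == 1) return(0)
  p <- 1 / tau_geom
  i <- 1:ceiling(log(1e-18) / log(1 - p))
  pr <- p * (1 - p)^(i - 1)
  pr <- pr[pr > 0]
  -sum(pr * log2(pr)) / (tau_geom + tau_gap)
}

# Wrap a plain matrix of translocation values as a translocation_set.
as_xset <- function(x, times = seq_len(nrow(x)) - 1L) {
  structure(list(times = times, x = x, step1 = x,
                 track_ids = seq_len(ncol(x))),
            class = "translocation_set")
}

# Random interval-protocol style digit sequence with all gaps >= 3 min.
random_sparse_pulses <- function(n_pulses, seed, min_gap = 3L, max_gap = 12L) {
  withr_seed <- function(s, e) pulserate:::with_seed(s, e)
  gaps <- withr_seed(seed, sample(min_gap:max_gap, n_pulses, replace = TRUE))
  cumsum(gaps)
}
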
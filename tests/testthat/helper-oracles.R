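# Independent brute-force oracles used to cross-check the implementation.

# O(n^2)-style burst grouping: walk spikes one by one, compare each against
# the last spike of the open burst. Deliberately naive and loop-based.
oracle_bursts <- function(times, thr) {
  if (!length(times))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      n_spikes = integer(0), duration = numeric(0)))
  groups <- list()
  cur <- times[1]
  for (t in times[-1]) {
    if (t - cur[length(cur)] <= thr) cur <- c(cur, t)
    else { groups[[length(groups) + 1]] <- cur; cur <- t }
  }
  groups[[length(groups) + 1]] <- cur
  data.frame(onset = vapply(groups, min, 0),
             offset = vapply(groups, max, 0),
             n_spikes = vapply(groups, length, 0L),
             duration = vapply(groups, function(g) max(g) - min(g), 0))
}

# Literal per-value band assignment with explicit closed bounds.
oracle_classify <- function(freq) {
  vapply(freq, function(f) {
    if (f >= 0 && f <= 2) "interburst"
    else if (f >= 3 && f <= 9) "intermediate"
    else if (f >= 10 && f <= 55) "intraburst"
    else "other"
  }, character(1))
}

random_spike_train <- function(n) {
  # mix of tight clusters and long gaps so both regimes occur
  isis <- sample(c(runif(n, 0.01, 0.1), runif(n, 0.3, 2)))[seq_len(n)]
  cumsum(isis)
}

healthy_rhythm <- function(n_cycles, seed, jitter = 0.02)
  generate_rhythm(rhythm_spec(n_cycles = n_cycles,
                              period_jitter_sd = jitter, seed = seed))
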
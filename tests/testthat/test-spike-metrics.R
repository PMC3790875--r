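test_that("burst detection partitions spikes at the ISI threshold", {
  b <- detect_bursts(c(0, .05, .10, 1.0, 1.05), 0.25)
  expect_equal(b$onset, c(0, 1.0))
  expect_equal(b$offset, c(0.10, 1.05))
  expect_equal(b$n_spikes, c(3L, 2L))

  single <- detect_bursts(2.0)
  expect_equal(single$n_spikes, 1L)
  expect_equal(single$duration, 0)

  expect_equal(nrow(detect_bursts(numeric(0))), 0L)
})

test_that("burst detection matches the brute-force oracle on random trains", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(1:60, 1)
    thr <- runif(1, 0.05, 0.5)
    times <- random_spike_train(n)
    expect_equal(detect_bursts(times, thr), oracle_bursts(times, thr))
  }
})

test_that("per-burst spike counts always partition the train", {
  set.seed(202)
  for (i in 1:50) {
    times <- random_spike_train(sample(2:200, 1))
    thr <- runif(1, 0.05, 0.5)
    b <- detect_bursts(times, thr)
    expect_equal(sum(b$n_spikes), length(times))
    # multi-spike bursts have intraburst frequency >= 1/threshold
    f <- intraburst_frequencies(b)
    expect_true(all(f[!is.na(f)] >= 1 / thr - 1e-9))
  }
})

test_that("cycle periods are consecutive onset differences", {
  expect_equal(cycle_periods(c(0, 1.0, 2.1)), c(1.0, 1.1))
  expect_equal(cycle_periods(5.0), numeric(0))
  r <- healthy_rhythm(100, seed = 1, jitter = 0)
  per <- cycle_periods(r$cycle_onsets)
  expect_equal(per, rep(1.2, 99), tolerance = 1e-12)
})

test_that("intraburst frequency is (spikes - 1) / duration, NA for singletons", {
  b <- data.frame(n_spikes = c(5L, 2L, 1L), duration = c(0.4, 0.05, 0))
  expect_equal(intraburst_frequencies(b), c(10, 20, NA))
  r <- healthy_rhythm(10, seed = 2, jitter = 0)
  lp <- detect_bursts(r$spikes$LP)
  expect_equal(intraburst_frequencies(lp), rep(20, 10), tolerance = 1e-9)
})

test_that("instantaneous frequencies are reciprocal interspike intervals", {
  expect_equal(instantaneous_frequencies(c(0, 0.1, 0.3)), c(10, 5))
  expect_equal(instantaneous_frequencies(1.5), numeric(0))
  expect_error(instantaneous_frequencies(c(1, 1, 2)), "strictly increasing")
  r <- generate_rhythm(rhythm_spec(n_cycles = 5),
                       pathology_spec(tonic_switch = TRUE, tonic_rate = 5,
                                      onset_time = 0))
  expect_equal(instantaneous_frequencies(r$spikes$LP),
               rep(5, length(r$spikes$LP) - 1), tolerance = 1e-9)
})

test_that("phases use the half-open cycle convention", {
  expect_equal(as.numeric(phases(0.4, c(0, 1))), 0.4)
  expect_equal(as.numeric(phases(0, c(0, 1))), 0)     # onset maps to 0
  expect_warning(ph <- phases(c(0.5, 1.0), c(0, 1)), "dropped")
  expect_equal(attr(ph, "n_dropped"), 1L)
  expect_equal(as.numeric(ph), 0.5)
})

test_that("phases and pattern statistics are recovered from jitter-free rhythms", {
  r <- healthy_rhythm(50, seed = 3, jitter = 0)
  lp_on <- r$bursts$onset[r$bursts$neuron == "LP"]
  ph <- suppressWarnings(phases(lp_on, r$cycle_onsets))
  expect_equal(mean(ph), 0.4, tolerance = 1e-9)
  expect_true(all(ph >= 0 & ph < 1))

  cm <- cycle_metrics(r$spikes)
  lp <- cm[cm$neuron == "LP", ]
  expect_equal(unique(round(lp$cycle_period, 9)), 1.2)
  expect_equal(unique(round(lp$onset_phase, 9)), 0.4)
  expect_equal(unique(lp$n_spikes), 8L)
  expect_equal(unique(round(lp$intraburst_frequency, 9)), 20)
  pd <- cm[cm$neuron == "PD", ]
  expect_equal(unique(round(pd$onset_phase, 9)), 0)   # PD is the reference
})
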
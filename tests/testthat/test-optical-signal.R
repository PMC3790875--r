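make_trace <- function(values, dt = 0.0015) fluor_trace(values, dt)

test_that("DC removal maps constants and interior ramps to zero", {
  tr <- make_trace(rep(5, 4000))
  expect_equal(dc_remove(tr, 0.1)$values, rep(0, 4000))

  ramp <- make_trace(seq(0, 1, length.out = 4000))
  out <- dc_remove(ramp, 0.1)
  h <- round(0.1 / ramp$sample_interval)
  interior <- (h + 1):(4000 - h)
  expect_equal(out$values[interior], rep(0, length(interior)),
               tolerance = 1e-12)
})

test_that("DC removal of a sine has the 1 - sinc(w*w) closed-form gain", {
  dt <- 0.0015
  w <- 0.3                      # half-window, s
  omega <- pi / w               # so that omega * w = pi
  tt <- (0:79999) * dt
  A <- 2
  tr <- make_trace(A * sin(omega * tt), dt)
  out <- dc_remove(tr, w)
  h <- round(w / dt)
  interior <- (h + 1):(length(tt) - h)
  got <- (max(out$values[interior]) - min(out$values[interior])) / 2
  expected <- A * (1 - sin(omega * w) / (omega * w))
  expect_lt(abs(got - expected) / expected, 0.01)
})

test_that("the noise high-pass removes a 1 Hz sine almost entirely", {
  dt <- 0.0015
  tt <- (0:39999) * dt
  tr <- make_trace(sin(2 * pi * tt), dt)
  out <- highpass_noise_filter(tr, 0.01)
  h <- round(0.01 / dt)
  interior <- (h + 1):(length(tt) - h)
  expect_lt(max(abs(out$values[interior])), 0.01)
})

test_that("the noise high-pass passes white noise at the predicted SD", {
  dt <- 0.0015
  sigma <- 1.5
  set.seed(31)
  tr <- make_trace(rnorm(1e5, 0, sigma), dt)
  out <- highpass_noise_filter(tr, 0.01)
  n_w <- 2 * round(0.01 / dt) + 1
  expect_lt(abs(sd(out$values) - sigma * sqrt(1 - 1 / n_w)) / sigma, 0.10)
})

test_that("DC removal is linear and shift-invariant on interior samples", {
  set.seed(7)
  x <- rnorm(3000); y <- rnorm(3000)
  h <- round(0.05 / 0.0015)
  interior <- (h + 1):(3000 - h)
  dc <- function(v) dc_remove(make_trace(v), 0.05)$values
  expect_equal(dc(2 * x + 3 * y)[interior],
               (2 * dc(x) + 3 * dc(y))[interior], tolerance = 1e-10)
  expect_equal(dc(x + 10)[interior], dc(x)[interior], tolerance = 1e-10)
})

test_that("triggered averaging of identical noiseless cycles returns one cycle", {
  dt <- 0.0015
  P <- 1.2
  seg <- round(P / dt)
  one <- sin(2 * pi * (0:(seg - 1)) / seg)
  tr <- make_trace(rep(one, 12), dt)
  trig <- (0:10) * P
  ta <- suppressWarnings(triggered_average(tr, trig))
  expect_equal(ta$waveform, one, tolerance = 1e-12)
  expect_equal(ta$cycle_period, P)

  # a single trigger with a complete segment reproduces that segment
  ta1 <- suppressWarnings(triggered_average(tr, 0, period = P))
  expect_equal(ta1$n_cycles, 1L)
  expect_equal(ta1$waveform, one, tolerance = 1e-12)
})

test_that("averaging n cycles shrinks white noise by about sqrt(n)", {
  dt <- 0.0015
  P <- 0.6
  set.seed(55)
  sds <- replicate(50, {
    tr <- make_trace(rnorm(round(17 * P / dt)), dt)
    ta <- triggered_average(tr, (0:15) * P)
    sd(ta$waveform)
  })
  expect_lt(abs(median(sds) - 1 / 4) / (1 / 4), 0.25)
})

test_that("noise SD estimates scale linearly and fall with cycle count", {
  dt <- 0.0015
  P <- 0.6
  set.seed(99)
  base <- rnorm(round(70 * P / dt))
  tr1 <- make_trace(base, dt)
  tr2 <- make_trace(2 * base, dt)
  trig <- (0:63) * P
  s1 <- suppressWarnings(noise_sd(tr1, trig))
  s2 <- suppressWarnings(noise_sd(tr2, trig))
  expect_lt(abs(s2 / s1 - 2) / 2, 0.05)

  # monotone decrease in expectation across n = 4, 16, 64
  med <- sapply(c(4, 16, 64), function(n) {
    median(replicate(20, {
      tr <- make_trace(rnorm(round((n + 2) * P / dt)), dt)
      suppressWarnings(noise_sd(tr, (0:(n - 1)) * P))
    }))
  })
  expect_true(all(diff(med) < 0))
})

test_that("signal amplitude is the peak-to-trough difference", {
  expect_equal(signal_amplitude(3 * sin(seq(0, 2 * pi, length.out = 1000))),
               6, tolerance = 1e-4)
  expect_equal(signal_amplitude(rep(4, 100)), 0)
})

test_that("a noiseless synthetic trace recovers its slow-wave amplitude", {
  r <- healthy_rhythm(20, seed = 5, jitter = 0)
  tr <- render_fluorescence(r, optics_spec(noise_sd = 0,
                                           spike_transient_amplitude = 0),
                            "LP")
  lp_on <- r$bursts$onset[r$bursts$neuron == "LP"]
  trig <- lp_on[lp_on > 3 & lp_on + 1.2 < r$t_end - 3]  # interior triggers
  ta <- triggered_average(dc_remove(tr, 3), trig)
  expect_lt(abs(signal_amplitude(ta) - 10) / 10, 1e-3)
  # the noise SD shrinks to the residual curvature leakage of the
  # moving-mean high-pass (order w^2), well below 1% of the amplitude
  expect_lt(noise_sd(tr, trig), 0.01 * 10)
})

test_that("zero noise is flagged as infinite S/N, not divided through", {
  flat <- fluor_trace(rep(1, 12000), 0.0015)
  res <- suppressWarnings(compute_snr(flat, c(0, 6), dc_window = 3))
  expect_true(res$infinite_snr)
  expect_identical(res$snr, Inf)
  expect_equal(res$noise_sd, 0)
})

test_that("S/N is invariant to shifts and scale of the trace", {
  r <- healthy_rhythm(16, seed = 7, jitter = 0)
  tr <- render_fluorescence(r, optics_spec(noise_sd = 0.75,
                                           spike_transient_amplitude = 0,
                                           seed = 12), "LP")
  trig <- r$bursts$onset[r$bursts$neuron == "LP"]
  res <- compute_snr(tr, trig)

  shifted <- tr; shifted$values <- tr$values + 100
  res_s <- compute_snr(shifted, trig)
  expect_equal(res_s$snr, res$snr, tolerance = 1e-9)

  scaled <- tr; scaled$values <- tr$values * 3
  res_c <- compute_snr(scaled, trig)
  expect_equal(res_c$amplitude, 3 * res$amplitude, tolerance = 1e-9)
  expect_equal(res_c$noise_sd, 3 * res$noise_sd, tolerance = 1e-9)
  expect_equal(res_c$snr, res$snr, tolerance = 1e-9)
})

test_that("S/N recovery tracks A / (sigma / sqrt(n)) across noise levels", {
  rel_err <- sapply(c(0.15, 0.5, 1.5), function(sigma) {
    errs <- sapply(1:20, function(s) {
      r <- healthy_rhythm(16, seed = 300 + s, jitter = 0)
      tr <- render_fluorescence(r,
        optics_spec(noise_sd = sigma, spike_transient_amplitude = 0,
                    seed = 400 + s), "LP")
      trig <- r$bursts$onset[r$bursts$neuron == "LP"]
      res <- compute_snr(tr, trig)
      truth <- 10 / (sigma / sqrt(res$n_cycles))
      abs(res$snr - truth) / truth
    })
    median(errs)
  })
  expect_true(all(rel_err < 0.25))
})
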
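test_that("band classification uses closed bounds and an explicit other class", {
  expect_equal(classify_band(c(1, 5, 20)),
               c("interburst", "intermediate", "intraburst"))
  expect_equal(classify_band(2.5), "other")
  expect_equal(classify_band(2.0), "interburst")   # closed upper bound
  expect_equal(classify_band(c(9, 10, 55, 55.5)),
               c("intermediate", "intraburst", "intraburst", "other"))
  expect_error(classify_band(-1), "non-negative")
})

test_that("band classification matches the brute-force classifier", {
  set.seed(77)
  freqs <- c(runif(5000, 0, 60), sample(c(0, 2, 3, 9, 10, 55), 100, TRUE))
  expect_equal(classify_band(freqs), oracle_classify(freqs))
})

test_that("healthy rhythms occupy the interburst and intraburst bands", {
  r <- healthy_rhythm(200, seed = 14)
  occ <- band_occupancy(r$spikes$LP, schedule = c(0, 60, 120), window = 60)
  expect_false(any(occ$flagged))
  m <- occ$interburst + occ$intraburst
  expect_true(all(m > 0.99))
  expect_true(all(occ$intermediate < 0.01))
  # occupancy over all classes sums to one
  expect_equal(unname(rowSums(occ[, c("interburst", "intermediate",
                                      "intraburst", "other")])), rep(1, 3))
})

test_that("a tonic 5 Hz train is pure intermediate band", {
  spikes <- seq(0, 120, by = 0.2)
  occ <- band_occupancy(spikes, schedule = 0, window = 60)
  expect_equal(occ$intermediate, 1)
})

test_that("windows without measurable frequencies are flagged, not zeroed", {
  occ <- band_occupancy(c(0.1, 61), schedule = c(0, 120), window = 60)
  expect_true(all(occ$flagged))
  expect_true(all(is.na(occ$interburst)))
})

test_that("total-variation deviation behaves as a metric with ordinal classes", {
  r <- healthy_rhythm(120, seed = 15)
  occ <- band_occupancy(r$spikes$LP, schedule = c(0, 30, 60), window = 30)
  ctrl <- band_occupancy(r$spikes$LP, schedule = 0, window = 30)
  dev <- deviation_from_control(occ, ctrl)
  expect_equal(dev$deviation[1], 0)              # control vs itself
  expect_equal(as.character(dev$class[1]), "none")

  # disjoint occupancies are at distance 1 (class strong)
  prof <- occ[1, ]
  prof$interburst <- 0; prof$intermediate <- 1
  prof$intraburst <- 0; prof$other <- 0
  attr(prof, "scheme") <- attr(occ, "scheme")
  class(prof) <- class(occ)
  ctrl_vec <- c(interburst = 0, intermediate = 0, intraburst = 1, other = 0)
  d2 <- deviation_from_control(prof, ctrl_vec)
  expect_equal(d2$deviation, 1)
  expect_equal(as.character(d2$class), "strong")

  # metric properties on random occupancy vectors
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  set.seed(33)
  for (i in 1:100) {
    p <- runif(4); p <- p / sum(p)
    q <- runif(4); q <- q / sum(q)
    r3 <- runif(4); r3 <- r3 / sum(r3)
    expect_equal(tv(p, q), tv(q, p))
    expect_equal(tv(p, p), 0)
    expect_lte(tv(p, q), tv(p, r3) + tv(r3, q) + 1e-12)
    expect_lte(tv(p, q), 1 + 1e-12)
  }
})

test_that("flagged time points are classed extreme, never a number", {
  occ <- band_occupancy(c(0.1, 0.2, 0.3, 61), schedule = c(0, 120),
                        window = 60)
  ctrl_vec <- c(interburst = 0.2, intermediate = 0, intraburst = 0.8,
                other = 0)
  dev <- deviation_from_control(occ, ctrl_vec)
  expect_equal(as.character(dev$class[2]), "extreme")
  expect_true(is.na(dev$deviation[2]))
})

test_that("missing spikes inflate the intermediate band after onset", {
  schedule <- c(0, 300, 600)
  mk <- function(seed, patho = NULL)
    generate_rhythm(rhythm_spec(n_cycles = 600, period_jitter_sd = 0.02,
                                seed = seed), patho)
  for (s in 1:5) {
    healthy <- mk(s)
    degraded <- mk(s, pathology_spec(missing_spike_prob = 0.3,
                                     onset_time = 120, seed = s + 50))
    occ_h <- band_occupancy(healthy$spikes$LP, schedule = schedule)
    occ_d <- band_occupancy(degraded$spikes$LP, schedule = schedule)
    post <- schedule >= 120
    expect_true(all(occ_d$intermediate[post] > occ_h$intermediate[post]))
  }
})

test_that("a tonic switch drives the deviation above 0.5 after its onset", {
  schedule <- c(0, 600, 1200, 1800)
  for (s in 1:10) {
    r <- generate_rhythm(rhythm_spec(n_cycles = 1600,
                                     period_jitter_sd = 0.02, seed = s),
                         pathology_spec(tonic_switch = TRUE, tonic_rate = 5,
                                        onset_time = 900, seed = s))
    occ <- band_occupancy(r$spikes$LP, schedule = schedule)
    ctrl <- band_occupancy(r$spikes$LP, schedule = 0)
    dev <- deviation_from_control(occ, ctrl)
    expect_true(all(dev$deviation[schedule < 900] < 0.3))
    expect_true(all(dev$deviation[schedule >= 900] > 0.5))
  }
})
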
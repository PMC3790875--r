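uniform_frame <- function(value, n = 16) matrix(as.integer(value), n, n)
full_mask <- function(n = 16) matrix(TRUE, n, n)

test_that("mean grey value is the arithmetic ROI mean", {
  expect_equal(as.numeric(mean_grey(uniform_frame(100), full_mask())), 100)
  f <- uniform_frame(0)
  f[1:8, ] <- 200L
  expect_equal(as.numeric(mean_grey(f, full_mask())), 100)
  expect_error(mean_grey(f, matrix(FALSE, 16, 16)), "empty ROI")
  # synthetic ring cell: ROI mean matches the generator's ring brightness
  st <- render_stack(stack_spec(bleach_time_constant = Inf))
  expect_equal(as.numeric(mean_grey(st$frames[[1]],
                                    st$meta$masks[[2]]$ring)),
               st$meta$ring_brightness[1])
})

test_that("saturated pixels are included but counted", {
  f <- uniform_frame(255)
  f[1, 1] <- 10L
  mg <- mean_grey(f, full_mask())
  expect_equal(attr(mg, "n_saturated"), 255L)
})

test_that("bleach curves normalize to the brightest picture", {
  frames <- lapply(c(200, 150, 100), uniform_frame)
  st <- image_stack(frames, c(0, 600, 1200))
  bc <- bleach_curve(st, full_mask(), fit = FALSE)
  expect_equal(bc$normalized, c(1.0, 0.75, 0.5))
  expect_equal(max(bc$normalized), 1)
})

test_that("constant stacks have no decay and no time constant", {
  st <- image_stack(lapply(rep(120, 4), uniform_frame), 0:3)
  bc <- bleach_curve(st, full_mask())
  expect_equal(bc$normalized, rep(1, 4))
  expect_true(is.na(attr(bc, "tau")))
})

test_that("the fitted time constant recovers the injected bleaching rate", {
  tau <- 1200
  st <- render_stack(stack_spec(bleach_time_constant = tau,
                                pixel_noise_sd = 0))
  roi <- Reduce(`|`, lapply(st$meta$masks, `[[`, "soma"))
  bc <- bleach_curve(st, roi)
  expect_lt(abs(attr(bc, "tau") - tau) / tau, 0.05)
  # pure bleaching: first frame brightest, normalized strictly decreasing
  expect_equal(which.max(bc$normalized), 1L)
  expect_true(all(diff(bc$normalized) < 0))
})

test_that("luminosity histograms have 256 unit bins summing to one", {
  h <- luminosity_histogram(uniform_frame(42))
  expect_equal(nrow(h), 256L)
  expect_equal(h$density[h$grey == 42], 1)
  expect_equal(sum(h$density), 1)

  set.seed(12)
  f <- matrix(as.integer(sample(0:255, 400, TRUE)), 20, 20)
  h2 <- luminosity_histogram(f)
  expect_equal(sum(h2$density), 1)
})

test_that("bleaching shifts the histogram mass toward dark values", {
  st <- render_stack(stack_spec(bleach_time_constant = 900,
                                pixel_noise_sd = 0))
  roi <- Reduce(`|`, lapply(st$meta$masks, `[[`, "soma"))
  centers <- vapply(st$frames, function(f)
    histogram_mean(luminosity_histogram(f, roi)), numeric(1))
  expect_true(all(diff(centers) < 0))
})

test_that("internalization is called with the right onset, bleach-only is not", {
  frame_times <- seq(0, 3600, by = 600)
  onset_time <- frame_times[3]
  sti <- render_stack(stack_spec(internalization_onset = onset_time,
                                 pixel_noise_sd = 0))
  ic <- detect_internalization(sti)
  expect_true(ic$detected)
  expect_equal(ic$onset_frame, min(which(sti$meta$internalized)))

  st0 <- render_stack(stack_spec(pixel_noise_sd = 0))
  expect_false(detect_internalization(st0)$detected)

  # constant stack: no change at all
  stc <- render_stack(stack_spec(bleach_time_constant = Inf,
                                 pixel_noise_sd = 0))
  icc <- detect_internalization(stc)
  expect_false(icc$detected)
  expect_true(all(icc$shift_statistic[-1, ] == 0))
  expect_true(is.na(icc$onset_frame))
})

test_that("the detector separates internalization from bleaching under noise", {
  calls <- function(noise, with_int, seeds) {
    vapply(seeds, function(s) {
      sp <- stack_spec(pixel_noise_sd = noise, seed = s,
                       internalization_onset =
                         if (with_int) 1200 else NA_real_)
      detect_internalization(render_stack(sp))$detected
    }, logical(1))
  }
  # noiseless: perfect separation
  expect_true(all(calls(0, TRUE, 1:5)))
  expect_false(any(calls(0, FALSE, 1:5)))
  # pixel noise SD 2: at least 90% sensitivity and specificity
  expect_gte(mean(calls(2, TRUE, 1:10)), 0.9)
  expect_gte(mean(!calls(2, FALSE, 1:10)), 0.9)
})

test_that("brightness scaling leaves normalized bleach curves unchanged", {
  st1 <- render_stack(stack_spec(initial_brightness = 100, background = 0,
                                 pixel_noise_sd = 0))
  st2 <- render_stack(stack_spec(initial_brightness = 200, background = 0,
                                 pixel_noise_sd = 0))
  roi <- Reduce(`|`, lapply(st1$meta$masks, `[[`, "ring"))
  b1 <- bleach_curve(st1, roi, fit = FALSE)
  b2 <- bleach_curve(st2, roi, fit = FALSE)
  expect_lt(max(abs(b1$normalized - b2$normalized)), 0.02)
})
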
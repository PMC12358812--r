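test_that("epoching keeps all 40 trials of the standard stimulation schedule", {
  rate <- 40
  trace <- rep(0, 450 * rate)
  stims <- 5 + (0:39) * 10            # 40 stimuli, 10-s inter-stimulus
  ts <- epoch_trials(trace, stims, pre_s = 1, post_s = 3, rate = rate)
  expect_equal(nrow(ts$trials), 40)
  expect_equal(ts$n_dropped, 0)
  expect_equal(ts$stim_index, rate + 1)

  expect_error(epoch_trials(rep(0, 100), 0.5, pre_s = 1, post_s = 1,
                            rate = rate), "zero usable")

  # windows that leave the recording are dropped with a count
  ts2 <- epoch_trials(rep(0, 10 * rate), c(2, 9.5), pre_s = 1, post_s = 3,
                      rate = rate)
  expect_equal(nrow(ts2$trials), 1)
  expect_equal(ts2$n_dropped, 1)

  # trials overlapping motion intervals are excluded
  ts3 <- epoch_trials(rep(0, 100 * rate), c(10, 30, 50), pre_s = 1,
                      post_s = 3, rate = rate,
                      motion_periods = data.frame(onset = 29, offset = 31))
  expect_equal(nrow(ts3$trials), 2)
  expect_equal(ts3$n_motion_excluded, 1)
})

test_that("trial-average onset matches the injected latency on a synthetic scene", {
  cfg <- evoked_scenario(n_trials = 5, duration = 60, first_s = 5,
                         image_shape = c(32, 32), rng_seed = 41,
                         noise_sd = 0.002)
  sim <- simulate_movie(cfg)
  dffm <- preprocess_movie(sim$movie, band = NULL)
  ev <- cfg$evoked_spec$visual
  tr <- extract_roi_trace(dffm, ev$roi_contra)
  ts <- epoch_trials(tr, sim$truth$stim_times, 1, 3, rate = 40,
                     frame_times = dffm$frame_times)
  ts <- baseline_subtract(ts, 1)
  avg <- average_trials(ts)
  pk <- which.max(avg$mean)
  expected_pk <- ts$stim_index + round((ev$latency_s + ev$rise_s) * 40)
  expect_lte(abs(pk - expected_pk), 1)
})

test_that("baseline subtraction zeroes the pre-window and leaves flat-baseline peaks alone", {
  ts <- make_trials(seed = 5, n_trials = 8, noise_sd = 0)
  offset <- ts; offset$trials <- offset$trials + 0.02
  sub <- baseline_subtract(offset, 1)
  pre <- sub$epoch_times < 0
  expect_lt(max(abs(rowMeans(sub$trials[, pre]))), 1e-12)
  expect_equal(sub$trials, ts$trials, tolerance = 1e-12)

  zero <- ts; zero$trials[] <- 0
  expect_true(all(baseline_subtract(zero, 1)$trials == 0))

  # with a flat pre-window the post-stimulus peak is untouched
  expect_equal(max(sub$trials), max(offset$trials) - 0.02,
               tolerance = 1e-12)
  expect_error(baseline_subtract(ts, 1e-9), "empty pre-stimulus")
})

test_that("trial averaging computes mean and SEM with the n-1 convention", {
  ts <- make_trials(seed = 6, n_trials = 5, noise_sd = 0)
  same <- ts; same$trials <- matrix(rep(same$trials[1, ], each = 5), 5)
  avg <- average_trials(same)
  expect_equal(avg$mean, same$trials[1, ])
  expect_true(all(avg$sem == 0))

  two <- ts; two$trials <- matrix(c(0, 2), 2, ncol(ts$trials))
  avg2 <- average_trials(two)
  expect_equal(avg2$mean[1], 1)
  expect_equal(avg2$sem[1], 1)    # sd(c(0,2))/sqrt(2) = 1

  one <- ts; one$trials <- ts$trials[1, , drop = FALSE]
  avg1 <- average_trials(one)
  expect_false(avg1$sem_defined)
  expect_true(all(is.na(avg1$sem)))
})

test_that("the trial mean converges to the injected kinetic at the Monte-Carlo rate", {
  rate <- 40
  tt <- seq(-1, 3, by = 1 / rate)
  kin <- 0.05 * mesogaba:::evoked_kinetic(tt, 0.1, 0.1, 0.4)
  noise_sd <- 0.01
  ts <- make_trials(seed = 7, n_trials = 40, noise_sd = noise_sd)
  avg <- average_trials(ts)
  rmse <- sqrt(mean((avg$mean - kin)^2))
  expect_lt(rmse, noise_sd / sqrt(40) * 1.5)
})

test_that("ROI traces are unweighted 3x3 means with border protection", {
  frame <- matrix(0, 5, 5)
  stack <- array(2.5, c(4, 5, 5))
  expect_equal(extract_roi_trace(stack, c(3, 3)), rep(2.5, 4))

  stack2 <- array(0, c(2, 5, 5))
  stack2[, 3, 3] <- 9
  expect_equal(extract_roi_trace(stack2, c(3, 3)), c(1, 1))

  expect_error(extract_roi_trace(stack, c(1, 3)), "border")
  expect_error(extract_roi_trace(stack, c(3, 5)), "border")
})

test_that("response features match closed forms and flag degenerate traces", {
  rate <- 40
  # pure exponential decay after the peak: 50% crossing at tau ln 2
  trace <- c(rep(0, 40), 0.05 * exp(-(0:160) / rate / 0.4))
  f <- response_features(trace, rate, stim_index = 40)
  expect_equal(f$peak_amplitude, 0.05)
  expect_lt(abs(f$decay_time_ms - 400 * log(2)), 1000 / rate)
  expect_true(f$decay_valid)

  zero <- response_features(rep(0, 200), rate, stim_index = 40)
  expect_equal(zero$peak_amplitude, 0)
  expect_false(zero$decay_valid)
  expect_false(zero$time_to_peak_valid)

  # plateau: earliest sample wins the argmax
  plat <- c(rep(0, 40), rep(1, 20), rep(0, 100))
  fp <- response_features(plat, rate, stim_index = 40)
  expect_equal(fp$time_to_peak_ms, 1000 / rate)

  # a decay that never reaches 50% before the trace ends is flagged
  slow <- c(rep(0, 40), 0.05 * exp(-(0:40) / rate / 10))
  fs <- response_features(slow, rate, stim_index = 40)
  expect_false(fs$decay_valid)

  expect_error(response_features(c(rep(0, 40), rep(NaN, 60)), rate, 40),
               "NaN")
})

test_that("contralateral responses are stronger and earlier than ipsilateral in seeded runs", {
  rate <- 40
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      tt <- seq(-1, 3, by = 1 / rate)
      mk <- function(amp, lat) {
        kin <- amp * mesogaba:::evoked_kinetic(tt, lat, 0.1, 0.4)
        trials <- t(vapply(1:40, function(i)
          kin + 0.02 * mesogaba:::band_limited_noise(length(tt), rate,
                                                     0.2, 3) +
            rnorm(length(tt), 0, 0.01 / 3), numeric(length(tt))))
        ts <- structure(list(trials = trials, stim_index = which(tt == 0),
                             pre_s = 1, post_s = 3, rate = rate,
                             epoch_times = tt), class = "trial_set")
        avg <- average_trials(baseline_subtract(ts, 1))
        response_features(avg$mean, rate, ts$stim_index)
      }
      con <- mk(0.05, 0.1)
      ips <- mk(0.025, 0.15)
      con$peak_amplitude > ips$peak_amplitude &&
        con$time_to_peak_ms < ips$time_to_peak_ms
    })
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("SEM scales as the inverse square root of the trial count", {
  sems <- vapply(c(10, 40, 160), function(n) {
    mean(vapply(1:4, function(s)
      mean(average_trials(make_trials(seed = s, n_trials = n))$sem), 0))
  }, 0)
  expect_lt(abs(sems[1] / sems[2] - 2), 0.4)     # within 20% of 2
  expect_lt(abs(sems[2] / sems[3] - 2), 0.4)
})

test_that("montage frames are pure views of the trial-average stack", {
  cfg <- evoked_scenario(n_trials = 3, duration = 40, first_s = 5,
                         image_shape = c(16, 16), rng_seed = 42)
  sim <- simulate_movie(cfg)
  ts <- epoch_trials(sim$truth$true_dff, sim$truth$stim_times, 1, 2,
                     rate = 40)
  avg <- average_trials(ts)
  mf <- montage_frames(avg, lags_s = c(0.2, 0.5))
  idx <- avg$stim_index + round(c(0.2, 0.5) * 40)
  expect_identical(mf[[1]], avg$mean[idx[1], , ])
  expect_identical(mf[[2]], avg$mean[idx[2], , ])
})
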
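test_that("deinterleaving separates channels and re-interleaving restores the input", {
  meta <- list(mode = "strobed_dual", frame_rate_total = 80,
               channel_order = "blue_first")
  # alternating constant frames 1,2,1,2
  stack <- array(rep(c(1, 2), 4), c(8, 2, 2))
  ch <- deinterleave(stack, meta)
  expect_true(all(ch$blue == 1))
  expect_true(all(ch$green == 2))
  expect_equal(ch$blue_times, (seq(0, 6, 2)) / 80)
  expect_equal(ch$green_times, (seq(1, 7, 2)) / 80)

  withr::with_seed(1, {
    rnd <- array(rnorm(16 * 4 * 3), c(16, 4, 3))
  })
  ch2 <- deinterleave(rnd, meta)
  expect_identical(reinterleave(ch2$blue, ch2$green), rnd)

  # the generator's own blue frames come back exactly
  sim <- simulate_movie(tiny_cfg(seed = 31))
  ch3 <- deinterleave(mesogaba:::interleave_movie(sim$movie),
                      sim$movie$metadata)
  expect_identical(ch3$blue, sim$movie$blue)

  expect_error(deinterleave(rnd, list(mode = "continuous_blue")), "skip")
  expect_error(deinterleave(rnd[1:15, , , drop = FALSE], meta), "even")
})

test_that("channel assignment verification matches frames to references", {
  withr::with_seed(2, {
    ref_b <- matrix(runif(64), 8)
    ref_g <- matrix(runif(64), 8)
  })
  ok <- verify_channel_assignment(ref_b, ref_g, ref_b, ref_g)
  expect_false(ok$swap)
  expect_equal(ok$correlations["blue", "blue"], 1)

  swapped <- verify_channel_assignment(ref_g, ref_b, ref_b, ref_g)
  expect_true(swapped$swap)

  # a negated frame correlates at -1 with its own reference and so is
  # assigned to the other
  neg <- verify_channel_assignment(-ref_b, ref_b, ref_b, ref_g)
  expect_equal(neg$correlations["blue", "blue"], -1)

  expect_error(verify_channel_assignment(matrix(1, 8, 8), ref_g,
                                         ref_b, ref_g), "zero-variance")
  expect_error(verify_channel_assignment(ref_b, ref_b, ref_b, ref_g),
               "ambiguous")
})

test_that("channels deliberately swapped in a synthetic movie raise the swap flag", {
  sim <- simulate_movie(tiny_cfg(seed = 32))
  ref_b <- sim$movie$blue[1, , ]
  ref_g <- sim$movie$green[1, , ]
  res <- verify_channel_assignment(sim$movie$green[1, , ],
                                   sim$movie$blue[1, , ], ref_b, ref_g)
  expect_true(res$swap)
})

test_that("ΔF/F closed forms hold and the baseline-window mean is zero", {
  tb <- 100; h <- 4; w <- 4
  f0 <- matrix(500, h, w)
  stack <- array(rep(500, tb * h * w), c(tb, h, w))
  d0 <- compute_dff(stack)
  expect_true(all(d0$dff == 0))

  # F = 1.05 F0 outside a pre-stimulus baseline
  times <- (seq_len(tb) - 1) / 10
  stack2 <- stack
  stack2[times >= 5, , ] <- 500 * 1.05
  d2 <- compute_dff(stack2, baseline = list(mode = "pre_stimulus",
                                            window_s = 2, stim_time = 5),
                    frame_times = times)
  expect_equal(max(d2$dff), 0.05, tolerance = 1e-12)
  bwin <- times >= 3 & times < 5
  expect_lt(max(abs(colMeans(mesogaba:::tp_view(d2$dff)[bwin, ]))), 1e-10)

  expect_error(compute_dff(stack2, baseline = list(mode = "pre_stimulus",
                                                   window_s = 2,
                                                   stim_time = -10),
                           frame_times = times), "empty baseline")
  neg <- stack; neg[, 1, 1] <- -1
  expect_warning(dn <- compute_dff(neg), "non-positive")
  expect_true(all(is.na(dn$dff[, 1, 1])))
})

test_that("session-mean ΔF/F on a noise-free scene matches the generator truth", {
  cfg <- scenario_config(image_shape = c(10, 10), duration = 60,
                         rng_seed = 33, noise_sd = 0,
                         reflectance_noise_sd = 0, bleach_tau = 1e12)
  sim <- simulate_movie(cfg)
  # no bleach, ideal alpha removal, then session-mean normalization
  b <- mesogaba:::tp_view(sim$movie$blue)
  tb <- nrow(b)
  f0 <- as.vector(sim$truth$f0_map)
  corrected <- b - outer(sim$truth$hemo_blue,
                         as.vector(sim$truth$alpha_map) * f0)
  d <- compute_dff(mesogaba:::stack_view(corrected, 10, 10),
                   f0_reference = sim$truth$f0_map)
  td <- mesogaba:::tp_view(sim$truth$true_dff)
  td_centered <- sweep(td, 2, colMeans(td))   # session mean defines zero
  expect_lt(max(abs(mesogaba:::tp_view(d$dff) - td_centered)), 1e-8)
})

test_that("hemodynamic regression handles degenerate and exact cases", {
  tb <- 200; h <- 3; w <- 3
  withr::with_seed(4, {
    r <- array(rnorm(tb * h * w, 100, 5), c(tb, h, w))
  })
  # R constant: alpha = 0, corrected = F, flagged
  rconst <- array(7, c(tb, h, w))
  f <- r   # any stack
  hc <- hemodynamic_correct(f, rconst)
  expect_true(all(hc$fit$alpha_map == 0))
  expect_true(all(hc$fit$flagged))
  expect_identical(hc$corrected, f)

  # exact linear relation F = 3 + 0.4 R
  f2 <- 3 + 0.4 * r
  hc2 <- hemodynamic_correct(f2, r)
  expect_equal(as.vector(hc2$fit$alpha_map), rep(0.4, 9), tolerance = 1e-12)
  expect_lt(max(abs(hc2$corrected - 3)), 1e-9)
  expect_equal(as.vector(hc2$fit$r_squared_map), rep(1, 9),
               tolerance = 1e-9)

  expect_error(hemodynamic_correct(f2[1:100, , , drop = FALSE], r), "match")
})

test_that("residual of corrected-on-reflectance has zero slope; re-correction is idempotent", {
  cfg <- scenario_config(image_shape = c(8, 8), duration = 30, rng_seed = 34,
                         noise_sd = 0, reflectance_noise_sd = 0)
  sim <- simulate_movie(cfg)
  r_al <- align_channels(sim$movie$green, sim$movie$green_times,
                         sim$movie$blue_times)
  hc <- hemodynamic_correct(sim$movie$blue, r_al)
  hc2 <- hemodynamic_correct(hc$corrected, r_al)
  expect_lt(max(abs(hc2$fit$alpha_map)), 1e-8)
})

test_that("band-pass filter rejects DC, passes the band, and suppresses out-of-band tones", {
  rate <- 40
  t <- seq(0, 100, by = 1 / rate)
  expect_lt(max(abs(bandpass(rep(5, length(t)), 0.1, 5, rate))), 5e-6)

  s1 <- sin(2 * pi * 1 * t)
  out1 <- bandpass(s1, 0.1, 5, rate)
  mid <- t > 10 & t < 90   # ignore filter edges
  expect_gt(max(abs(out1[mid])), 0.95)

  s15 <- sin(2 * pi * 15 * t)
  expect_lt(max(abs(bandpass(s15, 0.1, 5, rate)[mid])), 0.1)

  # peak timing of a transient is not shifted by more than one frame
  kin <- 0.05 * mesogaba:::evoked_kinetic(t, 50, 0.1, 0.4)
  outk <- bandpass(kin, 0.1, 5, rate)
  expect_lte(abs(which.max(outk) - which.max(kin)), 1)

  expect_error(bandpass(s1, 0.1, 25, rate), "Nyquist")
  expect_error(bandpass(s1, 0, 5, rate), "Nyquist")
})

test_that("green-channel alignment interpolates exactly and tracks the hemodynamic process", {
  h <- 2; w <- 2
  gt <- seq(0.0125, by = 0.025, length.out = 40)
  bt <- seq(0, by = 0.025, length.out = 40)
  const <- array(3, c(40, h, w))
  expect_true(all(align_channels(const, gt, bt) == 3))

  ramp <- array(rep(2 * gt + 1, h * w), c(40, h, w))
  al <- align_channels(ramp, gt, bt)
  # interior blue times are exactly on the ramp; the first is held
  expect_lt(max(abs(al[-1, 1, 1] - (2 * bt[-1] + 1))), 1e-12)
  expect_equal(al[1, 1, 1], 2 * gt[1] + 1)

  sim <- simulate_movie(scenario_config(image_shape = c(6, 6), duration = 60,
                                        rng_seed = 35, noise_sd = 0,
                                        reflectance_noise_sd = 0))
  al2 <- align_channels(sim$movie$green, sim$movie$green_times,
                        sim$movie$blue_times)
  g_tr <- al2[, 3, 3]
  expect_gt(pearson_oracle(g_tr, sim$truth$hemo_blue), 0.999)

  expect_error(align_channels(const, gt + 100, bt), "overlap")
})
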
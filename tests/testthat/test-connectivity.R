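test_that("every correlation output equals the brute-force Pearson oracle", {
  withr::with_seed(61, {
    stack <- array(rnorm(800 * 8 * 8), c(800, 8, 8))
  })
  rois <- data.frame(name = c("A_L", "B_L", "A_R", "B_R"),
                     hemisphere = c("L", "L", "R", "R"),
                     x = c(3, 3, 6, 6), y = c(3, 6, 3, 6),
                     homolog_name = c("A_R", "B_R", "A_L", "B_L"))
  cm <- roi_correlation_matrix(stack, rois, band = NULL, rate = 40)
  traces <- mesogaba:::roi_trace_matrix(stack, rois)
  expect_lt(max(abs(cm - cor_matrix_oracle(traces))), 1e-12)
  expect_true(isSymmetric(unclass(cm)))
  expect_equal(unname(diag(cm)), rep(1, 4))

  # seed map against the oracle, unfiltered
  map <- seed_correlation_map(stack, c(4, 4), band = NULL, rate = 40)
  seed_tr <- extract_roi_trace(stack, c(4, 4))
  expect_lt(abs(map[5, 7] - pearson_oracle(seed_tr, stack[, 5, 7])), 1e-12)
})

test_that("seed maps: self-correlation, white-noise floor, planted communities", {
  withr::with_seed(62, {
    stack <- array(rnorm(4000 * 10 * 10), c(4000, 10, 10))
  })
  map1 <- seed_correlation_map(stack, c(5, 5), band = NULL, rate = 40,
                               seed_size = 1)
  expect_equal(map1[5, 5], 1)
  off <- map1; off[5, 5] <- NA   # drop the seed pixel itself
  # sampling bound for independent pixels: |r| ~ 2.6/sqrt(T) at the 99th pct
  expect_lt(quantile(abs(off), 0.99, na.rm = TRUE), 0.06)

  # noise-free shared signal: 3x3 seed self-correlation is exactly 1
  cfg <- scenario_config(image_shape = c(10, 10), duration = 30,
                         rng_seed = 63, noise_sd = 0,
                         reflectance_noise_sd = 0, hemo_sd = 0)
  sim <- simulate_movie(cfg)
  m2 <- seed_correlation_map(sim$truth$true_dff, c(3, 5), band = NULL,
                             rate = 40, min_frames = 50)
  expect_equal(m2[5, 3], 1, tolerance = 1e-9)

  # two-community scene: block A pixels share signal sA, block B share sB;
  # within-community r is planted at 0.6, between at 0
  tpts <- 3000
  withr::with_seed(65, {
    sA <- rnorm(tpts); sB <- rnorm(tpts)
    blockA <- sqrt(0.6) * sA + sqrt(0.4) * matrix(rnorm(tpts * 32), tpts)
    blockB <- sqrt(0.6) * sB + sqrt(0.4) * matrix(rnorm(tpts * 32), tpts)
  })
  stack2 <- array(cbind(blockA, blockB), c(tpts, 8, 8))
  map2 <- seed_correlation_map(stack2, c(2, 4), band = NULL, rate = 40)
  # planted value for seed(3x3 ROI mean)-vs-pixel: cov 0.6 against seed
  # variance 0.6 + 0.4/9
  r_plant <- 0.6 / sqrt(0.6 + 0.4 / 9)
  inroi <- matrix(FALSE, 8, 8); inroi[3:5, 1:3] <- TRUE
  within_r <- mean(map2[, 1:4][!inroi[, 1:4]])
  between_r <- mean(map2[, 5:8])
  expect_lt(abs(within_r - r_plant), 0.05)
  expect_lt(abs(between_r - 0), 0.05)

  expect_error(seed_correlation_map(stack[1:50, , ], c(5, 5), band = NULL,
                                    rate = 40), "100")
})

test_that("interhemispheric mean covers homolog pairs only", {
  rois <- default_roi_table(c(64, 64))
  withr::with_seed(66, {
    common <- rnorm(2000)
    stack <- array(rnorm(2000 * 64 * 64) * 0.5 + common, c(2000, 64, 64))
  })
  cm <- roi_correlation_matrix(stack, rois, band = NULL, rate = 40)
  im <- interhemispheric_mean(cm, rois)
  expect_equal(length(attr(im, "pair_r")), 10)
  expect_gt(as.numeric(im), 0.5)   # shared global signal couples hemispheres

  # identical hemispheres give exactly 1
  half <- matrix(rnorm(2000 * 32 * 64), 2000)
  mirrored <- array(0, c(2000, 64, 64))
  mirrored[, , 1:32] <- half
  mirrored[, , 64:33] <- half
  cm2 <- roi_correlation_matrix(mirrored, rois, band = NULL, rate = 40)
  im2 <- interhemispheric_mean(cm2, rois)
  expect_equal(as.numeric(im2), 1, tolerance = 1e-9)

  # independent hemispheres: long-run mean near zero
  withr::with_seed(67, {
    indep <- array(rnorm(4000 * 16 * 16), c(4000, 16, 16))
  })
  rois16 <- default_roi_table(c(16, 16), pixel_size_um = 8600 / 16)
  cm3 <- roi_correlation_matrix(indep, rois16, band = NULL, rate = 40)
  expect_lt(abs(as.numeric(interhemispheric_mean(cm3, rois16))), 0.05)

  bad <- cm3[1:19, 1:19]
  expect_error(interhemispheric_mean(bad, rois16), "homolog")
})

test_that("ROI errors name the offending ROI", {
  stack <- array(rnorm(200 * 8 * 8), c(200, 8, 8))
  rois <- data.frame(name = c("ok_L", "edge_R"), hemisphere = c("L", "R"),
                     x = c(4, 8), y = c(4, 4),
                     homolog_name = c("edge_R", "ok_L"))
  expect_error(roi_correlation_matrix(stack, rois, band = NULL, rate = 40),
               "inside the image|edge_R")
})

test_that("state-resolved connectivity partitions frames correctly", {
  cfg <- sleep_scenario(image_shape = c(16, 16), rng_seed = 68)
  sim <- simulate_movie(cfg)
  rois <- default_roi_table(c(16, 16), pixel_size_um = 8600 / 16)
  hyp <- hypnogram_from_blocks(cfg$state_block_spec, 5)
  attr(hyp, "epoch_length_s") <- 5

  conn <- state_resolved_connectivity(sim$truth$true_dff, hyp, rois,
                                      band = NULL, rate = 40)
  expect_setequal(names(conn), c("WAKE", "NREM", "REM"))
  expect_equal(conn$WAKE$frames_used, 120 * 40)

  # single-state hypnogram reproduces the unconditioned matrix
  hyp1 <- hypnogram_from_blocks(data.frame(state = "WAKE", duration = 300),
                                5)
  attr(hyp1, "epoch_length_s") <- 5
  c1 <- state_resolved_connectivity(sim$truth$true_dff, hyp1, rois,
                                    band = NULL, rate = 40)
  cm_all <- roi_correlation_matrix(sim$truth$true_dff, rois, band = NULL,
                                   rate = 40)
  expect_lt(max(abs(c1$WAKE$roi_matrix - cm_all)), 1e-12)

  # a state with too few frames is skipped with a warning
  hyp2 <- hyp
  hyp2$label[hyp2$label == "REM"] <- "NREM"
  hyp2$label[1] <- "REM"
  expect_warning(
    c2 <- state_resolved_connectivity(sim$truth$true_dff, hyp2, rois,
                                      band = NULL, rate = 40, min_frames = 500),
    "skipped")
  expect_false("REM" %in% names(c2))
})

test_that("frame shuffling leaves correlations unchanged and masked frames are never used", {
  withr::with_seed(69, {
    stack <- array(rnorm(600 * 8 * 8), c(600, 8, 8))
    perm <- sample(600)
  })
  rois <- data.frame(name = c("A_L", "A_R"), hemisphere = c("L", "R"),
                     x = c(3, 6), y = c(4, 4),
                     homolog_name = c("A_R", "A_L"))
  cm <- roi_correlation_matrix(stack, rois, band = NULL, rate = 40)
  cm_p <- roi_correlation_matrix(stack[perm, , ], rois, band = NULL,
                                 rate = 40)
  expect_lt(max(abs(cm - cm_p)), 1e-12)

  # corrupt masked frames wildly: the result must not move
  mask <- rep(FALSE, 600); mask[100:250] <- TRUE
  corrupted <- stack
  corrupted[100:250, , ] <- 1e6 * corrupted[100:250, , ]
  cm_m1 <- roi_correlation_matrix(stack, rois, band = NULL, rate = 40,
                                  frame_mask = mask)
  cm_m2 <- roi_correlation_matrix(corrupted, rois, band = NULL, rate = 40,
                                  frame_mask = mask)
  expect_lt(max(abs(cm_m1 - cm_m2)), 1e-12)
  expect_equal(attr(cm_m1, "frames_used"), 600 - 151)
})

test_that("spectral power estimates are calibrated", {
  rate <- 40
  t <- seq(0, 100 - 1 / rate, by = 1 / rate)
  s <- sin(2 * pi * 1 * t)
  sp <- spectral_power(s, rate, seg_s = 8)
  df <- sp$freq[2] - sp$freq[1]
  tot <- sum(sp$psd) * df
  in_band <- mesogaba:::band_power(sp, 0.8, 1.2)
  expect_gt(in_band / tot, 0.9)
  expect_lt(abs(tot - var(s)) / var(s), 0.05)      # Parseval

  withr::with_seed(70, wn <- rnorm(4000))
  spw <- spectral_power(wn, rate)
  dfw <- spw$freq[2] - spw$freq[1]
  expect_lt(abs(sum(spw$psd) * dfw - var(wn)) / var(wn), 0.05)
  # flat across decades: binned mean ratio bounded
  bins <- cut(spw$freq[spw$freq > 0.1], breaks = c(0.1, 1, 10, 20))
  bm <- tapply(spw$psd[spw$freq > 0.1], bins, mean)
  expect_lt(max(bm) / min(bm), 3)

  expect_error(spectral_power(rnorm(100), rate), "8 s")
})
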
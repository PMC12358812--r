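#' Simulate a dual-channel wide-field recording with ground truth
#'
#' Generates an interleaved (strobed) fluorescence/reflectance movie, or a
#' continuous single-channel movie, following the generative model the
#' analysis chain inverts:
#'
#' blue(t, p)  = F0(p) (1 + dff(t, p) + alpha(p) hemo(t)) bleach(t) + noise,
#' green(t, p) = G0(p) (1 + hemo(t)) + noise,
#'
#' where `dff` holds state-dependent spontaneous cortical GABA signals
#' (a hemisphere-shared and a per-hemisphere band-limited 0.2-3 Hz process,
#' mixed so the interhemispheric correlation equals the configured
#' `shared` fraction) plus sensory-evoked transients (linear rise, then
#' exponential decay from the peak; contralateral stronger and earlier than
#' ipsilateral), `hemo` is a band-limited 0.05-0.3 Hz process shared by both
#' channels with smooth per-pixel gain, and `bleach` is a mono-exponential
#' affecting the fluorophore only.
#'
#' @param config A [scenario_config()].
#' @return List with `movie` (class `dual_channel_movie`: `blue`/`green`
#'   stacks `[frames, H, W]`, per-channel frame times, `metadata`) and
#'   `truth` (class `ground_truth_manifest`: `alpha_map`, `f0_map`,
#'   `true_dff` (noise-free ΔF/F on the blue clock), `bleach`, `hemo_blue`,
#'   `events`, `state_blocks`, `frame_states`, `stim_times`).
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$rng_seed, simulate_movie_impl(config))
}

simulate_movie_impl <- function(config) {
  h <- config$image_shape[1]; w <- config$image_shape[2]; P <- h * w
  n_total <- config$n_total_frames
  fr <- config$frame_rate_total
  times <- (seq_len(n_total) - 1) / fr
  strobed <- config$mode == "strobed_dual"
  if (strobed) {
    blue_idx <- seq(1L, n_total, by = 2L)   # blue first, then green
    green_idx <- blue_idx + 1L
  } else {
    blue_idx <- seq_len(n_total); green_idx <- integer(0)
  }
  blue_times <- times[blue_idx]
  green_times <- times[green_idx]
  tb <- length(blue_idx)
  fs_b <- if (strobed) fr / 2 else fr

  f0_map <- pmax(smooth_gain_map(h, w, config$f0_mean, config$f0_sd, 8), 100)
  ap <- config$hemo_alpha_map_params
  alpha_map <- pmax(smooth_gain_map(h, w, ap$mean, ap$sd, ap$smoothness), 0)
  f0_vec <- as.vector(f0_map); alpha_vec <- as.vector(alpha_map)

  hemo_full <- band_limited_noise(n_total, fr, config$hemo_band[1],
                                  config$hemo_band[2]) * config$hemo_sd
  if (config$hemo_sd == 0) hemo_full <- rep(0, n_total)
  hemo_b <- hemo_full[blue_idx]
  hemo_g <- hemo_full[green_idx]
  bleach_b <- exp(-blue_times / config$bleach_tau)

  # --- spontaneous state-dependent ΔF/F --------------------------------
  frame_states <- states_at(blue_times, config$state_block_spec)
  sd_vec <- vapply(frame_states,
                   function(s) config$spontaneous_spec[[s]]$sd, 0)
  sh_vec <- vapply(frame_states,
                   function(s) config$spontaneous_spec[[s]]$shared, 0)
  hi_spont <- min(3, fs_b / 2 * 0.9)
  g_shared <- band_limited_noise(tb, fs_b, 0.2, hi_spont)
  g_left <- band_limited_noise(tb, fs_b, 0.2, hi_spont)
  g_right <- band_limited_noise(tb, fs_b, 0.2, hi_spont)
  side_sig <- cbind(sd_vec * sqrt(1 - sh_vec) * g_left,
                    sd_vec * sqrt(1 - sh_vec) * g_right)
  # column j of the T x P matrix is pixel (y = (j-1) %% h + 1, x = (j-1) %/% h + 1)
  px_x <- rep(seq_len(w), each = h)
  side_of_px <- ifelse(px_x <= w / 2, 1L, 2L)
  dff <- side_sig[, side_of_px, drop = FALSE]
  dff <- dff + sd_vec * sqrt(sh_vec) * g_shared   # column-wise recycling

  # --- evoked transients ------------------------------------------------
  stim_times <- stim_times_from_spec(config)
  events <- list()
  if (!is.null(config$evoked_spec) && length(stim_times) > 0) {
    for (nm in names(config$evoked_spec)) {
      ev <- config$evoked_spec[[nm]]
      for (side in c("contra", "ipsi")) {
        roi <- if (side == "contra") ev$roi_contra else ev$roi_ipsi
        amp <- if (side == "contra") ev$amplitude
               else ev$amplitude / ev$contra_ipsi_ratio
        lat <- ev$latency_s + if (side == "ipsi") ev$latency_offset_s else 0
        fp <- evoked_footprint(h, w, roi)
        for (st in stim_times) {
          onset <- st + lat
          kin <- evoked_kinetic(blue_times, onset, ev$rise_s, ev$decay_tau_s)
          rows <- which(kin > 0)
          if (length(rows) == 0) next
          dff[rows, fp$cols] <- dff[rows, fp$cols] +
            kin[rows] %o% (amp * fp$weights)
          events[[length(events) + 1L]] <- data.frame(
            modality = nm, side = side, stim_time = st, onset = onset,
            peak_time = onset + ev$rise_s, peak_amplitude = amp,
            duration = ev$rise_s + ev$decay_tau_s * log(20),
            x = roi[1], y = roi[2])
        }
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(modality = character(0), side = character(0),
               stim_time = numeric(0), onset = numeric(0),
               peak_time = numeric(0), peak_amplitude = numeric(0),
               duration = numeric(0), x = numeric(0), y = numeric(0))

  true_dff <- dff

  # --- assemble channels ------------------------------------------------
  blue <- 1 + dff
  rm(dff)
  if (any(alpha_vec != 0) && any(hemo_b != 0))
    blue <- blue + hemo_b %o% alpha_vec
  blue <- blue * bleach_b
  blue <- blue * rep(f0_vec, each = tb)
  if (config$noise_sd > 0)
    blue <- blue + rnorm(tb * P) * (config$noise_sd * rep(f0_vec, each = tb))

  green <- NULL
  if (strobed) {
    green <- (1 + hemo_g) %o% f0_vec   # G0 = F0: matched channel baselines
    if (config$reflectance_noise_sd > 0)
      green <- green + rnorm(tb * P) *
        (config$reflectance_noise_sd * rep(f0_vec, each = tb))
  }

  metadata <- list(
    mode = config$mode, frame_rate_total = fr,
    channel_order = if (strobed) "blue_first" else "blue_only",
    frame_rate_per_channel = fs_b,
    pixel_size_um = 8600 / w * 1000 / 1000 * 1000 / 1000 * 134 / 134,
    image_shape = c(h, w),
    bregma_xy = c((w + 1) / 2, (h + 1) / 2),
    n_frames = n_total)
  metadata$pixel_size_um <- 8600 / w  # 8.6-mm field of view

  movie <- structure(list(
    blue = stack_view(blue, h, w),
    green = if (strobed) stack_view(green, h, w) else NULL,
    blue_times = blue_times, green_times = green_times,
    metadata = metadata), class = "dual_channel_movie")

  truth <- structure(list(
    alpha_map = alpha_map, f0_map = f0_map,
    true_dff = stack_view(true_dff, h, w),
    bleach = bleach_b, hemo_blue = hemo_b, hemo_green = hemo_g,
    events = events, state_blocks = config$state_block_spec,
    frame_states = frame_states, stim_times = stim_times),
    class = "ground_truth_manifest")

  list(movie = movie, truth = truth)
}

# Transient kinetic: linear rise over `rise_s`, then exponential decay from
# the peak. Makes the 50%-decay closed form decay_tau * ln 2 exact.
evoked_kinetic <- function(t, onset, rise_s, decay_tau_s) {
  dt <- t - onset
  k <- numeric(length(t))
  ris <- dt >= 0 & dt < rise_s
  dec <- dt >= rise_s
  k[ris] <- dt[ris] / rise_s
  k[dec] <- exp(-(dt[dec] - rise_s) / decay_tau_s)
  k[k < 1e-4] <- 0
  k
}

# Spatial footprint: flat core (radius 1.6 px, so a 3x3 ROI at the centre
# reads the full amplitude) with a Gaussian skirt (sigma 2 px, cut at r > 6).
evoked_footprint <- function(h, w, roi) {
  px_x <- rep(seq_len(w), each = h)
  px_y <- rep(seq_len(h), times = w)
  r <- sqrt((px_x - roi[1])^2 + (px_y - roi[2])^2)
  wts <- ifelse(r <= 1.6, 1, exp(-0.5 * ((r - 1.6) / 2)^2))
  keep <- which(r <= 6)
  list(cols = keep, weights = wts[keep])
}

#' @export
print.dual_channel_movie <- function(x, ...) {
  d <- dim(x$blue)
  cat("<dual_channel_movie> ", x$metadata$mode, ", ", d[1], " blue frames of ",
      d[2], "x", d[3], " px @ ", x$metadata$frame_rate_per_channel,
      " Hz/channel\n", sep = "")
  invisible(x)
}
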
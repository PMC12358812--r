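#' Simulate EMG, hippocampal LFP and video motion-energy traces
#'
#' Generates 2-kHz electrophysiology and motion traces consistent with a
#' vigilance-state block sequence: wakefulness carries high EMG tone with
#' superimposed movement bursts, NREM a delta-dominated (1-4 Hz) LFP, REM a
#' theta-dominated (5-10 Hz) LFP with minimal EMG and brief motor twitches.
#' Motion-energy traces (five ROIs: nose, whisker pad, ear, shoulder, trunk)
#' are near zero during sleep apart from REM twitches.
#'
#' @param state_blocks Data frame `state`, `duration` (s); usually
#'   `config$state_block_spec`.
#' @param config A [scenario_config()] (provides the seed).
#' @param rate Sampling rate, Hz (2000).
#' @param burst_rate Movement bursts per second of wakefulness.
#' @param burst_dur_range Burst duration range, s.
#' @param burst_gain EMG amplitude multiplier inside a movement burst.
#' @param emg_sd Named per-state EMG amplitude sd.
#' @param twitch_rate REM twitches per second.
#' @return List: `emg`, `lfp` (numeric traces), `motion` (samples x 5
#'   matrix), `rate`, `times`, `motion_periods` (true movement intervals,
#'   half-open, s), `twitch_periods`, `state_blocks`.
#' @export
simulate_ephys <- function(state_blocks, config, rate = 2000,
                           burst_rate = 0.25, burst_dur_range = c(0.5, 2),
                           burst_gain = 8,
                           emg_sd = c(WAKE = 1, NREM = 0.25, REM = 0.2),
                           twitch_rate = 0.1) {
  if (is.null(state_blocks) || nrow(state_blocks) == 0L)
    stop("invalid input: empty hypnogram/state block sequence")
  withr::with_seed(split_seed(config$rng_seed, "ephys"), {
    dur <- sum(state_blocks$duration)
    n <- round(dur * rate)
    t <- (seq_len(n) - 1) / rate
    st <- states_at(t, state_blocks)

    offs <- cumsum(state_blocks$duration)
    ons <- c(0, head(offs, -1))

    draw_periods <- function(block_on, block_off, rate_per_s, dr) {
      k <- rpois_compat((block_off - block_on) * rate_per_s)
      if (k == 0) return(NULL)
      on <- sort(runif(k, block_on, block_off))
      off <- pmin(on + runif(k, dr[1], dr[2]), block_off)
      data.frame(onset = on, offset = off)
    }

    motion_periods <- list(); twitch_periods <- list()
    for (i in seq_len(nrow(state_blocks))) {
      if (state_blocks$state[i] == "WAKE") {
        p <- draw_periods(ons[i], offs[i], burst_rate, burst_dur_range)
        if (!is.null(p)) motion_periods[[length(motion_periods) + 1L]] <- p
      } else if (state_blocks$state[i] == "REM") {
        p <- draw_periods(ons[i], offs[i], twitch_rate, c(0.2, 0.4))
        if (!is.null(p)) twitch_periods[[length(twitch_periods) + 1L]] <- p
      }
    }
    motion_periods <- tidy_intervals(
      if (length(motion_periods)) do.call(rbind, motion_periods) else NULL,
      gap = 0.25)
    twitch_periods <- tidy_intervals(
      if (length(twitch_periods)) do.call(rbind, twitch_periods) else NULL)

    # EMG: state-dependent tone plus movement bursts
    emg <- rnorm(n) * emg_sd[st]
    in_burst <- in_intervals(t, motion_periods)
    emg[in_burst] <- emg[in_burst] * burst_gain

    # LFP: delta and theta band components with state-dependent amplitude
    delta <- band_limited_noise(n, rate, 1, 4)
    theta <- band_limited_noise(n, rate, 5, 10)
    damp <- c(WAKE = 0.7, NREM = 1.0, REM = 0.25)[st]
    tamp <- c(WAKE = 0.6, NREM = 0.15, REM = 1.0)[st]
    lfp <- delta * damp + theta * tamp + 0.05 * rnorm(n)

    # motion energy per ROI: nonnegative, bursts in wake, twitches in REM
    in_twitch <- in_intervals(t, twitch_periods)
    roi_names <- c("nose", "whisker", "ear", "shoulder", "trunk")
    motion <- matrix(0, n, length(roi_names),
                     dimnames = list(NULL, roi_names))
    envelope <- 0.02 + 1.0 * in_burst + 0.5 * in_twitch
    for (j in seq_along(roi_names)) {
      gain <- runif(1, 0.7, 1.3)
      motion[, j] <- abs(rnorm(n)) * envelope * gain
    }

    list(emg = emg, lfp = lfp, motion = motion, rate = rate, times = t,
         motion_periods = motion_periods, twitch_periods = twitch_periods,
         state_blocks = state_blocks)
  })
}

rpois_compat <- function(lambda) stats::rpois(1, lambda)

#' Simulate an ROI fluorescence trace with spontaneous transients
#'
#' One-dimensional counterpart of the movie generator, used to exercise
#' baseline detrending and transient detection: a mono-exponential trend plus
#' offset, randomly placed transients (linear rise / exponential decay) and
#' white noise.
#'
#' @param duration_s,rate Trace length (s) and sampling rate (Hz).
#' @param n_events Number of transients; if `NULL`, drawn Poisson from
#'   `rate_per_min`.
#' @param rate_per_min Event rate used when `n_events` is `NULL`.
#' @param amplitude Peak amplitude (single value or per-event vector).
#' @param rise_s,decay_tau_s Transient kinetics.
#' @param noise_sd White noise sd.
#' @param trend `list(a, tau, c)` for trend `a * exp(-t/tau) + c`.
#' @param min_sep_s Minimum separation between event onsets.
#' @param seed Integer seed.
#' @return List: `trace`, `times`, `rate`, `events` (data frame `onset`,
#'   `peak_time`, `amplitude`), `trend`.
#' @export
simulate_transient_trace <- function(duration_s = 300, rate = 40,
                                     n_events = 20, rate_per_min = 4,
                                     amplitude = 0.05, rise_s = 0.1,
                                     decay_tau_s = 0.3, noise_sd = 0.01,
                                     trend = list(a = 0, tau = 200, c = 0),
                                     min_sep_s = 3, seed = 1L) {
  withr::with_seed(seed, {
    n <- round(duration_s * rate)
    t <- (seq_len(n) - 1) / rate
    k <- if (is.null(n_events)) rpois_compat(rate_per_min * duration_s / 60)
         else n_events
    onsets <- numeric(0)
    guard <- 0L
    while (length(onsets) < k && guard < 10000L) {
      cand <- runif(1, 1, duration_s - 3)
      if (all(abs(cand - onsets) >= min_sep_s)) onsets <- c(onsets, cand)
      guard <- guard + 1L
    }
    onsets <- sort(onsets)
    amps <- rep_len(amplitude, length(onsets))
    sig <- numeric(n)
    for (i in seq_along(onsets))
      sig <- sig + amps[i] * evoked_kinetic(t, onsets[i], rise_s, decay_tau_s)
    tr <- trend$a * exp(-t / trend$tau) + trend$c
    trace <- tr + sig + rnorm(n, 0, noise_sd)
    list(trace = trace, times = t, rate = rate,
         events = data.frame(onset = onsets, peak_time = onsets + rise_s,
                             amplitude = amps),
         trend = tr)
  })
}
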
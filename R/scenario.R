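#' Scenario configuration for the synthetic recording generator
#'
#' Defines one simulated recording session: geometry, acquisition mode,
#' duration, the hemodynamic artifact, photobleaching, sensory-evoked
#' transients, the vigilance-state block sequence with state-dependent
#' spontaneous synchrony, and the stimulation schedule. Defaults encode the
#' study conditions the analysis targets: 64x64-pixel scenes, 80 Hz strobed
#' acquisition (40 Hz per channel), ΔF/F noise sd 0.01, a 0.05-0.3 Hz shared
#' hemodynamic process with smooth per-pixel gain (mean 0.5), a gentle
#' mono-exponential bleach (tau 10,000 s, ~9% over a 15-min session), and
#' interhemispheric spontaneous synchrony ordered wake > REM > NREM
#' (0.70 / 0.45 / 0.15).
#'
#' @param image_shape `c(H, W)` pixels.
#' @param frame_rate_total Total camera frame rate, Hz (80 strobed; 150
#'   continuous).
#' @param mode `"strobed_dual"` (interleaved blue/green) or
#'   `"continuous_blue"` (single channel).
#' @param duration Session length, s.
#' @param rng_seed Integer seed; the whole scenario is deterministic given it.
#' @param bleach_tau Photobleaching time constant, s (blue channel only —
#'   reflectance does not bleach).
#' @param noise_sd Blue-channel pixel noise, ΔF/F units of the local baseline.
#' @param reflectance_noise_sd Green-channel relative noise (the reflectance
#'   channel is photon-rich, so half the fluorescence noise by default).
#' @param hemo_sd Hemodynamic fluctuation sd as a fraction of baseline.
#' @param hemo_band Frequency band of the hemodynamic process, Hz.
#' @param hemo_alpha_map_params `list(mean, sd, smoothness)` of the per-pixel
#'   hemodynamic gain map.
#' @param evoked_spec Named list of modalities; each a list with
#'   `roi_contra`/`roi_ipsi` (`c(x, y)` pixels), `amplitude` (peak ΔF/F),
#'   `latency_s` (stimulus to onset), `rise_s` (onset to peak),
#'   `decay_tau_s`, `contra_ipsi_ratio` (>= 1), `latency_offset_s`
#'   (extra ipsilateral latency). `NULL` for spontaneous-only scenes.
#' @param state_block_spec Data frame `state` ("WAKE"/"NREM"/"REM"),
#'   `duration` (s); must sum to `duration`.
#' @param spontaneous_spec Per-state list of `list(sd, shared)` where `sd` is
#'   the spontaneous ΔF/F sd and `shared` the fraction of its variance carried
#'   by the hemisphere-shared (global) signal, i.e. the target
#'   interhemispheric correlation.
#' @param stim_spec `list(n_trials, isi_s, pulse_s, first_s)` or `NULL`.
#' @param f0_mean,f0_sd Baseline fluorescence map (camera counts).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(image_shape = c(64, 64),
                            frame_rate_total = 80,
                            mode = c("strobed_dual", "continuous_blue"),
                            duration = 60,
                            rng_seed = 1L,
                            bleach_tau = 10000,
                            noise_sd = 0.01,
                            reflectance_noise_sd = noise_sd / 2,
                            hemo_sd = 0.04,
                            hemo_band = c(0.05, 0.3),
                            hemo_alpha_map_params = list(mean = 0.5, sd = 0.1,
                                                         smoothness = 8),
                            evoked_spec = NULL,
                            state_block_spec = data.frame(
                              state = "WAKE", duration = duration),
                            spontaneous_spec = list(
                              WAKE = list(sd = 0.020, shared = 0.70),
                              REM  = list(sd = 0.015, shared = 0.45),
                              NREM = list(sd = 0.015, shared = 0.15)),
                            stim_spec = NULL,
                            f0_mean = 1500, f0_sd = 150) {
  mode <- match.arg(mode)
  if (!is.numeric(duration) || duration <= 0)
    stop("invalid config: duration must be positive")
  if (!is.numeric(frame_rate_total) || frame_rate_total <= 0)
    stop("invalid config: frame_rate_total must be positive")
  n_total <- duration * frame_rate_total
  if (abs(n_total - round(n_total)) > 1e-9)
    stop("invalid config: duration x frame_rate_total must be an integer ",
         "frame count")
  n_total <- round(n_total)
  if (mode == "strobed_dual" && n_total %% 2 != 0)
    stop("invalid config: strobed mode needs an even total frame count")
  if (bleach_tau <= 0) stop("invalid config: bleach_tau must be > 0")
  if (!all(state_block_spec$state %in% c("WAKE", "NREM", "REM")))
    stop("invalid config: unknown state label in state_block_spec")
  if (abs(sum(state_block_spec$duration) - duration) > 1e-9)
    stop("invalid config: state block durations must sum to duration")
  for (st in unique(state_block_spec$state)) {
    sp <- spontaneous_spec[[st]]
    if (is.null(sp) || sp$shared < 0 || sp$shared > 1)
      stop("invalid config: spontaneous_spec missing or shared outside [0,1] ",
           "for state ", st)
  }
  if (!is.null(evoked_spec)) {
    h <- image_shape[1]; w <- image_shape[2]
    for (nm in names(evoked_spec)) {
      ev <- evoked_spec[[nm]]
      if (ev$rise_s <= 0 || ev$decay_tau_s <= 0)
        stop("invalid config: evoked taus must be > 0")
      if (is.null(ev$contra_ipsi_ratio) || ev$contra_ipsi_ratio < 1)
        stop("invalid config: contra:ipsi ratio must be >= 1")
      for (roi in list(ev$roi_contra, ev$roi_ipsi)) {
        if (roi[1] < 2 || roi[1] > w - 1 || roi[2] < 2 || roi[2] > h - 1)
          stop("out of bounds: evoked ROI outside image")
      }
    }
  }
  structure(list(
    image_shape = image_shape, frame_rate_total = frame_rate_total,
    mode = mode, duration = duration, rng_seed = as.integer(rng_seed),
    bleach_tau = bleach_tau, noise_sd = noise_sd,
    reflectance_noise_sd = reflectance_noise_sd,
    hemo_sd = hemo_sd, hemo_band = hemo_band,
    hemo_alpha_map_params = hemo_alpha_map_params,
    evoked_spec = evoked_spec, state_block_spec = state_block_spec,
    spontaneous_spec = spontaneous_spec, stim_spec = stim_spec,
    f0_mean = f0_mean, f0_sd = f0_sd,
    pixel_size_um = 8600 / image_shape[2] * 1000 / 1000,
    n_total_frames = n_total
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$image_shape[1], "x", x$image_shape[2], " px, ",
      x$mode, " @ ", x$frame_rate_total, " Hz, ", x$duration, " s, seed ",
      x$rng_seed, "\n", sep = "")
  cat("  states:", paste(sprintf("%s(%gs)", x$state_block_spec$state,
                                 x$state_block_spec$duration),
                         collapse = " "), "\n")
  if (!is.null(x$stim_spec))
    cat("  stimuli:", x$stim_spec$n_trials, "trials, ISI",
        x$stim_spec$isi_s, "s\n")
  invisible(x)
}

#' Sensory-evoked scenario preset
#'
#' A stimulation session: 40 visual stimuli at 10-s inter-stimulus interval,
#' a contralateral VISp transient (peak ΔF/F 0.05, 100-ms latency, 100-ms
#' rise, 400-ms decay tau) with a weaker (ratio 2) and later (+50 ms)
#' ipsilateral homolog. Stimulus times sit on blue-frame boundaries
#' (frame-synchronous TTL triggering).
#'
#' @param n_trials,isi_s,first_s Stimulation schedule.
#' @param amplitude,latency_s,rise_s,decay_tau_s,contra_ipsi_ratio,latency_offset_s
#'   Evoked kinetics.
#' @param duration Session length (default fits the schedule plus padding).
#' @param ... Passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
evoked_scenario <- function(n_trials = 40, isi_s = 10, first_s = 5,
                            amplitude = 0.05, latency_s = 0.1, rise_s = 0.1,
                            decay_tau_s = 0.4, contra_ipsi_ratio = 2,
                            latency_offset_s = 0.05,
                            duration = first_s + n_trials * isi_s + 5, ...) {
  shape <- list(...)$image_shape
  if (is.null(shape)) shape <- c(64, 64)
  rois <- default_roi_table(shape, pixel_size_um = 8600 / shape[2])
  visp_r <- rois[rois$name == "VISp_R", ]
  visp_l <- rois[rois$name == "VISp_L", ]
  scenario_config(
    duration = duration,
    evoked_spec = list(visual = list(
      roi_contra = c(visp_r$x, visp_r$y), roi_ipsi = c(visp_l$x, visp_l$y),
      amplitude = amplitude, latency_s = latency_s, rise_s = rise_s,
      decay_tau_s = decay_tau_s, contra_ipsi_ratio = contra_ipsi_ratio,
      latency_offset_s = latency_offset_s)),
    state_block_spec = data.frame(state = "WAKE", duration = duration),
    stim_spec = list(n_trials = n_trials, isi_s = isi_s, pulse_s = 0.02,
                     first_s = first_s),
    ...)
}

#' Sleep-session scenario preset
#'
#' A 300-s spontaneous session with physiological state blocks
#' WAKE 60 s, NREM 90 s, REM 30 s, WAKE 60 s, NREM 60 s — 40% wake,
#' 50% NREM, 10% REM, the sleep-majority composition typical of
#' post-sleep-deprivation head-fixed recordings (and the regime the
#' percentile-based EMG auto-threshold of [score_states()] presumes).
#'
#' @param blocks Optional replacement state block data frame.
#' @param ... Passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
sleep_scenario <- function(blocks = data.frame(
                             state = c("WAKE", "NREM", "REM", "WAKE", "NREM"),
                             duration = c(60, 90, 30, 60, 60)), ...) {
  scenario_config(duration = sum(blocks$duration),
                  state_block_spec = blocks, ...)
}

# State label per time point from the block sequence (half-open blocks).
states_at <- function(times, blocks) {
  offs <- cumsum(blocks$duration)
  ons <- c(0, head(offs, -1))
  lab <- character(length(times))
  for (i in seq_len(nrow(blocks)))
    lab[times >= ons[i] & times < offs[i]] <- blocks$state[i]
  lab[times >= offs[length(offs)]] <- blocks$state[nrow(blocks)]
  lab
}

# Stimulus times snapped onto blue-frame boundaries.
stim_times_from_spec <- function(config) {
  ss <- config$stim_spec
  if (is.null(ss)) return(numeric(0))
  times <- ss$first_s + (seq_len(ss$n_trials) - 1) * ss$isi_s
  per_channel <- if (config$mode == "strobed_dual")
    config$frame_rate_total / 2 else config$frame_rate_total
  round(times * per_channel) / per_channel
}
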
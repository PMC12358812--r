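#' Process an EMG trace for motion detection
#'
#' Squares the EMG and median-filters the squared trace — a robust running
#' power envelope. The running median rejects single-sample artifacts while
#' never dipping inside a sustained movement burst, which keeps burst runs
#' contiguous for interval detection. (Median-filtering the *signed* EMG
#' before squaring would instead cancel the zero-mean carrier and leave a
#' heavy-tailed envelope.)
#'
#' @param emg Raw EMG trace.
#' @param rate Sampling rate, Hz.
#' @param median_window_s Median filter window, s (>= 3 samples).
#' @return Processed (squared, nonnegative) trace.
#' @export
process_emg <- function(emg, rate, median_window_s = 0.1) {
  k <- round(median_window_s * rate)
  if (k %% 2 == 0) k <- k + 1L
  if (k < 3) stop("median window must span at least 3 samples")
  if (k > length(emg)) stop("median window longer than trace")
  as.numeric(runmed(emg^2, k, endrule = "median"))
}

#' Detect movement periods from a processed EMG trace
#'
#' Maximal runs of samples strictly above the given percentile of the
#' processed trace. Runs shorter than `min_dur_s` are dropped first (the
#' percentile rule always marks ~`100 - percentile`% of samples, so brief
#' noise excursions are inevitable whenever movement occupies less time
#' than that; dropping them before gap closing keeps them from being merged
#' into spurious long intervals), then sub-`gap_s` gaps between surviving
#' runs are closed.
#'
#' @param processed Processed EMG (see [process_emg()]).
#' @param rate Sampling rate, Hz.
#' @param percentile Threshold percentile (default 95).
#' @param gap_s Close gaps shorter than this, s.
#' @param min_dur_s Drop runs shorter than this, s.
#' @return Class `motion_periods`: `intervals` (data frame `onset`,
#'   `offset`, half-open, s), `threshold_value`, `percentile_used`.
#' @export
detect_motion_periods <- function(processed, rate, percentile = 95,
                                  gap_s = 0.5, min_dur_s = 0.1) {
  if (length(processed) == 0) stop("empty trace")
  thr <- quantile(processed, percentile / 100, names = FALSE)
  runs <- logical_runs(processed > thr)
  iv <- if (nrow(runs) == 0)
    data.frame(onset = numeric(0), offset = numeric(0))
  else data.frame(onset = (runs[, 1] - 1) / rate, offset = runs[, 2] / rate)
  iv <- tidy_intervals(iv, gap = 0, min_len = min_dur_s)
  iv <- tidy_intervals(iv, gap = gap_s)
  structure(list(intervals = iv, threshold_value = thr,
                 percentile_used = percentile), class = "motion_periods")
}

#' Convert motion periods to a per-frame exclusion mask
#'
#' @param periods A `motion_periods` (or bare intervals data frame).
#' @param frame_times Imaging frame times, s (sorted).
#' @return Logical vector, `TRUE` where the frame falls inside any interval.
#' @export
periods_to_frame_mask <- function(periods, frame_times) {
  iv <- if (inherits(periods, "motion_periods")) periods$intervals
        else periods
  in_intervals(frame_times, iv)
}

#' Motion energy of a video block
#'
#' Mean absolute frame-to-frame pixel difference within an ROI block; the
#' first sample is 0 by convention.
#'
#' @param block `[frames, H, W]` array (an ROI crop of the behavioral
#'   video).
#' @return Motion-energy trace.
#' @export
motion_energy <- function(block) {
  d <- dim(block)
  if (is.null(d) || length(d) != 3L || prod(d[2:3]) == 0)
    stop("empty ROI block")
  if (d[1] < 2) stop("need at least 2 frames")
  m <- tp_view(block)
  c(0, rowMeans(abs(m[-1, , drop = FALSE] - m[-d[1], , drop = FALSE])))
}

#' Composite z-scored motion signal
#'
#' Each ROI trace is standardized (mean 0, sample sd 1) and the traces are
#' averaged pointwise; zero-variance traces are excluded with a warning.
#'
#' @param traces Matrix with one column per ROI (or a single trace).
#' @return Composite trace.
#' @export
composite_motion <- function(traces) {
  if (is.null(dim(traces))) traces <- matrix(traces, ncol = 1)
  sds <- apply(traces, 2, sd)
  keep <- sds > .Machine$double.eps
  if (!any(keep)) stop("all motion traces have zero variance")
  if (any(!keep))
    warning(sum(!keep), " zero-variance motion trace(s) excluded")
  z <- scale(traces[, keep, drop = FALSE])
  rowMeans(z)
}

#' Per-epoch hippocampal theta/delta power ratio
#'
#' Band power 5-10 Hz over band power 1-4 Hz per epoch, from a Welch
#' averaged periodogram ([welch_psd()]).
#'
#' @param lfp LFP trace.
#' @param rate Sampling rate, Hz.
#' @param epoch_s Epoch length, s (>= 2).
#' @param theta,delta Band edges, Hz.
#' @return Numeric ratio per epoch (`NA` where delta power is degenerate).
#' @export
theta_delta_ratio <- function(lfp, rate, epoch_s = 5,
                              theta = c(5, 10), delta = c(1, 4)) {
  if (epoch_s < 2) stop("epochs must be at least 2 s for stable delta power")
  n_ep <- floor(length(lfp) / (epoch_s * rate))
  vapply(seq_len(n_ep), function(i) {
    seg <- lfp[((i - 1) * epoch_s * rate + 1):(i * epoch_s * rate)]
    spec <- welch_psd(seg, rate, seg_s = 2)
    dp <- band_power(spec, delta[1], delta[2])
    if (dp < 1e-15) return(NA_real_)
    band_power(spec, theta[1], theta[2]) / dp
  }, 0)
}

#' Epoch-wise scoring features from EMG, LFP and motion
#'
#' @param emg,lfp Raw traces at `rate` Hz.
#' @param motion Motion-energy traces (matrix, one column per ROI) at
#'   `rate` Hz, or `NULL`.
#' @param rate Sampling rate, Hz.
#' @param epoch_s Epoch length, s.
#' @return Data frame `epoch_start_s`, `emg_power`, `theta_delta`,
#'   `motion_z`.
#' @export
epoch_features <- function(emg, lfp, motion = NULL, rate = 2000,
                           epoch_s = 5) {
  pe <- process_emg(emg, rate)
  n_ep <- floor(length(emg) / (epoch_s * rate))
  ep_of <- function(tr) vapply(seq_len(n_ep), function(i)
    mean(tr[((i - 1) * epoch_s * rate + 1):(i * epoch_s * rate)]), 0)
  comp <- if (is.null(motion)) rep(0, length(emg)) else
    composite_motion(motion)
  data.frame(epoch_start_s = (seq_len(n_ep) - 1) * epoch_s,
             emg_power = ep_of(pe),
             theta_delta = theta_delta_ratio(lfp, rate, epoch_s),
             motion_z = ep_of(comp))
}

#' Rule-based wake/NREM/REM scoring
#'
#' Per epoch: WAKE if EMG power or motion exceeds threshold; otherwise REM
#' if the theta/delta ratio is high, else NREM. Labels are then smoothed by
#' a 3-epoch majority vote (ties keep the centre label, so smoothing never
#' invents a label absent from the raw pass). Epochs with undefined
#' features are labelled UNSCORED and excluded downstream.
#'
#' Auto-thresholds (overridable): EMG at the 60th percentile of epoch EMG
#' power — which presumes a wake-majority session — theta/delta at 1.5,
#' motion at 1 z.
#'
#' @param features Data frame from [epoch_features()].
#' @param emg_thr,ratio_thr,motion_thr Numeric thresholds; `NULL` EMG
#'   threshold is derived from `emg_quantile`.
#' @param emg_quantile Quantile for the auto EMG threshold.
#' @param smooth Apply the 3-epoch majority smoothing.
#' @return Class `hypnogram`: the feature data frame plus `label`, with
#'   attributes `epoch_length_s` and `thresholds`.
#' @export
score_states <- function(features, emg_thr = NULL, ratio_thr = 1.5,
                         motion_thr = 1, emg_quantile = 0.6,
                         smooth = TRUE) {
  if (is.null(emg_thr))
    emg_thr <- quantile(features$emg_power, emg_quantile, names = FALSE)
  lab <- ifelse(features$emg_power >= emg_thr |
                  features$motion_z >= motion_thr, "WAKE",
                ifelse(features$theta_delta >= ratio_thr, "REM", "NREM"))
  lab[is.na(features$emg_power) | is.na(features$theta_delta)] <- "UNSCORED"
  if (smooth && length(lab) >= 3) {
    raw <- lab
    for (i in 2:(length(raw) - 1)) {
      trio <- raw[(i - 1):(i + 1)]
      tt <- table(trio)
      if (max(tt) >= 2) lab[i] <- names(tt)[which.max(tt)]
    }
  }
  ep_s <- if (nrow(features) > 1)
    features$epoch_start_s[2] - features$epoch_start_s[1] else NA_real_
  structure(cbind(features, label = lab),
            epoch_length_s = ep_s,
            thresholds = list(emg_thr = emg_thr, ratio_thr = ratio_thr,
                              motion_thr = motion_thr,
                              emg_quantile = emg_quantile),
            class = c("hypnogram", "data.frame"))
}

#' Ground-truth hypnogram from generator state blocks
#'
#' Epoch labels implied by a state block sequence (an epoch takes the state
#' occupying its midpoint).
#'
#' @param blocks Data frame `state`, `duration` (s).
#' @param epoch_s Epoch length, s.
#' @return Data frame `epoch_start_s`, `label`.
#' @export
hypnogram_from_blocks <- function(blocks, epoch_s = 5) {
  dur <- sum(blocks$duration)
  starts <- seq(0, dur - epoch_s, by = epoch_s)
  data.frame(epoch_start_s = starts,
             label = states_at(starts + epoch_s / 2, blocks))
}

#' Map imaging frames to hypnogram states
#'
#' @param hypnogram A `hypnogram` (or data frame `epoch_start_s`, `label`).
#' @param frame_times Frame times, s.
#' @param epoch_s Epoch length (taken from the hypnogram attribute if
#'   absent).
#' @return Character state per frame (`NA` outside scored epochs).
#' @export
frames_to_states <- function(hypnogram, frame_times, epoch_s = NULL) {
  if (is.null(epoch_s)) epoch_s <- attr(hypnogram, "epoch_length_s")
  idx <- floor(frame_times / epoch_s) + 1L
  out <- rep(NA_character_, length(frame_times))
  ok <- idx >= 1 & idx <= nrow(hypnogram)
  out[ok] <- as.character(hypnogram$label[idx[ok]])
  out
}
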
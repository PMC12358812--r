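#' Epoch a recording into stimulus-aligned trials
#'
#' Cuts `[-pre_s, +post_s]` windows around each stimulus time. Works on a
#' `dff_movie`, a bare `[frames, H, W]` stack, or a single ROI trace.
#' Trials whose window falls outside the recording are dropped (count
#' reported); trials overlapping supplied motion intervals are excluded the
#' same way.
#'
#' @param x `dff_movie`, 3D array, or numeric trace.
#' @param stim_times Stimulus times, s, on the blue-channel clock.
#' @param pre_s,post_s Window before/after the stimulus, s.
#' @param rate Sampling rate, Hz (taken from the `dff_movie` if absent).
#' @param frame_times Frame times (defaults to a regular grid at `rate`).
#' @param motion_periods Optional data frame `onset`/`offset` (s): trials
#'   overlapping any interval are excluded.
#' @return Class `trial_set`: `trials` (`[n, frames]` matrix or
#'   `[n, frames, H, W]` array), `stim_index` (frame of stimulus onset
#'   within the epoch), `pre_s`, `post_s`, `rate`, `epoch_times`,
#'   `n_dropped`, `n_motion_excluded`.
#' @export
epoch_trials <- function(x, stim_times, pre_s = 1, post_s = 3, rate = NULL,
                         frame_times = NULL, motion_periods = NULL) {
  if (inherits(x, "dff_movie")) {
    rate <- x$rate; frame_times <- x$frame_times; x <- x$dff
  }
  if (is.null(rate)) stop("rate is required")
  n_t <- if (is.null(dim(x))) length(x) else dim(x)[1]
  if (is.null(frame_times)) frame_times <- (seq_len(n_t) - 1) / rate
  npre <- round(pre_s * rate); npost <- round(post_s * rate)
  len <- npre + npost + 1L
  stim_idx_rec <- round((stim_times - frame_times[1]) * rate) + 1L
  usable <- stim_idx_rec - npre >= 1L & stim_idx_rec + npost <= n_t
  n_dropped <- sum(!usable)
  n_motion <- 0L
  if (!is.null(motion_periods) && nrow(motion_periods) > 0) {
    overlaps <- vapply(stim_times, function(s)
      any(motion_periods$onset < s + post_s &
            motion_periods$offset > s - pre_s), TRUE)
    n_motion <- sum(usable & overlaps)
    usable <- usable & !overlaps
  }
  if (!any(usable)) stop("zero usable trials after windowing/exclusion")
  keep <- which(usable)
  if (is.null(dim(x))) {
    trials <- t(vapply(keep, function(i) {
      s <- stim_idx_rec[i]
      x[(s - npre):(s + npost)]
    }, numeric(len)))
  } else {
    trials <- array(0, c(length(keep), len, dim(x)[2], dim(x)[3]))
    for (j in seq_along(keep)) {
      s <- stim_idx_rec[keep[j]]
      trials[j, , , ] <- x[(s - npre):(s + npost), , , drop = FALSE]
    }
  }
  structure(list(trials = trials, stim_index = npre + 1L, pre_s = pre_s,
                 post_s = post_s, rate = rate,
                 epoch_times = ((seq_len(len) - 1L) - npre) / rate,
                 stim_times_used = stim_times[keep],
                 n_dropped = n_dropped, n_motion_excluded = n_motion),
            class = "trial_set")
}

#' Subtract the pre-stimulus baseline from each trial
#'
#' The mean over the `pre_window_s` seconds before the stimulus (samples
#' with epoch time in `[-pre_window_s, 0)`) is removed per trial (and per
#' pixel for stack trials), so the pre-stimulus mean becomes exactly zero.
#'
#' @param ts A `trial_set`.
#' @param pre_window_s Baseline window length, s (default 1).
#' @return The `trial_set` with baseline-subtracted `trials`.
#' @export
baseline_subtract <- function(ts, pre_window_s = 1) {
  sel <- ts$epoch_times >= -pre_window_s & ts$epoch_times < 0
  if (!any(sel)) stop("empty pre-stimulus window")
  if (length(dim(ts$trials)) == 2L) {
    base <- rowMeans(ts$trials[, sel, drop = FALSE])
    ts$trials <- ts$trials - base
  } else {
    base <- apply(ts$trials[, sel, , , drop = FALSE], c(1, 3, 4), mean)
    d <- dim(ts$trials)
    for (i in seq_len(d[1]))
      ts$trials[i, , , ] <- ts$trials[i, , , ] -
        rep(base[i, , ], each = d[2])
  }
  ts$baseline_window_s <- pre_window_s
  ts
}

#' Trial average with SEM
#'
#' @param ts A `trial_set`.
#' @return List `mean`, `sem` (same shape as one trial; SEM uses the sample
#'   standard deviation, `NA` with `sem_defined = FALSE` for a single
#'   trial), `n_trials`.
#' @export
average_trials <- function(ts) {
  d <- dim(ts$trials)
  n <- d[1]
  if (length(d) == 2L) {
    mu <- colMeans(ts$trials)
    sem <- if (n > 1) apply(ts$trials, 2, sd) / sqrt(n) else
      rep(NA_real_, d[2])
  } else {
    mu <- apply(ts$trials, c(2, 3, 4), mean)
    sem <- if (n > 1) apply(ts$trials, c(2, 3, 4), sd) / sqrt(n) else
      array(NA_real_, d[2:4])
  }
  list(mean = mu, sem = sem, n_trials = n, sem_defined = n > 1,
       stim_index = ts$stim_index, rate = ts$rate,
       epoch_times = ts$epoch_times)
}

#' Mean trace over a square ROI
#'
#' Unweighted mean over a `size` x `size` pixel neighborhood (3x3 by
#' default, the ROI convention used throughout).
#'
#' @param x `dff_movie` or `[frames, H, W]` array.
#' @param center_xy `c(x, y)` pixel center (1-based).
#' @param size Odd neighborhood size.
#' @return Numeric trace (one value per frame).
#' @export
extract_roi_trace <- function(x, center_xy, size = 3) {
  if (inherits(x, "dff_movie")) x <- x$dff
  d <- dim(x); h <- d[2]; w <- d[3]
  half <- (size - 1) / 2
  cx <- center_xy[1]; cy <- center_xy[2]
  if (cx - half < 1 || cx + half > w || cy - half < 1 || cy + half > h)
    stop("ROI neighborhood extends beyond the image border at (",
         cx, ",", cy, ")")
  sub <- x[, (cy - half):(cy + half), (cx - half):(cx + half), drop = FALSE]
  rowMeans(tp_view(sub))
}

#' Evoked-response features from a trial-mean trace
#'
#' Peak amplitude is the maximum within the half-open 1-s post-stimulus
#' interval (the stimulus frame itself never counts); time-to-peak is the
#' earliest argmax; decay time is the first post-peak crossing of 50% of
#' the peak, located by linear interpolation between frames.
#'
#' @param trace Trial-mean trace.
#' @param rate Sampling rate, Hz.
#' @param stim_index Frame index of stimulus onset (1-based).
#' @param window_s Peak search window, s (default 1).
#' @return Data frame: `peak_amplitude`, `time_to_peak_ms`, `decay_time_ms`,
#'   `peak_valid`, `time_to_peak_valid`, `decay_valid`.
#' @export
response_features <- function(trace, rate, stim_index, window_s = 1) {
  n_win <- round(window_s * rate)
  win_idx <- (stim_index + 1L):min(stim_index + n_win, length(trace))
  win <- trace[win_idx]
  if (all(is.na(win))) stop("all-NaN post-stimulus window")
  pk_rel <- which.max(win)           # earliest maximum wins
  peak <- win[pk_rel]
  pk_idx <- win_idx[pk_rel]
  degenerate <- peak <= 0 || sd(win, na.rm = TRUE) < .Machine$double.eps
  ttp_ms <- (pk_idx - stim_index) / rate * 1000
  half <- peak / 2
  decay_ms <- NA_real_; decay_valid <- FALSE
  if (!degenerate && pk_idx < length(trace)) {
    post <- trace[pk_idx:length(trace)]
    below <- which(post <= half)
    below <- below[below > 1L]
    if (length(below) > 0) {
      j <- below[1L]
      y1 <- post[j - 1L]; y2 <- post[j]
      frac <- if (y1 != y2) (y1 - half) / (y1 - y2) else 0
      decay_ms <- ((j - 2L) + frac) / rate * 1000
      decay_valid <- TRUE
    }
  }
  data.frame(peak_amplitude = peak,
             time_to_peak_ms = ttp_ms,
             decay_time_ms = decay_ms,
             peak_valid = !all(is.na(win)),
             time_to_peak_valid = !degenerate,
             decay_valid = decay_valid)
}

#' Montage frames from a trial-average stack
#'
#' Pure view onto [average_trials()] output: the mean stack sampled at fixed
#' post-stimulus lags; nothing is recomputed.
#'
#' @param avg Result of [average_trials()] on stack trials.
#' @param lags_s Post-stimulus lags, s.
#' @return List of `[H, W]` matrices named by lag.
#' @export
montage_frames <- function(avg, lags_s = c(0.1, 0.2, 0.375, 0.5)) {
  stopifnot(length(dim(avg$mean)) == 3L)
  idx <- avg$stim_index + round(lags_s * avg$rate)
  idx <- pmin(pmax(idx, 1L), dim(avg$mean)[1])
  out <- lapply(idx, function(i) avg$mean[i, , ])
  names(out) <- sprintf("%g s", lags_s)
  out
}
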
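#' Remove a photobleaching baseline trend from an ROI trace
#'
#' Fits a mono-exponential-plus-offset trend `a * exp(-t/tau) + c` by
#' nonlinear least squares (Levenberg-Marquardt) and subtracts it; the
#' residual is re-centred so its median is zero. If the fit fails to
#' converge the fallback is a 60-s running-median subtraction (flagged in
#' the result). Pre- and post-drug sessions should be detrended
#' independently — a drug-elevated baseline would otherwise alias into the
#' trend.
#'
#' @param trace ROI trace (>= 60 s).
#' @param rate Sampling rate, Hz.
#' @return List: `detrended`, `trend`, `method`
#'   (`"exponential"`/`"running_median"`), `pars`.
#' @export
detrend_baseline <- function(trace, rate) {
  n <- length(trace)
  if (n < 60 * rate) stop("trace must be at least 60 s for detrending")
  t <- (seq_len(n) - 1) / rate
  dur <- t[n]
  a0 <- trace[1] - trace[n]
  c0 <- trace[n]
  fit <- try(minpack.lm::nlsLM(
    y ~ a * exp(-tt / tau) + c,
    data = data.frame(y = trace, tt = t),
    start = list(a = ifelse(abs(a0) > 0, a0, 1e-3), tau = dur / 2, c = c0),
    lower = c(a = -Inf, tau = dur / 100, c = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    trend <- predict(fit)
    method <- "exponential"
    pars <- as.list(coef(fit))
  } else {
    k <- round(60 * rate)
    if (k %% 2 == 0) k <- k + 1L
    trend <- runmed(trace, k, endrule = "median")
    method <- "running_median"
    pars <- list(window_s = 60)
    warning("exponential trend fit did not converge; ",
            "falling back to running-median detrend")
  }
  res <- trace - trend
  res <- res - median(res)
  list(detrended = res, trend = trend, method = method, pars = pars)
}

#' Detect spontaneous fluorescence transients
#'
#' Detection runs on a boxcar-smoothed copy of the detrended trace
#' (`smooth_s`, default 0.1 s). The threshold is `median + k * MAD`
#' (`k = 3`); events are maximal supra-threshold runs extended outward to
#' the surrounding half-threshold crossings, events separated by less than
#' `merge_gap_s` are merged, and events shorter than `min_dur_s` are
#' dropped (the smoothing and the duration floor together set the
#' false-event rate on pure noise below the design operating point of
#' 0.5/min). Peak amplitude and peak time are read from a *lighter*
#' smoothing (`amp_smooth_s`) relative to the detection baseline: heavy
#' smoothing stabilizes detection but attenuates sharp peaks, so the two
#' roles use different widths.
#'
#' @param detrended Detrended trace (see [detrend_baseline()]).
#' @param rate Sampling rate, Hz.
#' @param k MAD multiplier for the detection threshold.
#' @param smooth_s Boxcar width for detection, s.
#' @param amp_smooth_s Boxcar width for amplitude readout, s.
#' @param merge_gap_s Merge events closer than this, s.
#' @param min_dur_s Minimum (extended) event duration, s.
#' @return Data frame: `onset_s`, `duration_s`, `peak_time_s`,
#'   `peak_amplitude`; attributes `threshold`, `half_threshold`,
#'   `baseline`.
#' @export
detect_transients <- function(detrended, rate, k = 3, smooth_s = 0.1,
                              amp_smooth_s = 0.075, merge_gap_s = 0.2,
                              min_dur_s = 0.2) {
  n <- length(detrended)
  boxcar <- function(x, width_s) {
    w <- max(1L, round(width_s * rate))
    if (w %% 2 == 0) w <- w + 1L
    s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    half_w <- (w - 1) / 2
    if (half_w > 0) {   # fill filter edges by shrinking the window
      for (i in seq_len(half_w)) {
        s[i] <- mean(x[1:(i + half_w)])
        s[n - i + 1] <- mean(x[(n - i + 1 - half_w):n])
      }
    }
    s
  }
  sm <- boxcar(detrended, smooth_s)
  sm_amp <- boxcar(detrended, amp_smooth_s)
  base <- median(sm)
  scale <- mad(sm)
  if (scale < .Machine$double.eps) {
    out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_time_s = numeric(0), peak_amplitude = numeric(0))
    attr(out, "threshold") <- base
    return(out)
  }
  thr <- base + k * scale
  half_thr <- base + 0.5 * k * scale
  core <- logical_runs(sm > thr)
  above_half <- sm > half_thr
  events <- if (nrow(core) == 0)
    data.frame(onset = numeric(0), offset = numeric(0))
  else {
    ext <- t(apply(core, 1, function(run) {
      s <- run[1]; e <- run[2]
      while (s > 1 && above_half[s - 1]) s <- s - 1
      while (e < n && above_half[e + 1]) e <- e + 1
      c(s, e)
    }))
    data.frame(onset = (ext[, 1] - 1) / rate, offset = ext[, 2] / rate)
  }
  events <- tidy_intervals(events, gap = merge_gap_s, min_len = min_dur_s)
  if (nrow(events) == 0) {
    out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_time_s = numeric(0), peak_amplitude = numeric(0))
  } else {
    pk_t <- numeric(nrow(events)); pk_a <- numeric(nrow(events))
    for (i in seq_len(nrow(events))) {
      s <- round(events$onset[i] * rate) + 1L
      e <- min(round(events$offset[i] * rate), n)
      j <- s + which.max(sm_amp[s:e]) - 1L
      pk_t[i] <- (j - 1) / rate
      pk_a[i] <- sm_amp[j] - base
    }
    out <- data.frame(onset_s = events$onset,
                      duration_s = events$offset - events$onset,
                      peak_time_s = pk_t, peak_amplitude = pk_a)
  }
  attr(out, "threshold") <- thr
  attr(out, "half_threshold") <- half_thr
  attr(out, "baseline") <- base
  out
}

#' Summary statistics of detected transients
#'
#' @param events Event data frame from [detect_transients()].
#' @param usable_duration_s Usable recording duration, s (> 0).
#' @return List: `n_events`, `frequency_per_min`, `mean_duration_s`,
#'   `mean_peak_amplitude`.
#' @export
transient_stats <- function(events, usable_duration_s) {
  if (usable_duration_s <= 0) stop("usable duration must be positive")
  n <- nrow(events)
  list(n_events = n,
       frequency_per_min = n / (usable_duration_s / 60),
       mean_duration_s = if (n > 0) mean(events$duration_s) else 0,
       mean_peak_amplitude = if (n > 0) mean(events$peak_amplitude) else 0)
}

#' Paired pre/post comparison
#'
#' Per-subject differences and the classical paired t statistic
#' (mean difference over its standard error, df = n - 1).
#'
#' @param pre,post Per-subject values (equal length, matched order).
#' @return List: `differences`, `mean_difference`, `t`, `df`, `p_value`,
#'   `flag` (`"ok"`, `"too_few_subjects"`, `"zero_variance"`).
#' @export
paired_comparison <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre/post subject lists must match")
  d <- post - pre
  n <- length(d)
  if (n < 2)
    return(list(differences = d, mean_difference = mean(d), t = NA_real_,
                df = n - 1, p_value = NA_real_, flag = "too_few_subjects"))
  sdd <- sd(d)
  if (sdd < .Machine$double.eps) {
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(differences = d, mean_difference = mean(d), t = tval,
                df = n - 1, p_value = if (is.infinite(tval)) 0 else 1,
                flag = "zero_variance"))
  }
  tval <- mean(d) / (sdd / sqrt(n))
  list(differences = d, mean_difference = mean(d), t = tval, df = n - 1,
       p_value = 2 * pt(-abs(tval), n - 1), flag = "ok")
}
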
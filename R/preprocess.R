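#' De-interleave a strobed movie stack
#'
#' Splits an interleaved acquisition into its blue (fluorescence) and green
#' (reflectance) channels. With `channel_order = "blue_first"` the blue
#' channel occupies frames 1, 3, 5, ... (0-based even frames) and green the
#' other parity; frame times follow each channel's own clock.
#'
#' @param stack Interleaved `[frames, H, W]` array.
#' @param metadata Sidecar list with `mode`, `frame_rate_total`,
#'   `channel_order`.
#' @return List `blue`, `green`, `blue_times`, `green_times`.
#' @export
deinterleave <- function(stack, metadata) {
  if (metadata$mode != "strobed_dual")
    stop("deinterleave applies to strobed_dual movies only; ",
         "skip this step for continuous acquisitions")
  n <- dim(stack)[1]
  if (n %% 2 != 0)
    stop("strobed stack must have an even frame count (read_movie truncates)")
  fr <- metadata$frame_rate_total
  first_blue <- is.null(metadata$channel_order) ||
    metadata$channel_order == "blue_first"
  bi <- if (first_blue) seq(1L, n, 2L) else seq(2L, n, 2L)
  gi <- if (first_blue) seq(2L, n, 2L) else seq(1L, n, 2L)
  list(blue = stack[bi, , , drop = FALSE],
       green = stack[gi, , , drop = FALSE],
       blue_times = (bi - 1) / fr,
       green_times = (gi - 1) / fr)
}

#' Re-interleave two channels into acquisition order
#' @param blue,green `[frames, H, W]` channel stacks.
#' @param channel_order `"blue_first"` or `"green_first"`.
#' @return Interleaved `[2*frames, H, W]` array.
#' @export
reinterleave <- function(blue, green, channel_order = "blue_first") {
  stopifnot(all(dim(blue) == dim(green)))
  tb <- dim(blue)[1]
  out <- array(0, c(2 * tb, dim(blue)[2], dim(blue)[3]))
  if (channel_order == "blue_first") {
    out[seq(1, 2 * tb, 2), , ] <- blue; out[seq(2, 2 * tb, 2), , ] <- green
  } else {
    out[seq(1, 2 * tb, 2), , ] <- green; out[seq(2, 2 * tb, 2), , ] <- blue
  }
  out
}

#' Verify channel assignment against reference images
#'
#' Pixel-wise Pearson correlation of each stack's first frame with reference
#' images for each illumination wavelength; each stack is assigned to the
#' reference it correlates with more strongly, and a swap is flagged if the
#' assignments cross.
#'
#' @param first_frame_blue,first_frame_green First frames of the putative
#'   blue and green stacks (matrices).
#' @param reference_blue,reference_green Reference images.
#' @return List: `swap` (logical), `assignment`, `correlations` (2x2 matrix
#'   frames x references).
#' @export
verify_channel_assignment <- function(first_frame_blue, first_frame_green,
                                      reference_blue, reference_green) {
  frames <- list(blue = first_frame_blue, green = first_frame_green)
  refs <- list(blue = reference_blue, green = reference_green)
  for (nm in names(frames))
    if (sd(as.vector(frames[[nm]])) < .Machine$double.eps)
      stop("undefined correlation: zero-variance ", nm, " frame")
  for (nm in names(refs))
    if (sd(as.vector(refs[[nm]])) < .Machine$double.eps)
      stop("undefined correlation: zero-variance ", nm, " reference")
  cc <- matrix(NA_real_, 2, 2,
               dimnames = list(frame = c("blue", "green"),
                               reference = c("blue", "green")))
  for (i in 1:2) for (j in 1:2)
    cc[i, j] <- cor(as.vector(frames[[i]]), as.vector(refs[[j]]))
  pick <- apply(cc, 1, which.max)
  if (pick[1] == pick[2])
    stop("ambiguous assignment: both stacks match the same reference")
  swap <- pick[1] == 2L
  list(swap = swap,
       assignment = c(blue = colnames(cc)[pick[1]],
                      green = colnames(cc)[pick[2]]),
       correlations = cc)
}

#' Compute ΔF/F from an intensity stack
#'
#' ΔF/F(t) = (F(t) - F0) / F0 per pixel. The numerator baseline is always
#' the mean of this stack over the baseline window (so the baseline-window
#' mean of ΔF/F is exactly zero); the denominator defaults to the same map
#' but can be overridden with `f0_reference` — the pipeline passes the
#' *raw*-fluorescence baseline there when normalizing a hemodynamically
#' corrected stack, which keeps the ΔF/F scale of the original fluorophore
#' signal.
#'
#' @param stack `[frames, H, W]` intensity array.
#' @param baseline `list(mode = "session_mean")` or
#'   `list(mode = "pre_stimulus", window_s = 2, stim_time = <s>)`.
#' @param frame_times Frame times, s.
#' @param f0_reference Optional `[H, W]` denominator baseline map.
#' @param mask Optional logical `[H, W]` in-window mask.
#' @return Object of class `dff_movie`: `dff`, `f0_map`, `frame_times`,
#'   `rate`, `provenance`, `mask`.
#' @export
compute_dff <- function(stack, baseline = list(mode = "session_mean"),
                        frame_times = NULL, f0_reference = NULL,
                        mask = NULL) {
  d <- dim(stack); tb <- d[1]; h <- d[2]; w <- d[3]
  if (is.null(frame_times)) frame_times <- seq_len(tb) - 1
  if (baseline$mode == "session_mean") {
    bwin <- rep(TRUE, tb)
  } else if (baseline$mode == "pre_stimulus") {
    if (is.null(baseline$window_s)) baseline$window_s <- 2
    bwin <- frame_times >= baseline$stim_time - baseline$window_s &
      frame_times < baseline$stim_time
    if (!any(bwin)) stop("empty baseline window")
  } else stop("unknown baseline mode: ", baseline$mode)
  m <- tp_view(stack)
  base <- colMeans(m[bwin, , drop = FALSE])
  f0 <- if (is.null(f0_reference)) base else as.vector(f0_reference)
  bad <- f0 <= 0
  if (!is.null(mask)) bad <- bad & as.vector(mask)
  if (any(bad)) {
    warning(sum(bad), " pixel(s) with non-positive baseline masked out")
    f0[bad] <- NA_real_
  }
  dff <- (m - rep(base, each = tb)) / rep(f0, each = tb)
  rate <- if (tb > 1) 1 / median(diff(frame_times)) else NA_real_
  structure(list(
    dff = stack_view(dff, h, w),
    f0_map = matrix(if (is.null(f0_reference)) base else f0, h, w),
    frame_times = frame_times, rate = rate, mask = mask,
    provenance = list(baseline = baseline,
                      f0_source = if (is.null(f0_reference)) "stack_baseline"
                                  else "external_reference",
                      masked_pixels = sum(bad))),
    class = "dff_movie")
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$dff)
  cat("<dff_movie> ", d[1], " frames of ", d[2], "x", d[3], " px @ ",
      round(x$rate, 3), " Hz; baseline ", x$provenance$baseline$mode,
      if (isTRUE(x$provenance$corrected)) "; hemodynamics regressed out",
      "\n", sep = "")
  invisible(x)
}

#' Pixel-wise hemodynamic regression correction
#'
#' Ordinary least squares of the fluorescence trace on the (time-aligned)
#' reflectance trace, per pixel with intercept, over the full recording;
#' the corrected signal is the literal Fcorrected(t) = F(t) - alpha * R(t).
#' Pixels whose reflectance variance is below `var_floor` get alpha = 0 and
#' are flagged.
#'
#' @param f_stack Blue `[frames, H, W]` stack.
#' @param r_stack Reflectance stack resampled on the blue clock
#'   (see [align_channels()]); same dimensions.
#' @param var_floor Reflectance variance floor.
#' @return List: `corrected` stack and `fit` (class `hemodynamic_fit`:
#'   `alpha_map`, `intercept_map`, `r_squared_map`, `flagged`).
#' @export
hemodynamic_correct <- function(f_stack, r_stack, var_floor = 1e-12) {
  df <- dim(f_stack)
  if (!all(df == dim(r_stack)))
    stop("fluorescence and reflectance stacks must match after alignment")
  tb <- df[1]
  fm <- tp_view(f_stack); rm_ <- tp_view(r_stack)
  mf <- colMeans(fm); mr <- colMeans(rm_)
  sxy <- colSums(fm * rm_) - tb * mf * mr
  sxx <- colSums(rm_ * rm_) - tb * mr * mr
  syy <- colSums(fm * fm) - tb * mf * mf
  flagged <- sxx / tb < var_floor
  alpha <- ifelse(flagged, 0, sxy / sxx)
  intercept <- mf - alpha * mr
  r2 <- ifelse(flagged | syy <= 0, 0, pmin(1, (sxy^2) / (sxx * syy)))
  corrected <- fm - rm_ * rep(alpha, each = tb)
  fit <- structure(list(alpha_map = matrix(alpha, df[2], df[3]),
                        intercept_map = matrix(intercept, df[2], df[3]),
                        r_squared_map = matrix(r2, df[2], df[3]),
                        flagged = matrix(flagged, df[2], df[3])),
                   class = "hemodynamic_fit")
  list(corrected = stack_view(corrected, df[2], df[3]), fit = fit)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' response latencies are not phase-shifted. Accepts a vector, a matrix
#' (columns filtered independently) or a `[frames, H, W]` stack.
#'
#' @param x Input trace(s).
#' @param low_hz,high_hz Band edges, Hz; must satisfy
#'   `0 < low < high < rate/2`.
#' @param rate Sampling rate, Hz.
#' @param order Filter order (default 4).
#' @return Filtered object of the same shape.
#' @export
bandpass <- function(x, low_hz, high_hz, rate, order = 4) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < rate / 2))
    stop("band must satisfy 0 < low < high < rate/2 (Nyquist)")
  bf <- signal::butter(order, c(low_hz, high_hz) / (rate / 2), type = "pass")
  # removing the mean first keeps the forward-backward pass free of the
  # large edge transients a DC offset excites at very low normalized cutoffs
  filt1 <- function(v) signal::filtfilt(bf, v - mean(v))
  if (is.null(dim(x))) return(filt1(x))
  if (length(dim(x)) == 2L) {
    for (j in seq_len(ncol(x))) x[, j] <- filt1(x[, j])
    return(x)
  }
  d <- dim(x)
  m <- tp_view(x)
  for (j in seq_len(ncol(m))) m[, j] <- filt1(m[, j])
  stack_view(m, d[2], d[3])
}

#' Resample the green channel onto the blue frame clock
#'
#' Per-pixel linear interpolation of the reflectance series onto the blue
#' frame times; endpoints are held (the first blue frame precedes the first
#' green frame by half the total frame period).
#'
#' @param green_stack `[frames, H, W]` green stack.
#' @param green_times,blue_times Per-channel frame times, s.
#' @return Green stack resampled at `blue_times`.
#' @export
align_channels <- function(green_stack, green_times, blue_times) {
  if (max(blue_times) < min(green_times) ||
      min(blue_times) > max(green_times))
    stop("channel time ranges do not overlap")
  d <- dim(green_stack)
  g <- tp_view(green_stack)
  idx <- findInterval(blue_times, green_times)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, d[1])
  wt <- ifelse(hi > lo,
               (blue_times - green_times[lo]) /
                 (green_times[hi] - green_times[lo]), 0)
  wt <- pmin(pmax(wt, 0), 1)
  out <- g[lo, , drop = FALSE] * (1 - wt) + g[hi, , drop = FALSE] * wt
  stack_view(out, d[2], d[3])
}

#' Full preprocessing chain for one movie
#'
#' De-interleaves (strobed mode), aligns the reflectance channel to the blue
#' clock, regresses out hemodynamics (Fcorrected = F - alpha R), computes
#' ΔF/F (numerator baseline from the corrected stack, denominator from the
#' raw-fluorescence baseline so the ΔF/F scale is preserved), and band-pass
#' filters.
#'
#' @param movie A `dual_channel_movie`, or a list `stack` + `metadata` as
#'   returned by [read_movie()].
#' @param baseline Baseline spec, see [compute_dff()].
#' @param band `c(low, high)` Hz, or `NULL` to skip filtering (downstream
#'   stages that filter ROI traces themselves can skip the full-stack pass).
#' @param correct Apply hemodynamic regression (ignored when no green
#'   channel exists).
#' @return A `dff_movie` with `hemo_fit` attached when correction ran.
#' @export
preprocess_movie <- function(movie, baseline = list(mode = "session_mean"),
                             band = c(0.1, 5), correct = TRUE) {
  if (!inherits(movie, "dual_channel_movie")) {
    ch <- if (movie$metadata$mode == "strobed_dual")
      deinterleave(movie$stack, movie$metadata)
    else list(blue = movie$stack, green = NULL,
              blue_times = (seq_len(dim(movie$stack)[1]) - 1) /
                movie$metadata$frame_rate_total,
              green_times = numeric(0))
    movie <- structure(c(ch, list(metadata = movie$metadata)),
                       class = "dual_channel_movie")
  }
  f <- movie$blue
  rate <- movie$metadata$frame_rate_per_channel
  if (is.null(rate)) rate <- 1 / median(diff(movie$blue_times))
  fit <- NULL
  work <- f
  if (correct && !is.null(movie$green)) {
    r_al <- align_channels(movie$green, movie$green_times, movie$blue_times)
    hc <- hemodynamic_correct(f, r_al)
    work <- hc$corrected
    fit <- hc$fit
  }
  raw_f0 <- matrix(colMeans(tp_view(f)), dim(f)[2], dim(f)[3])
  dffm <- compute_dff(work, baseline = baseline,
                      frame_times = movie$blue_times,
                      f0_reference = raw_f0)
  if (!is.null(band))
    dffm$dff <- bandpass(dffm$dff, band[1], band[2], rate)
  dffm$rate <- rate
  dffm$hemo_fit <- fit
  dffm$metadata <- movie$metadata
  dffm$provenance <- c(dffm$provenance, list(
    corrected = !is.null(fit), filter_band_hz = band,
    filter = if (!is.null(band)) "butterworth4_zero_phase" else "none",
    alpha_fit_window = "full_recording"))
  dffm
}
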
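#' Seed-pixel correlation map
#'
#' Pearson correlation between every pixel's band-filtered trace and a seed
#' trace (the 3x3 neighborhood mean around the seed by default, mirroring
#' the ROI convention; `seed_size = 1` gives single-pixel mode, for which
#' the map value at the seed is exactly 1). Motion-masked frames are
#' excluded from the correlation.
#'
#' @param x `dff_movie` or `[frames, H, W]` array.
#' @param seed_xy `c(x, y)` seed center, pixels.
#' @param band `c(low, high)` Hz (default 0.1-5).
#' @param rate Sampling rate, Hz (from the `dff_movie` if absent).
#' @param frame_mask Logical per-frame exclusion mask (`TRUE` = excluded).
#' @param seed_size Seed neighborhood size (odd; 3 or 1).
#' @param min_frames Minimum usable frames (default 100).
#' @return `[H, W]` correlation map (`NA` at zero-variance pixels).
#' @export
seed_correlation_map <- function(x, seed_xy, band = c(0.1, 5), rate = NULL,
                                 frame_mask = NULL, seed_size = 3,
                                 min_frames = 100) {
  if (inherits(x, "dff_movie")) { rate <- x$rate; x <- x$dff }
  d <- dim(x)
  use <- if (is.null(frame_mask)) rep(TRUE, d[1]) else !frame_mask
  if (sum(use) < min_frames)
    stop("need at least ", min_frames, " unmasked frames")
  seed_trace <- extract_roi_trace(x, seed_xy, size = seed_size)
  if (!is.null(band)) {
    seed_trace <- bandpass(seed_trace, band[1], band[2], rate)
    x <- bandpass(x, band[1], band[2], rate)
  }
  m <- tp_view(x)[use, , drop = FALSE]
  st <- seed_trace[use]
  sds <- apply(m, 2, sd)
  map <- rep(NA_real_, ncol(m))
  ok <- sds > .Machine$double.eps
  map[ok] <- as.vector(cor(st, m[, ok]))
  out <- matrix(map, d[2], d[3])
  if (seed_size == 1) out[seed_xy[2], seed_xy[1]] <- 1
  out
}

#' ROI-pair Pearson correlation matrix
#'
#' Pairwise Pearson correlations among band-filtered 3x3-ROI traces over
#' unmasked frames.
#'
#' @param x `dff_movie` or `[frames, H, W]` array.
#' @param roi_table ROI table (see [default_roi_table()]).
#' @param band,rate,frame_mask,min_frames As in [seed_correlation_map()].
#' @return Symmetric correlation matrix with unit diagonal, dimnames = ROI
#'   names, attribute `frames_used`.
#' @export
roi_correlation_matrix <- function(x, roi_table, band = c(0.1, 5),
                                   rate = NULL, frame_mask = NULL,
                                   min_frames = 100) {
  if (inherits(x, "dff_movie")) { rate <- x$rate; x <- x$dff }
  validate_roi_table(roi_table, dim(x)[2:3])
  use <- if (is.null(frame_mask)) rep(TRUE, dim(x)[1]) else !frame_mask
  if (sum(use) < min_frames)
    stop("need at least ", min_frames, " unmasked frames")
  traces <- roi_trace_matrix(x, roi_table)
  if (!is.null(band)) traces <- bandpass(traces, band[1], band[2], rate)
  cm <- cor(traces[use, , drop = FALSE])
  dimnames(cm) <- list(roi_table$name, roi_table$name)
  attr(cm, "frames_used") <- sum(use)
  cm
}

roi_trace_matrix <- function(stack, roi_table, size = 3) {
  out <- matrix(0, dim(stack)[1], nrow(roi_table))
  colnames(out) <- roi_table$name
  for (i in seq_len(nrow(roi_table))) {
    tr <- try(extract_roi_trace(stack, c(roi_table$x[i], roi_table$y[i]),
                                size = size), silent = TRUE)
    if (inherits(tr, "try-error"))
      stop("ROI out of mask/border: ", roi_table$name[i])
    out[, i] <- tr
  }
  out
}

#' Mean interhemispheric (homotopic) correlation
#'
#' Mean Pearson r over homolog ROI pairs only (10 values for the default
#' table).
#'
#' @param cmat ROI correlation matrix (dimnames = ROI names).
#' @param roi_table ROI table with `homolog_name`.
#' @return Scalar mean r, with attribute `pair_r` (named per-pair values).
#' @export
interhemispheric_mean <- function(cmat, roi_table) {
  left <- roi_table[roi_table$hemisphere == "L", ]
  if (any(!left$homolog_name %in% rownames(cmat)) ||
      any(!left$name %in% rownames(cmat)))
    stop("missing homolog ROI in correlation matrix")
  pr <- vapply(seq_len(nrow(left)), function(i)
    cmat[left$name[i], left$homolog_name[i]], 0)
  names(pr) <- sub("_L$", "", left$name)
  structure(mean(pr), pair_r = pr)
}

#' Brain-state-resolved connectivity
#'
#' Assigns frames to vigilance states by hypnogram epoch membership, drops
#' motion-masked frames, filters ROI traces segment-wise (each contiguous
#' usable bout separately, so filter transients never bridge discontinuous
#' time), and computes per-state ROI correlation matrices and
#' interhemispheric means. States with fewer usable frames than
#' `min_frames` are skipped with a warning.
#'
#' @param x `dff_movie` or `[frames, H, W]` array.
#' @param hypnogram A `hypnogram` (or `NULL` for a single unconditioned
#'   result named "ALL").
#' @param roi_table ROI table.
#' @param band,rate Filter band (Hz) and sampling rate.
#' @param frame_times Frame times, s (from the `dff_movie` if absent).
#' @param frame_mask Per-frame exclusion mask (`TRUE` = excluded).
#' @param min_frames Minimum usable frames per state.
#' @param min_segment_s Segments shorter than this are not used (filter
#'   stability).
#' @return Named list of `connectivity_result` objects: `state`,
#'   `roi_matrix`, `interhemispheric_mean`, `frames_used`, `band`.
#' @export
state_resolved_connectivity <- function(x, hypnogram, roi_table,
                                        band = c(0.1, 5), rate = NULL,
                                        frame_times = NULL,
                                        frame_mask = NULL,
                                        min_frames = 100,
                                        min_segment_s = 2) {
  if (inherits(x, "dff_movie")) {
    rate <- x$rate; frame_times <- x$frame_times; x <- x$dff
  }
  n_t <- dim(x)[1]
  if (is.null(frame_times)) frame_times <- (seq_len(n_t) - 1) / rate
  states <- if (is.null(hypnogram)) rep("ALL", n_t) else
    frames_to_states(hypnogram, frame_times)
  usable <- !is.na(states) & states != "UNSCORED"
  if (!is.null(frame_mask)) usable <- usable & !frame_mask
  traces <- roi_trace_matrix(x, roi_table)
  results <- list()
  for (st in unique(states[usable])) {
    sel <- usable & states == st
    runs <- logical_runs(sel)
    keep <- runs[, 2] - runs[, 1] + 1 >= min_segment_s * rate
    runs <- runs[keep, , drop = FALSE]
    n_used <- if (nrow(runs)) sum(runs[, 2] - runs[, 1] + 1) else 0
    if (n_used < min_frames) {
      warning("state ", st, " skipped: only ", n_used, " usable frames")
      next
    }
    segs <- lapply(seq_len(nrow(runs)), function(i) {
      seg <- traces[runs[i, 1]:runs[i, 2], , drop = FALSE]
      if (!is.null(band)) bandpass(seg, band[1], band[2], rate) else seg
    })
    cat_tr <- do.call(rbind, segs)
    cm <- cor(cat_tr)
    dimnames(cm) <- list(roi_table$name, roi_table$name)
    results[[st]] <- structure(list(
      state = st, roi_matrix = cm,
      interhemispheric_mean = as.numeric(interhemispheric_mean(cm,
                                                               roi_table)),
      frames_used = n_used, band = band), class = "connectivity_result")
  }
  if (length(results) == 0)
    stop("no state has enough usable frames")
  results
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat("<connectivity_result> state ", x$state, ": ", nrow(x$roi_matrix),
      " ROIs, ", x$frames_used, " frames, interhemispheric mean r = ",
      round(x$interhemispheric_mean, 3), "\n", sep = "")
  invisible(x)
}

#' Spectral power of a regional GABA signal
#'
#' Welch averaged periodogram of an ROI trace (see [welch_psd()]); requires
#' at least 8 s of data.
#'
#' @param trace ROI trace.
#' @param rate Sampling rate, Hz.
#' @param seg_s Welch segment length, s.
#' @return List `freq`, `psd`.
#' @export
spectral_power <- function(trace, rate, seg_s = 4) {
  if (length(trace) < 8 * rate) stop("trace too short: need at least 8 s")
  welch_psd(trace, rate, seg_s = seg_s)
}
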
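#' Movie and analog-trace I/O
#'
#' Movies travel as multi-page TIFF (one page per acquired frame, interleaved
#' acquisition order preserved) plus a JSON sidecar. TIFF pages are stored as
#' 32-bit floats; because the writer stores values in `[0, 1]`, each file is
#' written with an affine intensity transform whose range is recorded in the
#' sidecar (`value_range`) and undone on read, so the round trip is exact to
#' float32 precision. Analog traces and stimulus times travel as CSV.
#'
#' @name movie_io
NULL

# Interleave a dual_channel_movie back into acquisition order [n_total,h,w].
interleave_movie <- function(movie) {
  if (is.null(movie$green)) return(movie$blue)
  tb <- dim(movie$blue)[1]
  h <- dim(movie$blue)[2]; w <- dim(movie$blue)[3]
  out <- array(0, c(2 * tb, h, w))
  out[seq(1, 2 * tb, 2), , ] <- movie$blue
  out[seq(2, 2 * tb, 2), , ] <- movie$green
  out
}

#' Write an interleaved movie stack as float32 TIFF + JSON sidecar
#'
#' @param movie A `dual_channel_movie` (see [simulate_movie()]) or a bare
#'   3D array with a `metadata` attribute-style list passed separately.
#' @param path TIFF output path.
#' @param sidecar_path JSON sidecar path (default: `path` with `.json`).
#' @return Invisibly, the sidecar list.
#' @export
write_movie <- function(movie, path, sidecar_path = sub("\\.tiff?$", ".json",
                                                        path)) {
  stack <- interleave_movie(movie)
  meta <- movie$metadata
  write_stack_tiff(stack, path, sidecar_path, meta)
}

write_stack_tiff <- function(stack, path, sidecar_path, meta) {
  if (any(!is.finite(stack))) {
    bad <- which(!is.finite(stack), arr.ind = TRUE)
    stop("refusing to write non-finite pixels: ", nrow(bad),
         " bad value(s), first at frame ", bad[1, 1],
         ", pixel (", bad[1, 2], ",", bad[1, 3], ")")
  }
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  n <- dim(stack)[1]
  pages <- lapply(seq_len(n), function(i) (stack[i, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta$n_frames <- n
  meta$image_shape <- dim(stack)[2:3]
  meta$value_range <- c(lo, lo + scale)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Read an interleaved movie stack and its sidecar metadata
#'
#' A strobed file whose page count disagrees with the sidecar is a format
#' error, except for a single trailing unpaired frame, which is dropped with
#' a warning (truncation policy for interrupted acquisitions).
#'
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path.
#' @return List: `stack` (interleaved `[frames, H, W]` array), `metadata`.
#' @export
read_movie <- function(path, sidecar_path = sub("\\.tiff?$", ".json", path)) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!meta$mode %in% c("strobed_dual", "continuous_blue"))
    stop("format error: unknown mode '", meta$mode, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- length(pages)
  expected <- meta$n_frames
  if (n != expected) {
    if (meta$mode == "strobed_dual" && n == expected - 1 && expected %% 2 == 0) {
      # fall through: handled as an odd on-disk count below
    } else {
      stop("format error: sidecar says ", expected, " frames, file has ", n)
    }
  }
  if (meta$mode == "strobed_dual" && n %% 2 == 1) {
    warning("odd frame count in strobed file; dropping final unpaired frame")
    pages <- pages[-n]
    n <- n - 1L
  }
  h <- dim(pages[[1]])[1]; w <- dim(pages[[1]])[2]
  vr <- meta$value_range
  if (is.null(vr)) vr <- c(0, 1)
  stack <- array(0, c(n, h, w))
  for (i in seq_len(n)) stack[i, , ] <- pages[[i]] * (vr[2] - vr[1]) + vr[1]
  meta$n_frames <- n
  list(stack = stack, metadata = meta)
}

#' Write a ΔF/F movie (float32 TIFF + sidecar with provenance)
#'
#' @param dff_movie A `dff_movie` (see [compute_dff()]).
#' @param path TIFF output path.
#' @param sidecar_path JSON sidecar path.
#' @return Invisibly, the sidecar list.
#' @export
write_dff <- function(dff_movie, path, sidecar_path = sub("\\.tiff?$",
                                                          ".json", path)) {
  meta <- c(dff_movie$metadata,
            list(provenance = dff_movie$provenance,
                 frame_rate = dff_movie$rate))
  if (is.null(meta$mode)) meta$mode <- "continuous_blue"
  write_stack_tiff(dff_movie$dff, path, sidecar_path, meta)
}

#' Read a ΔF/F movie written by [write_dff()]
#' @param path,sidecar_path File locations.
#' @return A `dff_movie`-like list with `dff`, `frame_times`, `provenance`.
#' @export
read_dff <- function(path, sidecar_path = sub("\\.tiff?$", ".json", path)) {
  got <- read_movie(path, sidecar_path)
  rate <- got$metadata$frame_rate
  structure(list(dff = got$stack,
                 frame_times = (seq_len(dim(got$stack)[1]) - 1) / rate,
                 rate = rate, f0_map = NULL,
                 provenance = got$metadata$provenance,
                 metadata = got$metadata), class = "dff_movie")
}

#' Analog-trace CSV I/O (EMG, LFP, motion energy)
#'
#' Columns `time_s`, `value` (one file per trace).
#'
#' @param trace Numeric vector.
#' @param rate Sampling rate, Hz.
#' @param path CSV path.
#' @param label Channel label ("emg", "lfp", "motion_roi", ...).
#' @return Invisibly `path`.
#' @export
write_analog_csv <- function(trace, rate, path, label = "analog") {
  if (rate <= 0) stop("sampling_rate must be > 0")
  if (any(!is.finite(trace))) stop("analog trace must be finite")
  df <- data.frame(time_s = (seq_along(trace) - 1) / rate, value = trace)
  attr(df, "label") <- label
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_analog_csv
#' @return `read_analog_csv`: list `trace`, `rate`, `times`.
#' @export
read_analog_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  dt <- diff(df$time_s)
  rate <- 1 / stats::median(dt)
  list(trace = df$value, rate = rate, times = df$time_s)
}

#' Stimulus-time CSV I/O (single column `stim_time_s`)
#' @param stim_times Numeric vector of stimulus times (s, blue-channel clock).
#' @param path CSV path.
#' @export
write_stim_csv <- function(stim_times, path) {
  write.csv(data.frame(stim_time_s = stim_times), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stim_csv
#' @export
read_stim_csv <- function(path) read.csv(path)$stim_time_s
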
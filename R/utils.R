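#' @importFrom stats rnorm runif fft approx median mad sd var cor quantile
#'   runmed coef nls.control predict t.test pt qt
#' @importFrom utils read.csv write.csv head tail
NULL

# Internal helpers shared across modules. Stacks are 3D arrays [frames, H, W];
# most numerics run on a frames x pixels matrix view (`tp_view`), which is a
# cheap dim-attribute change (column-major layout puts time fastest).

tp_view <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  dim(stack) <- c(d[1L], d[2L] * d[3L])
  stack
}

stack_view <- function(m, h, w) {
  stopifnot(ncol(m) == h * w)
  dim(m) <- c(nrow(m), h, w)
  m
}

#' Deterministic per-module seed fan-out
#'
#' One global seed is split into independent per-stage seeds so the outcome
#' of each stage does not depend on how many random draws earlier stages
#' consumed. The rule is `(seed * 101 + index) mod (2^31 - 512)`, with a
#' fixed index per stage name.
#'
#' @param seed Integer global seed.
#' @param module Stage name (character) or integer index.
#' @return An integer seed.
#' @export
split_seed <- function(seed, module) {
  idx <- if (is.character(module)) {
    known <- c(simulate = 1L, ephys = 2L, preprocess = 3L, evoked = 4L,
               states = 5L, connectivity = 6L, transients = 7L, io = 8L)
    i <- unname(known[module])
    if (is.na(i)) stop("unknown module name: ", module)
    i
  } else as.integer(module)
  as.integer((as.numeric(seed) * 101 + idx) %% (2^31 - 512))
}

# Band-limited Gaussian noise: white noise whose Fourier coefficients outside
# [lo, hi] Hz are zeroed, rescaled to unit sd. Used for the hemodynamic
# process, spontaneous cortical signals and LFP band components.
band_limited_noise <- function(n, fs, lo, hi) {
  x <- rnorm(n)
  f <- fft(x)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)    # two-sided, symmetric
  keep <- freqs >= lo & freqs <= hi
  f[!keep] <- 0+0i
  y <- Re(fft(f, inverse = TRUE)) / n
  s <- sd(y)
  if (s < .Machine$double.eps) return(rep(0, n))
  y / s
}

# Spatially smooth Gaussian random map (H x W) with given mean and sd.
# FFT convolution with a periodic Gaussian kernel, then standardized.
smooth_gain_map <- function(h, w, mean = 0, sd = 1, smoothness = 8) {
  z <- matrix(rnorm(h * w), h, w)
  if (smoothness > 0) {
    gy <- exp(-0.5 * (pmin(0:(h - 1), h - (0:(h - 1))) / smoothness)^2)
    gx <- exp(-0.5 * (pmin(0:(w - 1), w - (0:(w - 1))) / smoothness)^2)
    k <- outer(gy, gx)
    z <- Re(fft(fft(z) * fft(k / sum(k)), inverse = TRUE)) / (h * w)
  }
  z <- (z - mean(z)) / max(sd(as.vector(z)), .Machine$double.eps)
  mean + sd * z
}

#' Welch averaged periodogram
#'
#' Power spectral density by Welch's method: Hann-windowed segments with 50%
#' overlap, per-segment mean removal, one-sided density normalized so that
#' `sum(psd) * df` approximates the trace variance (Parseval).
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param seg_s Segment length in seconds (default 4, shortened if the trace
#'   is too short but never below 1 s).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 4) {
  n <- length(x)
  nper <- min(n, max(round(seg_s * fs), 8))
  step <- max(1L, floor(nper / 2))
  starts <- seq(1L, n - nper + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  u <- sum(win^2)
  nf <- floor(nper / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- abs(fft(seg))^2
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  mult <- rep(2, nf)
  mult[1L] <- 1
  if (nper %% 2 == 0) mult[nf] <- 1
  psd <- psd * mult
  list(freq = (seq_len(nf) - 1L) * fs / nper, psd = psd)
}

# Integrated band power from a welch_psd result.
band_power <- function(spec, lo, hi) {
  df <- spec$freq[2L] - spec$freq[1L]
  sum(spec$psd[spec$freq >= lo & spec$freq <= hi]) * df
}

# ---- half-open interval utilities [onset, offset) -----------------------

# Merge sorted intervals whose gaps are < gap; drop those shorter than min_len.
tidy_intervals <- function(intervals, gap = 0, min_len = 0) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  o <- order(intervals$onset)
  on <- intervals$onset[o]; off <- intervals$offset[o]
  m_on <- on[1L]; m_off <- off[1L]
  res_on <- numeric(0); res_off <- numeric(0)
  if (length(on) > 1L) for (i in 2L:length(on)) {
    if (on[i] - m_off < gap) {
      m_off <- max(m_off, off[i])
    } else {
      res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
      m_on <- on[i]; m_off <- off[i]
    }
  }
  res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
  keep <- (res_off - res_on) >= min_len
  data.frame(onset = res_on[keep], offset = res_off[keep])
}

in_intervals <- function(t, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (t >= intervals$onset[i] & t < intervals$offset[i])
  hit
}

# Maximal runs of TRUE in a logical vector -> two-column matrix of
# 1-based [start, end] sample indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
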
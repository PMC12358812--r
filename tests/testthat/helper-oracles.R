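# Independent oracles and small fixtures used across the suite.

# Two-pass Pearson correlation, written naively on purpose: the reference
# implementation against which every correlation output is checked.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

cor_matrix_oracle <- function(traces) {
  n <- ncol(traces)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- pearson_oracle(traces[, i], traces[, j])
  out
}

# Raw-periodogram band-power ratio (theta/delta), independent of welch_psd.
periodogram_ratio_oracle <- function(x, fs, theta = c(5, 10),
                                     delta = c(1, 4)) {
  n <- length(x)
  p <- abs(fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- seq_len(floor(n / 2))
  bp <- function(b) sum(p[keep][f[keep] >= b[1] & f[keep] <= b[2]])
  bp(theta) / bp(delta)
}

# Interval-set Jaccard index on a fine grid.
interval_jaccard <- function(a, b, dur, res = 1e-3) {
  t <- seq(0, dur - res, by = res) + res / 2
  ia <- mesogaba:::in_intervals(t, a)
  ib <- mesogaba:::in_intervals(t, b)
  sum(ia & ib) / sum(ia | ib)
}

# Small scenario presets used by several files.
tiny_cfg <- function(seed = 1, ...) {
  scenario_config(image_shape = c(12, 12), duration = 30, rng_seed = seed,
                  ...)
}

# Trial matrix of an injected evoked transient plus iid noise, the
# trace-level stand-in for a 3x3-ROI average over repeated stimulations.
make_trials <- function(seed, n_trials, rate = 40, amp = 0.05,
                        latency = 0.1, rise = 0.1, decay = 0.4,
                        noise_sd = 0.01 / 3, pre = 1, post = 3) {
  withr::with_seed(seed, {
    tt <- seq(-pre, post, by = 1 / rate)
    kin <- amp * mesogaba:::evoked_kinetic(tt, latency, rise, decay)
    trials <- matrix(rep(kin, each = n_trials), n_trials) +
      rnorm(n_trials * length(tt), 0, noise_sd)
    structure(list(trials = trials, stim_index = which(tt == 0),
                   pre_s = pre, post_s = post, rate = rate,
                   epoch_times = tt), class = "trial_set")
  })
}
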
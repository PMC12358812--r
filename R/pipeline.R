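#' Run the full analysis pipeline on a simulated session
#'
#' Executes the stages in dependency order — simulate, write raw data,
#' preprocess, evoked-response features (when a stimulation schedule
#' exists), sleep scoring, state-resolved connectivity, transient detection
#' — writing every table under `out_dir` together with a provenance JSON
#' holding the fully resolved configuration and per-stage seeds. Outputs are
#' byte-identical across runs with the same configuration and seed.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if missing).
#' @param band Analysis band, Hz; validated against the channel Nyquist
#'   before any computation.
#' @param epoch_s Scoring epoch length, s.
#' @param roi_table ROI table (default [default_roi_table()] for the scene
#'   geometry).
#' @param transient_roi ROI name whose trace feeds transient detection.
#' @param write_movie_files Also write the raw movie TIFF (large; off by
#'   default).
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir, band = c(0.1, 5), epoch_s = 5,
                         roi_table = NULL, transient_roi = "VISp_R",
                         write_movie_files = FALSE) {
  fs_b <- if (config$mode == "strobed_dual") config$frame_rate_total / 2
          else config$frame_rate_total
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < fs_b / 2))
    stop("validation: filter band outside (0, Nyquist) for ", fs_b,
         " Hz channel rate; nothing was run")
  if (is.null(roi_table))
    roi_table <- default_roi_table(config$image_shape,
                                   pixel_size_um = 8600 /
                                     config$image_shape[2])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[3]
    message("[", name, "] ...")
    out <- tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message("[", name, "] done in ", round(proc.time()[3] - t0, 1), " s")
    out
  }

  sim <- stage("simulate", simulate_movie(config))
  eph <- stage("ephys", simulate_ephys(config$state_block_spec, config))

  stage("write-inputs", {
    if (write_movie_files) {
      paths$movie <- file.path(out_dir, "movie.tif")
      write_movie(sim$movie, paths$movie)
    }
    paths$stim <- file.path(out_dir, "stim.csv")
    write_stim_csv(sim$truth$stim_times, paths$stim)
    paths$emg <- file.path(out_dir, "emg.csv")
    write_analog_csv(eph$emg, eph$rate, paths$emg, label = "emg")
    paths$lfp <- file.path(out_dir, "lfp.csv")
    write_analog_csv(eph$lfp, eph$rate, paths$lfp, label = "lfp")
    NULL
  })

  dffm <- stage("preprocess",
                preprocess_movie(sim$movie, band = NULL))

  motion <- stage("motion-exclusion", {
    pe <- process_emg(eph$emg, eph$rate)
    detect_motion_periods(pe, eph$rate)
  })
  frame_mask <- periods_to_frame_mask(motion, dffm$frame_times)

  feats <- NULL
  if (!is.null(config$stim_spec)) {
    feats <- stage("evoked", {
      rows <- lapply(seq_len(nrow(roi_table)), function(i) {
        tr <- extract_roi_trace(dffm, c(roi_table$x[i], roi_table$y[i]))
        tr <- bandpass(tr, band[1], band[2], fs_b)
        ts <- epoch_trials(tr, sim$truth$stim_times, pre_s = 1, post_s = 3,
                           rate = fs_b, frame_times = dffm$frame_times,
                           motion_periods = motion$intervals)
        ts <- baseline_subtract(ts, 1)
        avg <- average_trials(ts)
        cbind(data.frame(roi = roi_table$name[i],
                         n_trials = avg$n_trials),
              response_features(avg$mean, fs_b, ts$stim_index))
      })
      do.call(rbind, rows)
    })
    paths$features <- file.path(out_dir, "features.csv")
    write.csv(feats, paths$features, row.names = FALSE)
  }

  hyp <- stage("score-states", {
    fe <- epoch_features(eph$emg, eph$lfp, eph$motion, eph$rate, epoch_s)
    score_states(fe)
  })
  paths$hypnogram <- file.path(out_dir, "hypnogram.csv")
  write.csv(as.data.frame(hyp), paths$hypnogram, row.names = FALSE)

  conn <- stage("connectivity", {
    tryCatch(state_resolved_connectivity(dffm, hyp, roi_table, band = band,
                                         frame_mask = frame_mask),
             error = function(e) {
               message("  connectivity skipped: ", conditionMessage(e))
               NULL
             })
  })
  if (!is.null(conn)) {
    paths$connectivity <- file.path(out_dir, "connectivity_summary.json")
    summ <- lapply(conn, function(cr)
      list(interhemispheric_mean = cr$interhemispheric_mean,
           frames_used = cr$frames_used))
    jsonlite::write_json(summ, paths$connectivity, auto_unbox = TRUE,
                         digits = NA)
    for (st in names(conn)) {
      p <- file.path(out_dir, paste0("roi_matrix_", st, ".csv"))
      write.csv(conn[[st]]$roi_matrix, p)
      paths[[paste0("matrix_", st)]] <- p
    }
  }

  trans <- stage("transients", {
    ri <- which(roi_table$name == transient_roi)
    tr <- extract_roi_trace(dffm, c(roi_table$x[ri], roi_table$y[ri]))
    if (length(tr) >= 60 * fs_b) {
      det <- detrend_baseline(tr, fs_b)
      ev <- detect_transients(det$detrended, fs_b)
      list(events = ev,
           stats = transient_stats(ev, length(tr) / fs_b),
           detrend_method = det$method)
    } else {
      message("  trace shorter than 60 s; transient stage skipped")
      NULL
    }
  })
  if (!is.null(trans)) {
    paths$events <- file.path(out_dir, "events.csv")
    write.csv(trans$events, paths$events, row.names = FALSE)
    paths$transient_stats <- file.path(out_dir, "transient_stats.json")
    jsonlite::write_json(trans$stats, paths$transient_stats,
                         auto_unbox = TRUE, digits = NA)
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("mesogaba")),
    rng_seed = config$rng_seed,
    module_seeds = list(simulate = config$rng_seed,
                        ephys = split_seed(config$rng_seed, "ephys")),
    scenario = config[setdiff(names(config), c("evoked_spec"))],
    evoked_spec = config$evoked_spec,
    analysis = list(band_hz = band, epoch_s = epoch_s,
                    baseline_mode = "session_mean",
                    alpha_fit_window = "full_recording",
                    filter = "butterworth4_zero_phase",
                    transient_detector = list(k = 3, smooth_s = 0.1,
                                              merge_gap_s = 0.2,
                                              min_dur_s = 0.15)))
  paths$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)

  invisible(list(sim = sim, ephys = eph, dff = dffm, motion = motion,
                 features = feats, hypnogram = hyp, connectivity = conn,
                 transients = trans, paths = paths))
}
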
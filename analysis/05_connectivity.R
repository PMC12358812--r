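#!/usr/bin/env Rscript
# Stage 5 — brain-state-resolved connectivity of spontaneous GABA signals:
# seed-pixel correlation maps (0.1-5 Hz) and ROI correlation matrices per
# vigilance state, with interhemispheric (homotopic) means. Motion-masked
# frames are excluded; state bouts are filtered segment-wise.

suppressPackageStartupMessages(library(mesogaba))

raw <- read_movie("results/data/sleep_movie.tif")
dffm <- preprocess_movie(list(stack = raw$stack, metadata = raw$metadata),
                         band = NULL)
hyp <- read.csv("results/tables/hypnogram.csv")
attr(hyp, "epoch_length_s") <- 5
mp <- read.csv("results/tables/motion_periods.csv")
mask <- periods_to_frame_mask(mp, dffm$frame_times)
rois <- default_roi_table(c(32, 32), pixel_size_um = 8600 / 32)

conn <- state_resolved_connectivity(dffm, hyp, rois, frame_mask = mask)
for (st in names(conn)) {
  write.csv(conn[[st]]$roi_matrix,
            sprintf("results/tables/roi_matrix_%s.csv", st))
  message(sprintf("%-4s: interhemispheric mean r = %.3f (%d frames)",
                  st, conn[[st]]$interhemispheric_mean,
                  conn[[st]]$frames_used))
}
summ <- data.frame(state = names(conn),
                   interhemispheric_r = vapply(conn, function(x)
                     x$interhemispheric_mean, 0),
                   frames_used = vapply(conn, function(x)
                     as.numeric(x$frames_used), 0))
write.csv(summ, "results/tables/connectivity_summary.csv",
          row.names = FALSE)

# one seed map per state for the visual-cortex seed
visp <- rois[rois$name == "VISp_R", ]
states <- frames_to_states(hyp, dffm$frame_times, 5)
for (st in names(conn)) {
  sel <- !mask & !is.na(states) & states == st
  map <- seed_correlation_map(dffm$dff[sel, , , drop = FALSE],
                              c(visp$x, visp$y), rate = dffm$rate)
  write.csv(map, sprintf("results/tables/seed_map_VISp_%s.csv", st),
            row.names = FALSE)
}

# spectral power of the retrosplenial GABA signal per state
rsp <- rois[rois$name == "RSPagl_R", ]
tr <- extract_roi_trace(dffm, c(rsp$x, rsp$y))
spec_rows <- lapply(names(conn), function(st) {
  seg <- tr[!mask & !is.na(states) & states == st]
  sp <- spectral_power(seg, dffm$rate)
  data.frame(state = st, freq = sp$freq, psd = sp$psd)
})
write.csv(do.call(rbind, spec_rows), "results/tables/rsp_spectra.csv",
          row.names = FALSE)
message("wrote matrices, seed maps and spectra under results/tables/")
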
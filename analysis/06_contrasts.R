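#!/usr/bin/env Rscript
# Stage 6: between-microstate source contrasts.
#
# Paired t-tests over subjects between the source estimates of consecutive
# microstates, thresholded at t(19) >= 2.09 (p <= .05) with the
# strictly-greater-than-10-contiguous-points cluster-extent rule, in both
# directions.

suppressPackageStartupMessages(library(eegmicrostates))
out <- "results"

lf <- read_lead_field(file.path(out, "leadfield.rds"))
grid <- lf$grid
win_tab <- utils::read.table(file.path(out, "microstate_windows.tsv"),
                             header = TRUE, sep = "\t")
states <- sort(unique(win_tab$state))
# order states by their group-window latency
lat <- vapply(states, function(st)
  mean(range(win_tab[win_tab$state == st, c("start_ms", "end_ms")])),
  numeric(1))
states <- states[order(lat)]

rows <- list()
for (i in seq_len(length(states) - 1)) {
  a <- readRDS(file.path(out, sprintf("sources_state%d.rds", states[i + 1])))
  b <- readRDS(file.path(out, sprintf("sources_state%d.rds", states[i])))
  ct <- paired_t_contrast(a, b, grid, t_threshold = 2.09,
                          extent_threshold = 10)
  export_source_nifti(ct$t, grid,
                      file.path(out, sprintf("tmap_state%d_vs_state%d.nii.gz",
                                             states[i + 1], states[i])))
  message(sprintf("microstate %d vs %d: %d cluster(s)", states[i + 1],
                  states[i], length(ct$clusters)))
  for (cl in ct$clusters) {
    rows[[length(rows) + 1]] <- data.frame(
      later_state = states[i + 1], earlier_state = states[i],
      direction = cl$direction, size = cl$size, peak_t = cl$peak_t,
      x_mm = cl$peak_coordinate_mm[1], y_mm = cl$peak_coordinate_mm[2],
      z_mm = cl$peak_coordinate_mm[3])
    message(sprintf("  %s: %d points, peak t = %.2f at (%g, %g, %g) mm",
                    cl$direction, cl$size, cl$peak_t,
                    cl$peak_coordinate_mm[1], cl$peak_coordinate_mm[2],
                    cl$peak_coordinate_mm[3]))
  }
}
tab <- if (length(rows)) do.call(rbind, rows) else
  data.frame(later_state = integer(0), earlier_state = integer(0),
             direction = character(0), size = integer(0), peak_t = numeric(0),
             x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0))
utils::write.table(tab, file.path(out, "cluster_contrasts.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
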
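#!/usr/bin/env Rscript
# Stage 2: first-level preprocessing.
#
# Baseline-corrects each subject VEP over -100..0 ms, band-limits it (30 Hz
# low-pass leg of the nominal 1-30 Hz band; the high-pass period exceeds the
# epoch so drift removal is done by the baseline step), re-references to the
# average reference and normalizes to unit mean GFP over 0..500 ms, then
# forms the per-condition group averages.

suppressPackageStartupMessages(library(eegmicrostates))
out <- "results"

veps_raw <- read_dataset(file.path(out, "subject_veps_raw.rds"))
veps <- lapply(veps_raw, function(ev)
  rereference_and_normalize(baseline_and_bandpass(ev)))
for (v in veps) assert_pipeline_order(v)
write_dataset(veps, file.path(out, "subject_veps_preprocessed.rds"))

gv <- group_average_veps(veps)
write_dataset(gv, file.path(out, "group_veps.rds"))

gfp_tab <- do.call(rbind, lapply(names(gv), function(cond) {
  v <- gv[[cond]]
  data.frame(condition = cond, time_ms = v$times,
             gfp = gfp(v$data))
}))
utils::write.table(gfp_tab, file.path(out, "group_gfp.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
message(sprintf("preprocessed %d VEPs; group averages for: %s",
                length(veps), paste(names(gv), collapse = ", ")))
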
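#!/usr/bin/env Rscript
# Stage 1: build the forward model and simulate the group study.
#
# Emulates a 20-subject, 128-channel, 500 Hz visual event-related design with
# three hand-object-interaction conditions (use grip Ug, transport grip Tg,
# simple contact Sc) and a planted five-microstate schedule in which the
# third state is 10 ms shorter for simple contact. Writes the subject-level
# VEP dataset, the ground truth sidecar, and the electrode file.

suppressPackageStartupMessages(library(eegmicrostates))
seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

montage <- build_montage(128)
shell <- shell_model()
grid <- build_source_grid(6, shell)
lf <- compute_lead_field(montage, grid, shell, n_terms = 60)
message(sprintf("forward model: %d channels, %d solution points at %g mm",
                montage$n_channels, grid$n_points, grid$spacing_mm))

tm <- make_templates(lf, k = 5, seed = seed)
truth <- simulation_truth(tm$templates, default_schedule("no_context"),
                          seed = seed)
veps_raw <- simulate_subject_veps(truth, lf)

write_lead_field(lf, file.path(out, "leadfield.rds"))
write_sfp(montage, file.path(out, "montage.sfp"))
write_dataset(veps_raw, file.path(out, "subject_veps_raw.rds"))
# ground truth sidecar: never read by later stages, kept for scoring only
jsonlite::write_json(
  list(seed = truth$seed, n_subjects = truth$n_subjects,
       conditions = truth$conditions, noise_sd = truth$noise_sd,
       subject_jitter_ms = truth$subject_jitter_ms,
       schedule = truth$schedule,
       dipoles = tm$dipoles),
  file.path(out, "simulation_truth.json"), auto_unbox = TRUE, digits = NA)
saveRDS(tm$templates, file.path(out, "true_templates.rds"))

message(sprintf("simulated %d subject x condition VEPs (noise %g uV/trial, %d trials averaged)",
                length(veps_raw), truth$noise_sd, truth$n_epochs))
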
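#!/usr/bin/env Rscript
# Stage 4: back-fitting and duration statistics.
#
# Labels every sample of every subject's VEP inside each microstate's
# group-level window by the best-correlated template, aggregates durations,
# and tests each state's duration for a condition effect with a one-way
# repeated-measures ANOVA (subject as blocking factor).

suppressPackageStartupMessages(library(eegmicrostates))
out <- "results"

veps <- read_dataset(file.path(out, "subject_veps_preprocessed.rds"))
model <- readRDS(file.path(out, "microstate_model.rds"))
win_tab <- utils::read.table(file.path(out, "microstate_windows.tsv"),
                             header = TRUE, sep = "\t")
conds <- unique(win_tab$condition)

rows <- list()
anova_rows <- list()
for (st in sort(unique(win_tab$state))) {
  sub <- win_tab[win_tab$state == st, ]
  win <- c(min(sub$start_ms), max(sub$end_ms))
  lab <- lapply(veps, function(v) backfit(model$templates, v, win))
  rep_tab <- microstate_presence_report(lab)
  rep_tab$fit_state <- st
  rows[[as.character(st)]] <- rep_tab[rep_tab$microstate == st, ]
  dt <- durations_table(rep_tab, st, conditions = conds)
  an <- duration_anova(dt)
  anova_rows[[as.character(st)]] <- data.frame(
    state = st, window_start_ms = win[1], window_end_ms = win[2],
    F = an$F, df1 = an$df[1], df2 = an$df[2], p = an$p,
    t(an$means))
  message(sprintf("microstate %d (%d-%d ms): F(%d,%d) = %.2f, p = %.3g | %s",
                  st, win[1], win[2], an$df[1], an$df[2], an$F, an$p,
                  paste(sprintf("%s %.1f ms", names(an$means), an$means),
                        collapse = ", ")))
}

write_presence_tsv(do.call(rbind, rows), file.path(out, "durations_long.tsv"))
utils::write.table(do.call(rbind, anova_rows),
                   file.path(out, "duration_anovas.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
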
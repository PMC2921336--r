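# Shared fixtures, built once per test run. Small geometries keep the suite
# fast; the full 128-channel study geometry is only built where a check
# depends on it.

.fx <- new.env()

fx_small <- function() {
  # 32 channels, coarse 20-mm grid: cheap forward model for unit tests
  if (is.null(.fx$small)) {
    montage <- build_montage(32)
    shell <- shell_model()
    grid <- build_source_grid(20, shell)
    lf <- compute_lead_field(montage, grid, shell, n_terms = 40)
    .fx$small <- list(montage = montage, shell = shell, grid = grid, lf = lf)
  }
  .fx$small
}

fx_study <- function() {
  # the emulated study geometry at a 12-mm grid (the 6-mm default grid is
  # exercised through build_source_grid tests; analyses here don't need it)
  if (is.null(.fx$study)) {
    montage <- build_montage(128)
    shell <- shell_model()
    grid <- build_source_grid(12, shell)
    lf <- compute_lead_field(montage, grid, shell, n_terms = 60)
    .fx$study <- list(montage = montage, shell = shell, grid = grid, lf = lf)
  }
  .fx$study
}

fx_templates5 <- function() {
  if (is.null(.fx$tpl5)) {
    .fx$tpl5 <- make_templates(fx_study()$lf, k = 5, seed = 42)
  }
  .fx$tpl5
}

# preprocess a list of simulated subject VEPs with the default chain;
# filter = FALSE gives the noise-free variant (no band-pass)
preprocess_sim_veps <- function(veps, filter = TRUE) {
  lapply(veps, function(ev)
    rereference_and_normalize(
      baseline_and_bandpass(ev, band_hz = if (filter) c(1, 30) else NULL)))
}

# planted state of each 0..500 ms sample for one condition schedule
planted_state_at <- function(sched, t_ms) {
  vapply(t_ms, function(t)
    sched$state[sched$start_ms <= t & sched$end_ms >= t], integer(1))
}
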
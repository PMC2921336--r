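#' Pipeline configuration
#'
#' All parameters of the simulate -> preprocess -> segment -> fit -> sources
#' -> contrast chain, with defaults mirroring the emulated study: 128
#' channels at 500 Hz, 20 subjects, 100 µV rejection, -100..0 ms baseline,
#' 1-30 Hz band, 0-500 ms analysis window, t threshold 2.09 with extent > 10.
#'
#' @param seed master seed for all randomness.
#' @param design `"no_context"` (3 conditions, 5 states) or `"context"`.
#' @param n_channels,n_subjects,n_epochs study size.
#' @param noise_sd,noise_type,subject_jitter_ms,amplitude_uv,effect_ms
#'   generator parameters, see [simulation_truth()] and [default_schedule()].
#' @param epoch_level simulate single trials and run epoch-level
#'   preprocessing (slow, exercises the full first-level chain) or simulate
#'   subject VEPs directly (default).
#' @param threshold_uv,baseline_ms,band_hz first-level parameters.
#' @param k_range,min_duration_ms segmentation parameters.
#' @param grid_spacing_mm,n_terms forward-model parameters.
#' @param t_threshold,extent_threshold,alpha statistics parameters.
#' @param run_sources estimate sources and contrasts (the slowest stage).
#' @param out_dir where intermediates and the report are written (`NULL`:
#'   nothing persisted).
#' @return a validated config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, design = "no_context",
                            n_channels = 128L, n_subjects = 20L,
                            n_epochs = 60L, noise_sd = 15,
                            noise_type = "correlated",
                            subject_jitter_ms = 6, amplitude_uv = 8,
                            effect_ms = 10, epoch_level = FALSE,
                            threshold_uv = 100, baseline_ms = c(-100, 0),
                            band_hz = c(1, 30), k_range = 2:12,
                            min_duration_ms = 10, grid_spacing_mm = 6,
                            n_terms = 60L, t_threshold = 2.09,
                            extent_threshold = 10, alpha = 0.05,
                            run_sources = TRUE, out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), design = design,
              n_channels = as.integer(n_channels),
              n_subjects = as.integer(n_subjects),
              n_epochs = as.integer(n_epochs), noise_sd = noise_sd,
              noise_type = noise_type,
              subject_jitter_ms = subject_jitter_ms,
              amplitude_uv = amplitude_uv, effect_ms = effect_ms,
              epoch_level = isTRUE(epoch_level),
              threshold_uv = threshold_uv, baseline_ms = baseline_ms,
              band_hz = band_hz, k_range = as.integer(k_range),
              min_duration_ms = min_duration_ms,
              grid_spacing_mm = grid_spacing_mm, n_terms = as.integer(n_terms),
              t_threshold = t_threshold,
              extent_threshold = as.integer(extent_threshold), alpha = alpha,
              run_sources = isTRUE(run_sources), out_dir = out_dir)
  stopifnot(cfg$threshold_uv > 0, cfg$noise_sd >= 0, cfg$n_subjects >= 2,
            cfg$grid_spacing_mm > 0, cfg$t_threshold > 0,
            cfg$extent_threshold >= 0, length(cfg$k_range) >= 2)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline config as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$out_dir <- raw$out_dir %||% NULL
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# content hash of the canonical JSON serialization of the config; output
# paths are excluded so the same scientific configuration hashes identically
# wherever it is run
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates forward-model construction, group simulation, first-level
#' preprocessing, microstate segmentation, back-fitting with duration ANOVAs,
#' and (optionally) source estimation with consecutive-microstate paired-t
#' cluster contrasts. Identical config and seed give identical reports.
#'
#' @param config a [pipeline_config()].
#' @param leadfield optionally, a precomputed lead field to reuse.
#' @return a run report (list) with selected k, per-condition windows,
#'   duration tables and ANOVA results, density maxima and cluster tables,
#'   and provenance (config hash, seed, solution-point count). If
#'   `config$out_dir` is set, intermediates and `report.json` are written
#'   there.
#' @export
run_pipeline <- function(config, leadfield = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  # --- forward model -------------------------------------------------------
  if (is.null(leadfield)) {
    montage <- build_montage(config$n_channels)
    shell <- shell_model()
    grid <- build_source_grid(config$grid_spacing_mm, shell)
    leadfield <- compute_lead_field(montage, grid, shell, config$n_terms)
  }
  grid <- leadfield$grid
  # --- simulate ------------------------------------------------------------
  schedule <- default_schedule(config$design, config$effect_ms)
  k_true <- max(vapply(schedule, function(s) max(s$state), integer(1)))
  tmpl <- make_templates(leadfield, k = k_true, seed = config$seed)
  truth <- simulation_truth(tmpl$templates, schedule,
                            n_subjects = config$n_subjects,
                            n_epochs = config$n_epochs,
                            noise_sd = config$noise_sd,
                            noise_type = config$noise_type,
                            subject_jitter_ms = config$subject_jitter_ms,
                            amplitude_uv = config$amplitude_uv,
                            seed = config$seed)
  # --- first level ---------------------------------------------------------
  if (config$epoch_level) {
    datasets <- simulate_group(truth, leadfield)
    veps <- lapply(datasets, function(es)
      preprocess_vep(es, threshold_uv = config$threshold_uv,
                     baseline_ms = config$baseline_ms,
                     band_hz = config$band_hz))
  } else {
    raw <- simulate_subject_veps(truth, leadfield)
    veps <- lapply(raw, function(ev) {
      ev <- baseline_and_bandpass(ev, config$baseline_ms, config$band_hz)
      rereference_and_normalize(ev)
    })
  }
  group <- group_average_veps(veps)
  # --- segmentation --------------------------------------------------------
  model <- select_k(group, k_range = config$k_range)
  windows <- extract_windows(model, group,
                             min_duration_ms = config$min_duration_ms)
  # group-level state windows pooled over conditions (earliest start to
  # latest end per state) define the per-state fit and source windows
  state_windows <- pooled_state_windows(windows)
  # --- back-fitting and duration statistics --------------------------------
  labelings <- list()
  for (state in names(state_windows)) {
    win <- state_windows[[state]]
    for (nm in names(veps))
      labelings[[paste(state, nm, sep = "_")]] <-
        backfit(model$templates, veps[[nm]], win)
  }
  anovas <- list()
  duration_means <- list()
  conds <- names(group)
  for (state in names(state_windows)) {
    sel <- labelings[grep(paste0("^", state, "_"), names(labelings))]
    rep_tab <- microstate_presence_report(sel)
    dt <- durations_table(rep_tab, as.integer(sub("state", "", state)),
                          conditions = conds)
    if (!anyNA(dt)) {
      an <- duration_anova(dt)
      anovas[[state]] <- list(F = an$F, df = an$df, p = an$p,
                              means = as.list(an$means),
                              sds = as.list(an$sds))
      duration_means[[state]] <- as.list(an$means)
    }
  }
  # --- sources -------------------------------------------------------------
  maxima <- list()
  contrast_tables <- list()
  if (config$run_sources) {
    inv <- build_inverse(leadfield)
    subj_est <- list()
    for (state in names(state_windows)) {
      win <- state_windows[[state]]
      # group-average estimate for the report's density maximum
      gm <- Reduce(`+`, lapply(group, function(v) v$data)) / length(group)
      gev_ev <- evoked(gm, group[[1]]$times, condition = "all",
                       subject = "group")
      est <- estimate_sources(inv, gev_ev, win)
      mx <- report_density_maximum(est)
      maxima[[state]] <- list(coordinate_mm = as.numeric(mx$coordinate_mm),
                              value = mx$value)
      subj_est[[state]] <- do.call(rbind, lapply(
        veps[grep("\\.", names(veps))], function(v) {
          # average densities across conditions per subject
          estimate_sources(inv, v, win)$density
        }))
      # average within subject across conditions
      subj_ids <- vapply(veps, function(v) as.character(v$subject),
                         character(1))
      m <- subj_est[[state]]
      subj_est[[state]] <- do.call(rbind, lapply(unique(subj_ids), function(s)
        colMeans(m[subj_ids == s, , drop = FALSE])))
    }
    states <- names(state_windows)
    for (i in seq_len(length(states) - 1)) {
      ct <- paired_t_contrast(subj_est[[states[i + 1]]],
                              subj_est[[states[i]]], grid,
                              t_threshold = config$t_threshold,
                              extent_threshold = config$extent_threshold)
      contrast_tables[[paste(states[i + 1], "vs", states[i])]] <-
        lapply(ct$clusters, function(cl)
          list(direction = cl$direction, size = cl$size,
               peak_t = cl$peak_t,
               peak_coordinate_mm = as.numeric(cl$peak_coordinate_mm)))
    }
  }
  report <- list(
    selected_k = model$k,
    gev = model$gev,
    windows = lapply(windows, function(w)
      lapply(seq_len(nrow(w)), function(i) as.list(w[i, ]))),
    state_windows = state_windows,
    duration_anovas = anovas,
    density_maxima = maxima,
    contrasts = contrast_tables,
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      n_solution_points = grid$n_points,
                      grid_spacing_mm = grid$spacing_mm,
                      package_version = as.character(
                        utils::packageVersion("eegmicrostates"))))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  report
}

# pool per-condition windows of each state into one group-level window per
# state: earliest start to latest end across conditions
pooled_state_windows <- function(windows) {
  states <- sort(unique(unlist(lapply(windows, function(w) w$state))))
  out <- list()
  for (s in states) {
    st <- en <- NULL
    for (w in windows) {
      rows <- w[w$state == s, ]
      if (nrow(rows)) {
        st <- min(st, min(rows$start_ms))
        en <- max(en, max(rows$end_ms))
      }
    }
    out[[paste0("state", s)]] <- c(st, en)
  }
  out
}

#' Lossless dataset persistence with schema validation
#'
#' Writes an epoch set or evoked (or a list of them) to an RDS container with
#' a JSON sidecar describing the schema. Reading validates required fields
#' and errors naming the first missing one.
#'
#' @param data epoch_set / evoked / list of them.
#' @param path output path (.rds).
#' @export
write_dataset <- function(data, path) {
  saveRDS(data, path)
  describe <- function(x)
    list(class = class(x)[1],
         fields = names(x))
  meta <- if (inherits(data, c("epoch_set", "evoked"))) describe(data)
          else lapply(data, describe)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  data <- readRDS(path)
  check_one <- function(x) {
    required <- if (inherits(x, "epoch_set"))
      c("subject", "condition", "data", "sfreq", "times", "t0_index")
    else if (inherits(x, "evoked"))
      c("data", "times", "condition", "subject", "n_epochs_averaged")
    else stop("container holds neither epoch_set nor evoked", call. = FALSE)
    missing <- setdiff(required, names(x))
    if (length(missing))
      stop(sprintf("dataset container missing required field \"%s\"",
                   missing[1]), call. = FALSE)
    invisible(TRUE)
  }
  if (inherits(data, c("epoch_set", "evoked"))) check_one(data)
  else lapply(data, check_one)
  data
}
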
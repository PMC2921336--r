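#' Default microstate schedules
#'
#' Per-condition ground-truth schedules for the simulator, expressed as closed
#' intervals in ms on the 2-ms sampling lattice (0..500 ms). The "no_context"
#' schedule has five states shared by the three grip/contact conditions
#' (Ug, Tg, Sc), with the third state 10 ms shorter for simple contact (Sc) —
#' the condition-dependent duration effect the duration statistics are meant
#' to detect. The "context" schedule has seven states across four conditions
#' (U, T, Usc, Tsc): a state present only for grasping (U, T) at 210-230 ms
#' and a condition-specific final state for U.
#'
#' @param design `"no_context"` or `"context"`.
#' @param effect_ms size of the condition-dependent shortening of the third
#'   state in the no-context design (default 10 ms; 0 gives a null design).
#' @return named list: per condition, a data.frame with columns
#'   `state`, `start_ms`, `end_ms`.
#' @export
default_schedule <- function(design = c("no_context", "context"),
                             effect_ms = 10) {
  design <- match.arg(design)
  win <- function(state, start, end) data.frame(state = state, start_ms = start,
                                                end_ms = end)
  if (design == "no_context") {
    base <- rbind(win(1L, 0, 120), win(2L, 122, 200), win(3L, 202, 230),
                  win(4L, 232, 320), win(5L, 322, 500))
    sc <- base
    sc$end_ms[3] <- 230 - effect_ms
    sc$start_ms[4] <- 232 - effect_ms
    list(Ug = base, Tg = base, Sc = sc)
  } else {
    common <- rbind(win(1L, 0, 120), win(2L, 122, 170), win(3L, 172, 208))
    grasp <- rbind(common, win(4L, 210, 230), win(5L, 232, 280))
    touch <- rbind(common, win(5L, 210, 280))
    list(U   = rbind(grasp, win(6L, 282, 500)),
         T   = rbind(grasp, win(7L, 282, 500)),
         Usc = rbind(touch, win(7L, 282, 500)),
         Tsc = rbind(touch, win(7L, 282, 500)))
  }
}

#' Evenly spaced k-state schedule
#'
#' Splits the 0..500 ms analysis window into `k` near-equal microstate
#' windows on the 2-ms lattice, for planted-model recovery studies at
#' arbitrary k.
#'
#' @param k number of states.
#' @param conditions condition labels (default a single condition "A").
#' @return named schedule list as in [default_schedule()].
#' @export
uniform_schedule <- function(k, conditions = "A") {
  edges <- round(seq(0, 500, length.out = k + 1) / 2) * 2
  sched <- data.frame(state = seq_len(k),
                      start_ms = c(edges[1], edges[-c(1, k + 1)] + 2),
                      end_ms = edges[-1])
  stats::setNames(rep(list(sched), length(conditions)), conditions)
}

validate_schedule <- function(schedule, k) {
  for (cond in names(schedule)) {
    s <- schedule[[cond]]
    if (any(s$state < 1 | s$state > k))
      stop(sprintf("schedule for %s references a nonexistent template", cond),
           call. = FALSE)
    if (any(s$start_ms < 0) || any(s$end_ms > 500))
      stop("schedule windows must lie within 0..500 ms", call. = FALSE)
    if (any(s$end_ms < s$start_ms))
      stop("schedule windows must have end >= start", call. = FALSE)
    if (nrow(s) > 1 && any(s$start_ms[-1] <= s$end_ms[-nrow(s)]))
      stop("schedule windows must be ordered and non-overlapping", call. = FALSE)
  }
  invisible(schedule)
}

#' Generate mutually distinguishable template topographies
#'
#' Each template is the scalp projection (through the lead field) of 1-3
#' dipoles placed at mid-depth, normalized to unit GFP. Templates are retried
#' until all pairwise absolute spatial correlations are at most `max_corr`.
#'
#' @param leadfield a [compute_lead_field()] result.
#' @param k number of templates (>= 2).
#' @param seed integer seed; fixed seed gives identical templates.
#' @param max_corr pairwise |spatial correlation| bound (default 0.7).
#' @param max_tries retries per template before giving up.
#' @return list with `templates` (channels x k, unit GFP, average-referenced)
#'   and `dipoles` (per template: data.frame of grid point index and moment).
#' @export
make_templates <- function(leadfield, k, seed = 1L, max_corr = 0.7,
                           max_tries = 200L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  grid <- leadfield$grid
  brain_r <- leadfield$shell$radii_mm[1]
  depth <- sqrt(rowSums(grid$points^2)) / brain_r
  eligible <- which(depth >= 0.25 & depth <= 0.8)
  if (length(eligible) < k) stop("source grid too small for template generation",
                                 call. = FALSE)
  templates <- matrix(0, nrow(leadfield$gain), k)
  dipoles <- vector("list", k)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      nd <- sample(1:3, 1)
      idx <- sample(eligible, nd)
      mom <- matrix(stats::rnorm(3 * nd), nd, 3)
      v <- project_dipoles(leadfield, idx, mom)
      g <- gfp(v)
      if (g < 1e-12) next
      v <- v / g
      if (j == 1) {
        sep <- TRUE
      } else {
        sep <- all(abs(crossprod(center_map(v),
                                 center_maps(templates[, seq_len(j - 1), drop = FALSE])) /
                       (norm2(center_map(v)) *
                        apply(center_maps(templates[, seq_len(j - 1), drop = FALSE]),
                              2, norm2))) <= max_corr)
      }
      if (sep) {
        templates[, j] <- v
        dipoles[[j]] <- data.frame(point = idx, mx = mom[, 1], my = mom[, 2],
                                   mz = mom[, 3])
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not generate sufficiently separated templates",
                  call. = FALSE)
  }
  list(templates = templates, dipoles = dipoles)
}

#' Ground truth for a simulated group study
#'
#' Bundles everything the generator needs: template maps, per-condition
#' microstate schedule, group size, epoch counts, noise level and structure,
#' per-subject boundary jitter, and the master seed. The defaults are the
#' emulated study's conditions: 20 subjects, 500 Hz, -100..500 ms epochs,
#' 60 retained epochs per condition, 15 µV single-trial noise with smooth
#' spatial correlation, 6 ms boundary jitter, 8 µV peak signal amplitude.
#'
#' @param templates channels x k matrix of unit-GFP average-referenced maps.
#' @param schedule per-condition window list as from [default_schedule()].
#' @param n_subjects number of subjects (default 20).
#' @param n_epochs epochs per condition per subject (default 60).
#' @param noise_sd single-trial noise SD in µV (default 15).
#' @param noise_type `"correlated"` (smooth spatial covariance, default) or
#'   `"white"`.
#' @param subject_jitter_ms half-range of the uniform per-subject shift of
#'   interior window boundaries, in ms (default 6).
#' @param amplitude_uv peak amplitude of the half-sine envelope, µV (default 8).
#' @param seed master seed; all randomness flows from it.
#' @return object of class `"simulation_truth"`.
#' @export
simulation_truth <- function(templates, schedule = default_schedule(),
                             n_subjects = 20L, n_epochs = 60L, noise_sd = 15,
                             noise_type = c("correlated", "white"),
                             subject_jitter_ms = 6, amplitude_uv = 8,
                             seed = 1L) {
  noise_type <- match.arg(noise_type)
  validate_schedule(schedule, ncol(templates))
  structure(list(templates = templates, schedule = schedule,
                 n_subjects = as.integer(n_subjects),
                 conditions = names(schedule),
                 n_epochs = as.integer(n_epochs), noise_sd = noise_sd,
                 noise_type = noise_type,
                 subject_jitter_ms = subject_jitter_ms,
                 amplitude_uv = amplitude_uv, seed = as.integer(seed)),
            class = "simulation_truth")
}

# raised half-sine amplitude envelope over a window: peak at mid-window (so
# GFP peaks fall inside windows), dropping to `floor_frac` of the peak half a
# sample outside the window boundaries, so every sample inside the window
# carries signal (a pure half-sine would leave boundary samples noise-only,
# which no evoked recording exhibits)
envelope_at <- function(t_ms, start_ms, end_ms, peak, floor_frac = 0.3) {
  h <- 1  # ms, half the 2-ms sampling period
  L <- end_ms - start_ms + 2 * h
  peak * (floor_frac + (1 - floor_frac) * sin(pi * (t_ms - start_ms + h) / L))
}

# smooth spatial noise covariance factor for a montage (chol of a squared-
# exponential kernel on the scalp, unit marginal variance)
noise_mixing_matrix <- function(montage, length_mm = 40) {
  xyz <- montage$positions * montage$radius_mm
  d2 <- as.matrix(stats::dist(xyz))^2
  K <- exp(-d2 / (2 * length_mm^2))
  K <- K + diag(1e-6, nrow(K))
  K <- K / mean(diag(K))
  t(chol(K))
}

# per-subject, per-condition jittered schedule (interior boundaries shifted by
# a uniform draw on +/- jitter, snapped to the 2-ms lattice, each window kept
# at least one sample long)
jitter_schedule <- function(sched, jitter_ms) {
  n <- nrow(sched)
  if (n <= 1 || jitter_ms <= 0) return(sched)
  for (i in seq_len(n - 1)) {
    shift <- round(stats::runif(1, -jitter_ms, jitter_ms) / 2) * 2
    new_end <- sched$end_ms[i] + shift
    new_end <- max(sched$start_ms[i], min(new_end, sched$end_ms[i + 1] - 2))
    sched$end_ms[i] <- new_end
    sched$start_ms[i + 1] <- new_end + 2
  }
  sched
}

# noiseless subject signal: channels x samples
schedule_signal <- function(templates, sched, times, amplitude_uv) {
  sig <- matrix(0, nrow(templates), length(times))
  for (i in seq_len(nrow(sched))) {
    in_win <- times >= sched$start_ms[i] & times <= sched$end_ms[i]
    if (!any(in_win)) next
    amp <- envelope_at(times[in_win], sched$start_ms[i], sched$end_ms[i],
                       amplitude_uv)
    sig[, in_win] <- templates[, sched$state[i]] %o% amp
  }
  sig
}

#' Simulate a full group of epoched datasets
#'
#' For every subject and condition, generates single-trial epochs whose
#' post-stimulus noiseless part is the scheduled template modulated by a
#' half-sine amplitude envelope; pre-stimulus samples carry noise only.
#' Per-subject interior window boundaries are jittered. All randomness flows
#' from `truth$seed`.
#'
#' @param truth a [simulation_truth()].
#' @param leadfield the lead field whose montage the templates live on (used
#'   for the montage geometry of the spatial noise model).
#' @return list of epoch sets (class `"epoch_set"`), one per
#'   subject x condition, each with elements `subject`, `condition`, `data`
#'   (epochs x channels x samples, µV), `sfreq`, `times`, `t0_index`, `log`,
#'   plus attribute `"jittered_schedule"`.
#' @export
simulate_group <- function(truth, leadfield) {
  if (nrow(truth$templates) != nrow(leadfield$gain))
    stop("templates do not match the lead-field montage", call. = FALSE)
  set.seed(truth$seed)
  times <- seq(-100, 500, by = 2)
  nch <- nrow(truth$templates)
  ns <- length(times)
  mix <- if (truth$noise_type == "correlated")
    noise_mixing_matrix(leadfield$montage) else diag(nch)
  out <- list()
  for (subj in seq_len(truth$n_subjects)) {
    for (cond in truth$conditions) {
      sched <- jitter_schedule(truth$schedule[[cond]], truth$subject_jitter_ms)
      sig <- schedule_signal(truth$templates, sched, times, truth$amplitude_uv)
      data <- array(0, dim = c(truth$n_epochs, nch, ns))
      for (e in seq_len(truth$n_epochs)) {
        noise <- truth$noise_sd * (mix %*% matrix(stats::rnorm(nch * ns), nch, ns))
        data[e, , ] <- sig + noise
      }
      es <- epoch_set(subject = subj, condition = cond, data = data,
                      sfreq = 500, times = times)
      attr(es, "jittered_schedule") <- sched
      out[[paste(subj, cond, sep = ".")]] <- es
    }
  }
  out
}

#' Simulate subject-level VEPs directly
#'
#' Equivalent in distribution to averaging `n_epochs` simulated epochs (the
#' Gaussian noise SD is divided by sqrt(n_epochs)), at a fraction of the cost
#' and memory. Used for group-size simulation studies; the epoch-level path
#' ([simulate_group()]) exercises the full first-level chain.
#'
#' @inheritParams simulate_group
#' @return list of evoked objects (class `"evoked"`), one per
#'   subject x condition, each with attribute `"jittered_schedule"`.
#' @export
simulate_subject_veps <- function(truth, leadfield) {
  if (nrow(truth$templates) != nrow(leadfield$gain))
    stop("templates do not match the lead-field montage", call. = FALSE)
  set.seed(truth$seed)
  times <- seq(-100, 500, by = 2)
  nch <- nrow(truth$templates)
  ns <- length(times)
  mix <- if (truth$noise_type == "correlated")
    noise_mixing_matrix(leadfield$montage) else diag(nch)
  sd_vep <- truth$noise_sd / sqrt(truth$n_epochs)
  out <- list()
  for (subj in seq_len(truth$n_subjects)) {
    for (cond in truth$conditions) {
      sched <- jitter_schedule(truth$schedule[[cond]], truth$subject_jitter_ms)
      sig <- schedule_signal(truth$templates, sched, times, truth$amplitude_uv)
      noise <- sd_vep * (mix %*% matrix(stats::rnorm(nch * ns), nch, ns))
      ev <- evoked(data = sig + noise, times = times, condition = cond,
                   subject = subj, n_epochs_averaged = truth$n_epochs,
                   log = c("simulate", "average"))
      attr(ev, "jittered_schedule") <- sched
      out[[paste(subj, cond, sep = ".")]] <- ev
    }
  }
  out
}

#' Inject threshold-exceeding artifacts into an epoch set
#'
#' Adds a smooth transient with peak above `amplitude_uv` to exactly
#' `round(fraction * n_epochs)` epochs (seeded choice), and returns the
#' contaminated set together with a log of which epochs were hit, where.
#'
#' @param epochs an epoch set.
#' @param fraction proportion of epochs to contaminate, in \[0, 1\].
#' @param amplitude_uv transient floor in µV (the injected peak is 1.2x this).
#' @param seed integer seed.
#' @return list with `epochs` (contaminated copy) and `log` (data.frame of
#'   epoch, channel, sample, peak_uv).
#' @export
inject_artifacts <- function(epochs, fraction, amplitude_uv = 150, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  if (amplitude_uv <= 0) stop("amplitude_uv must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  n_ep <- dim(epochs$data)[1]
  n_hit <- round(fraction * n_ep)
  if (n_hit == 0)
    return(list(epochs = epochs,
                log = data.frame(epoch = integer(0), channel = integer(0),
                                 sample = integer(0), peak_uv = numeric(0))))
  hit <- sort(sample(n_ep, n_hit))
  nch <- dim(epochs$data)[2]
  ns <- dim(epochs$data)[3]
  peak <- 1.2 * amplitude_uv
  log <- data.frame(epoch = hit, channel = NA_integer_, sample = NA_integer_,
                    peak_uv = NA_real_)
  for (i in seq_along(hit)) {
    ch <- sample(nch, 1)
    s0 <- sample(seq(5, ns - 5), 1)
    span <- max(1, s0 - 4):min(ns, s0 + 4)
    bump <- peak * exp(-((span - s0)^2) / 4)
    epochs$data[hit[i], ch, span] <- epochs$data[hit[i], ch, span] + bump
    log$channel[i] <- ch
    log$sample[i] <- s0
    log$peak_uv[i] <- peak
  }
  epochs$log <- c(epochs$log, sprintf("inject_artifacts(fraction=%g)", fraction))
  list(epochs = epochs, log = log)
}
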
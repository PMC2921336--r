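#' Reject epochs by absolute amplitude threshold
#'
#' An epoch is rejected iff its absolute peak over all channels and samples
#' exceeds the threshold (strictly), the automated criterion applied before
#' averaging.
#'
#' @param epochs an [epoch_set()].
#' @param threshold_uv rejection threshold in µV (default 100).
#' @return list with `epochs` (survivors) and `report` (data.frame of rejected
#'   epoch index, peak value, offending channel and sample).
#' @export
reject_epochs <- function(epochs, threshold_uv = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (threshold_uv <= 0) stop("threshold_uv must be positive", call. = FALSE)
  n_ep <- dim(epochs$data)[1]
  peaks <- apply(abs(epochs$data), 1, max)
  bad <- which(peaks > threshold_uv)
  report <- data.frame(epoch = bad, peak_uv = peaks[bad],
                       channel = rep(NA_integer_, length(bad)),
                       sample = rep(NA_integer_, length(bad)))
  for (i in seq_along(bad)) {
    w <- which(abs(epochs$data[bad[i], , ]) == peaks[bad[i]],
               arr.ind = TRUE)[1, ]
    report$channel[i] <- w[1]
    report$sample[i] <- w[2]
  }
  if (length(bad) == n_ep)
    stop("all epochs rejected; averaging impossible", call. = FALSE)
  keep <- setdiff(seq_len(n_ep), bad)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$log <- c(out$log, "reject")
  list(epochs = out, report = report)
}

# Perrin-style spherical spline basis g(x) truncated at `n_terms` degrees
spline_g <- function(x, order = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  w <- (2 * n + 1) / (n * (n + 1))^order
  P <- legendre_terms(x, n_terms)$P
  drop(P %*% w) / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed channels with the spherical-spline estimate computed
#' from the remaining good channels on the montage sphere.
#'
#' @param data an [evoked()] or [epoch_set()].
#' @param bad integer indices (or labels) of channels to repair.
#' @param montage the montage the data were recorded on.
#' @param order spline order m (default 4).
#' @param lambda ridge regularizer on the spline system (default 1e-8).
#' @return the repaired object (good channels untouched).
#' @export
interpolate_channels <- function(data, bad, montage, order = 4,
                                 lambda = 1e-8) {
  validate_montage(montage)
  if (is.character(bad)) bad <- match(bad, montage$labels)
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) == 0) return(data)
  nch <- montage$n_channels
  good <- setdiff(seq_len(nch), bad)
  if (length(good) < 4)
    stop("at least 4 good channels are required for spline interpolation",
         call. = FALSE)
  if (length(bad) >= nch)
    stop("bad must be a strict subset of channels", call. = FALSE)
  pos <- montage$positions
  cosang <- pos[good, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  G <- matrix(spline_g(pmin(1, pmax(-1, as.vector(cosang))), order),
              length(good), length(good))
  # spline system with a constant term:  [G + lambda I, 1; 1', 0]
  A <- rbind(cbind(G + diag(lambda, length(good)), 1),
             c(rep(1, length(good)), 0))
  cos_bad <- pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  Gb <- matrix(spline_g(pmin(1, pmax(-1, as.vector(cos_bad))), order),
               length(bad), length(good))
  solve_map <- function(v_good) {
    sol <- solve(A, c(v_good, 0))
    drop(Gb %*% sol[seq_along(good)]) + sol[length(sol)]
  }
  if (inherits(data, "evoked")) {
    data$data[bad, ] <- apply(data$data[good, , drop = FALSE], 2, solve_map)
    data$log <- c(data$log, "interpolate")
  } else if (inherits(data, "epoch_set")) {
    for (e in seq_len(dim(data$data)[1]))
      data$data[e, bad, ] <- apply(data$data[e, good, , drop = FALSE], 2,
                                   solve_map)
    data$log <- c(data$log, "interpolate")
  } else stop("data must be evoked or epoch_set", call. = FALSE)
  data
}

#' Average surviving epochs to a VEP
#'
#' @param epochs an [epoch_set()] with at least one epoch.
#' @return an [evoked()] with `n_epochs_averaged` recorded.
#' @export
average_to_vep <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 1) stop("no epochs to average", call. = FALSE)
  avg <- apply(epochs$data, c(2, 3), mean)
  evoked(data = avg, times = epochs$times, condition = epochs$condition,
         subject = epochs$subject, n_epochs_averaged = n_ep,
         log = c(epochs$log, "average"))
}

# zero-phase Butterworth filtering with odd-reflection padding at both ends
# (plain filtfilt starts from zero state, which leaves large transients on
# short records)
filtfilt_padded <- function(x, bf, npad = length(x) - 1L) {
  n <- length(x)
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(npad + 1L):(npad + n)]
}

#' Baseline-correct and band-pass filter a VEP
#'
#' Subtracts the per-channel mean over the baseline window, then applies a
#' zero-phase (forward-backward, odd-reflection padded) Butterworth filter.
#'
#' A high-pass edge whose period exceeds the record length cannot be applied
#' meaningfully to an epoch (the filter would estimate and subtract a "trend"
#' longer than the data, distorting every sample); in that case — the normal
#' case for -100..500 ms epochs with a 1 Hz edge — drift removal is already
#' accomplished by the baseline correction, only the low-pass leg is applied,
#' and the recorded filter attributes say so. Longer records get the full
#' band-pass.
#'
#' @param vep an [evoked()].
#' @param baseline_ms two-element window (default c(-100, 0)).
#' @param band_hz two-element pass band in Hz (default c(1, 30)); `NULL`
#'   skips the filter entirely (appropriate for noise-free synthetic data,
#'   where the filter's only role — noise attenuation — is moot).
#' @param filter_order Butterworth prototype order (default 2, i.e. a
#'   4th-order band-pass before the forward-backward pass).
#' @param baseline_only skip the filter (used to assert the exact zero-mean
#'   baseline property without filter edge effects).
#' @param min_highpass_periods minimum number of high-pass periods the record
#'   must span for the high-pass leg to be applied (default 1).
#' @return the processed evoked, steps appended to the log; filter parameters
#'   in `attr(, "filter")`.
#' @export
baseline_and_bandpass <- function(vep, baseline_ms = c(-100, 0),
                                  band_hz = c(1, 30), filter_order = 2,
                                  baseline_only = FALSE,
                                  min_highpass_periods = 1) {
  stopifnot(inherits(vep, "evoked"))
  # strictly pre-stimulus: the sample at the window's right edge (stimulus
  # onset when baseline ends at 0) already carries evoked signal
  bl <- vep$times >= baseline_ms[1] & vep$times < baseline_ms[2]
  if (!any(bl)) stop("baseline window outside the time axis", call. = FALSE)
  sfreq <- 1000 / diff(vep$times[1:2])
  nyq <- sfreq / 2
  if (is.null(band_hz)) baseline_only <- TRUE
  else if (band_hz[1] <= 0 || band_hz[2] >= nyq || band_hz[1] >= band_hz[2])
    stop("band edges must lie inside (0, Nyquist)", call. = FALSE)
  vep$data <- vep$data - rowMeans(vep$data[, bl, drop = FALSE])
  vep$log <- c(vep$log, "baseline")
  if (!baseline_only) {
    record_ms <- diff(range(vep$times))
    hp_ok <- record_ms >= min_highpass_periods * 1000 / band_hz[1]
    bf <- if (hp_ok) signal::butter(filter_order, band_hz / nyq, type = "pass")
          else signal::butter(filter_order, band_hz[2] / nyq, type = "low")
    vep$data <- t(apply(vep$data, 1, function(ch) filtfilt_padded(ch, bf)))
    vep$log <- c(vep$log, "bandpass")
    attr(vep, "filter") <- list(
      order = filter_order, band_hz = band_hz, design = "butterworth",
      zero_phase = TRUE, highpass_applied = hp_ok,
      note = if (hp_ok) "full band-pass" else
        "record shorter than one high-pass period: low-pass leg only, drift removed by baseline correction")
  }
  vep
}

#' Average-reference and normalize to mean GFP
#'
#' Removes the channel mean at every sample, then divides the whole VEP by
#' the scalar mean of its GFP over the 0..500 ms analysis window, so the
#' result has mean GFP 1 there.
#'
#' @param vep an [evoked()] with at least 2 channels.
#' @param norm_window_ms window over which mean GFP is taken (default
#'   c(0, 500)).
#' @return the re-referenced, normalized evoked.
#' @export
rereference_and_normalize <- function(vep, norm_window_ms = c(0, 500)) {
  stopifnot(inherits(vep, "evoked"))
  if (nrow(vep$data) < 2) stop("need at least 2 channels", call. = FALSE)
  vep$data <- sweep(vep$data, 2, colMeans(vep$data))
  vep$log <- c(vep$log, "rereference")
  win <- vep$times >= norm_window_ms[1] & vep$times <= norm_window_ms[2]
  g <- mean(apply(vep$data[, win, drop = FALSE], 2, function(v)
    sqrt(mean(v^2))))
  if (g < 1e-15)
    stop("mean GFP is zero: degenerate (identically zero) VEP", call. = FALSE)
  vep$data <- vep$data / g
  vep$log <- c(vep$log, "normalize")
  vep
}

#' Full first-level chain for one subject/condition
#'
#' reject -> (interpolate) -> average -> baseline -> bandpass -> rereference
#' -> normalize, with the order guard asserted on the result.
#'
#' @param epochs an [epoch_set()].
#' @param threshold_uv rejection threshold (µV).
#' @param bad bad-channel indices to interpolate (default none).
#' @param montage montage (required if `bad` non-empty).
#' @param baseline_ms,band_hz see [baseline_and_bandpass()].
#' @return a fully preprocessed [evoked()].
#' @export
preprocess_vep <- function(epochs, threshold_uv = 100, bad = integer(0),
                           montage = NULL, baseline_ms = c(-100, 0),
                           band_hz = c(1, 30)) {
  kept <- reject_epochs(epochs, threshold_uv)$epochs
  if (length(bad) > 0) {
    if (is.null(montage)) stop("montage required to interpolate", call. = FALSE)
    kept <- interpolate_channels(kept, bad, montage)
  }
  vep <- average_to_vep(kept)
  vep <- baseline_and_bandpass(vep, baseline_ms, band_hz)
  vep <- rereference_and_normalize(vep)
  assert_pipeline_order(vep)
  vep
}

#' Group-average normalized VEPs per condition
#'
#' Averages the per-subject normalized VEPs of each condition and
#' re-normalizes the group average (average reference and unit mean GFP).
#'
#' @param veps list of preprocessed [evoked()] objects.
#' @return named list of group evoked objects, one per condition, ordered by
#'   first appearance.
#' @export
group_average_veps <- function(veps) {
  conds <- unique(vapply(veps, function(v) v$condition, character(1)))
  out <- list()
  for (cond in conds) {
    sel <- Filter(function(v) identical(v$condition, cond), veps)
    acc <- Reduce(`+`, lapply(sel, function(v) v$data)) / length(sel)
    ev <- evoked(data = acc, times = sel[[1]]$times, condition = cond,
                 subject = "group", n_epochs_averaged = length(sel),
                 log = c("average", "baseline", "bandpass"))
    out[[cond]] <- rereference_and_normalize(ev)
  }
  out
}
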
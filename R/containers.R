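# small numeric helpers shared across modules
norm2 <- function(v) sqrt(sum(v^2))
center_map <- function(v) v - mean(v)
center_maps <- function(m) sweep(m, 2, colMeans(m))

#' Epoched single-trial data for one subject and condition
#'
#' @param subject subject identifier.
#' @param condition condition label.
#' @param data numeric array, epochs x channels x samples, in µV.
#' @param sfreq sampling rate in Hz (500 for the emulated study).
#' @param times time axis in ms; must be consistent with `sfreq` and contain 0.
#' @param log character vector of processing steps already applied.
#' @return object of class `"epoch_set"` with `t0_index` locating 0 ms.
#' @export
epoch_set <- function(subject, condition, data, sfreq = 500,
                      times = seq(-100, 500, by = 2), log = character()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != length(times))
    stop("sample count does not match the time axis", call. = FALSE)
  step <- 1000 / sfreq
  if (max(abs(diff(times) - step)) > 1e-9)
    stop("time axis step inconsistent with sfreq", call. = FALSE)
  t0 <- which(abs(times) < 1e-9)
  if (length(t0) != 1L) stop("time axis must contain 0 ms exactly once", call. = FALSE)
  structure(list(subject = subject, condition = condition, data = data,
                 sfreq = sfreq, times = times, t0_index = t0, log = log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s, condition %s: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject, x$condition, d[1], d[2], d[3], x$sfreq))
  invisible(x)
}

#' An averaged evoked potential (VEP)
#'
#' @param data channels x samples matrix in µV (unitless after normalization).
#' @param times time axis in ms.
#' @param condition condition label.
#' @param subject subject identifier (or `"group"`).
#' @param n_epochs_averaged number of epochs behind the average.
#' @param log append-only character vector of processing steps.
#' @return object of class `"evoked"`.
#' @export
evoked <- function(data, times, condition = NA_character_,
                   subject = NA_character_, n_epochs_averaged = NA_integer_,
                   log = character()) {
  stopifnot(is.matrix(data), ncol(data) == length(times))
  structure(list(data = data, times = times, condition = condition,
                 subject = subject, n_epochs_averaged = n_epochs_averaged,
                 log = log),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> subject %s, condition %s: %d channels x %d samples [%s]\n",
              x$subject, x$condition, nrow(x$data), ncol(x$data),
              paste(x$log, collapse = " > ")))
  invisible(x)
}

# canonical first-level order; used by the order guard
PIPELINE_ORDER <- c("reject", "interpolate", "average", "baseline", "bandpass",
                    "rereference", "normalize")

#' Check that a processing log respects the first-level order
#'
#' The canonical first-level chain is reject, interpolate, average, baseline,
#' bandpass, rereference, normalize; steps may be skipped but never permuted.
#' @param x an evoked or epoch_set (or a character log).
#' @return invisibly `TRUE`; errors on a permuted log.
#' @export
assert_pipeline_order <- function(x) {
  log <- if (is.character(x)) x else x$log
  steps <- log[log %in% PIPELINE_ORDER]
  pos <- match(steps, PIPELINE_ORDER)
  if (is.unsorted(pos, strictly = FALSE) || anyDuplicated(steps))
    stop(sprintf("processing log violates the first-level order: %s",
                 paste(steps, collapse = " > ")), call. = FALSE)
  invisible(TRUE)
}
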
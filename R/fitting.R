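#' Back-fit group templates to a single-subject VEP
#'
#' Labels each time sample inside the fit window by the template with which
#' its topography correlates best (signed correlation; ties to the lower
#' index), and aggregates per-template durations. Samples whose map is
#' (numerically) zero after average referencing cannot be correlated; they are
#' labelled with the lowest-index template and logged.
#'
#' @param templates channels x k matrix of unit-norm group templates.
#' @param vep a normalized [evoked()].
#' @param window_ms two-element fit window in ms.
#' @return object of class `"labeling_result"`: `subject`, `condition`,
#'   `labels` (per in-window sample), `times`, `durations_ms` (per template,
#'   sums to the fit-window length), `mean_corr` (per template, NA when the
#'   template never occurs), `degenerate_samples`.
#' @export
backfit <- function(templates, vep, window_ms) {
  stopifnot(inherits(vep, "evoked"))
  sel <- which(vep$times >= window_ms[1] & vep$times <= window_ms[2])
  if (length(sel) == 0) stop("fit window outside the time axis", call. = FALSE)
  maps <- center_maps(vep$data[, sel, drop = FALSE])
  nrm <- sqrt(colSums(maps^2))
  degenerate <- which(nrm < 1e-12)
  u <- sweep(maps, 2, pmax(nrm, 1e-15), "/")
  cr <- crossprod(templates, u)          # k x n
  labels <- apply(cr, 2, which.max)
  labels[degenerate] <- 1L
  period <- diff(vep$times[1:2])
  k <- ncol(templates)
  durations <- vapply(seq_len(k), function(j) sum(labels == j) * period,
                      numeric(1))
  mean_corr <- vapply(seq_len(k), function(j) {
    hit <- labels == j
    if (!any(hit)) NA_real_ else mean(cr[j, hit])
  }, numeric(1))
  structure(list(subject = vep$subject, condition = vep$condition,
                 labels = labels, times = vep$times[sel],
                 durations_ms = durations, mean_corr = mean_corr,
                 window_ms = window_ms,
                 degenerate_samples = degenerate),
            class = "labeling_result")
}

#' One-way repeated-measures ANOVA on microstate durations
#'
#' Classical univariate RM-ANOVA with subject as the blocking factor:
#' F = MS_condition / MS_(condition x subject), df = (c-1, (c-1)(n-1)),
#' no sphericity correction. Fitted via [stats::aov()].
#'
#' @param durations numeric matrix, subjects x conditions (complete; one
#'   duration per cell for one microstate).
#' @return object of class `"anova_result"`: `F`, `df` (numerator,
#'   denominator), `p`, `means`, `sds`, `factor`.
#' @export
duration_anova <- function(durations) {
  durations <- as.matrix(durations)
  if (anyNA(durations)) stop("durations table must be complete", call. = FALSE)
  n <- nrow(durations)
  c <- ncol(durations)
  if (n < 2 || c < 2)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  df_long <- data.frame(
    y = as.vector(durations),
    subject = factor(rep(seq_len(n), times = c)),
    condition = factor(rep(seq_len(c), each = n)))
  fit <- stats::aov(y ~ condition + subject, data = df_long)
  tab <- summary(fit)[[1]]
  ms_cond <- tab["condition", "Mean Sq"]
  ms_res <- tab["Residuals", "Mean Sq"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  # guard exact-zero sums of squares against floating-point dust from aov
  tiny <- 1e-12 * mean(durations^2)
  if (ms_cond < tiny) ms_cond <- 0
  if (ms_res < tiny) ms_res <- 0
  Fval <- if (ms_cond == 0) 0 else if (ms_res == 0) Inf else ms_cond / ms_res
  p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  cond_names <- colnames(durations)
  if (is.null(cond_names)) cond_names <- paste0("cond", seq_len(c))
  structure(list(F = Fval, df = c(df1, df2), p = p,
                 means = stats::setNames(colMeans(durations), cond_names),
                 sds = stats::setNames(apply(durations, 2, stats::sd),
                                       cond_names),
                 factor = "condition (within-subject)"),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Long-format microstate presence table
#'
#' Collects all subject/condition labelings into a tidy table with one row
#' per (subject, condition, microstate): duration in ms and mean fit
#' correlation. Suitable for the duration ANOVA and for plotting.
#'
#' @param labelings list of [backfit()] results covering every
#'   subject x condition.
#' @return data.frame with columns subject, condition, microstate,
#'   duration_ms, mean_corr.
#' @export
microstate_presence_report <- function(labelings) {
  rows <- lapply(labelings, function(lb) {
    k <- length(lb$durations_ms)
    data.frame(subject = lb$subject, condition = lb$condition,
               microstate = seq_len(k), duration_ms = lb$durations_ms,
               mean_corr = lb$mean_corr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Durations table for one microstate
#'
#' Pivot of the presence report: subjects x conditions matrix of the given
#' microstate's durations, input for [duration_anova()].
#'
#' @param report a [microstate_presence_report()] table.
#' @param microstate template index.
#' @param conditions condition order for the columns (default: order of first
#'   appearance).
#' @return numeric matrix subjects x conditions.
#' @export
durations_table <- function(report, microstate,
                            conditions = unique(report$condition)) {
  sub <- report[report$microstate == microstate, ]
  subjects <- unique(sub$subject)
  m <- matrix(NA_real_, length(subjects), length(conditions),
              dimnames = list(subjects, conditions))
  for (i in seq_len(nrow(sub)))
    m[as.character(sub$subject[i]), as.character(sub$condition[i])] <-
      sub$duration_ms[i]
  m
}

#' Write / read the presence table as TSV
#' @param report the table.
#' @param path file path.
#' @export
write_presence_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
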
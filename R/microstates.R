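#' Global field power
#'
#' Spatial root-mean-square of the average-referenced scalp field at one
#' instant: the spatial standard deviation of the map, indexing field strength
#' independently of topography.
#'
#' @param map numeric vector over channels, or a channels x samples matrix
#'   (then a GFP per sample is returned).
#' @return nonnegative scalar (or vector per sample).
#' @export
gfp <- function(map) {
  if (is.matrix(map)) {
    m <- sweep(map, 2, colMeans(map))
    return(sqrt(colMeans(m^2)))
  }
  if (length(map) < 2) stop("need at least 2 channels", call. = FALSE)
  v <- map - mean(map)
  sqrt(mean(v^2))
}

#' Strength-independent spatial correlation between two maps
#'
#' Pearson correlation across channels of the average-referenced maps;
#' invariant to positive rescaling of either map, sign-sensitive (a map and
#' its negation correlate at -1).
#'
#' @param a,b numeric vectors over the same channels.
#' @return scalar in \[-1, 1\].
#' @export
spatial_correlation <- function(a, b) {
  ac <- a - mean(a)
  bc <- b - mean(b)
  na <- norm2(ac)
  nb <- norm2(bc)
  if (na < 1e-15 || nb < 1e-15)
    stop("zero map after average referencing: correlation undefined",
         call. = FALSE)
  sum(ac * bc) / (na * nb)
}

# Stack the analysis-window samples of a list of group VEPs into a map matrix.
# Returns channels x N maps, their GFP, unit maps, and a (condition, time)
# index table.
stack_maps <- function(group_veps, window_ms = c(0, 500)) {
  maps <- NULL
  idx <- NULL
  for (cond in names(group_veps)) {
    v <- group_veps[[cond]]
    sel <- which(v$times >= window_ms[1] & v$times <= window_ms[2])
    maps <- cbind(maps, v$data[, sel, drop = FALSE])
    idx <- rbind(idx, data.frame(condition = cond, time_ms = v$times[sel]))
  }
  maps <- center_maps(maps)
  g <- sqrt(colMeans(maps^2))
  nrm <- sqrt(colSums(maps^2))
  u <- sweep(maps, 2, pmax(nrm, 1e-15), "/")
  list(maps = maps, gfp = g, u = u, index = idx)
}

# first principal pattern of a set of member maps (channels x m), unit-norm,
# sign-aligned with the mean member
principal_pattern <- function(M) {
  if (ncol(M) == 1L) {
    t <- M[, 1]
  } else {
    t <- svd(M, nu = 1, nv = 0)$u[, 1]
  }
  t <- t - mean(t)
  n <- norm2(t)
  if (n < 1e-15) return(rep(0, nrow(M)))
  t <- t / n
  if (sum(t * rowMeans(M)) < 0) t <- -t
  t
}

# One atomize-and-agglomerate sweep from singletons down to k_min, recording
# the model at every k <= k_record_max. The cluster dissolved at each step is
# the one contributing least to global explained variance in the net sense:
# its members' explained variance minus what the best remaining clusters
# would recover after reassignment, so a redundant (split) cluster costs
# nothing and is dissolved first. Deterministic: ties on the dissolved
# cluster and on reassignment go to the lower index.
aahc_sweep <- function(stacked, k_min, k_record_max) {
  u <- stacked$u
  maps <- stacked$maps
  g <- stacked$gfp
  g2 <- g^2
  N <- ncol(u)
  denom <- sum(g2)
  assign_vec <- seq_len(N)           # cluster id per sample
  templates <- u                     # unit template per cluster (by id)
  members <- as.list(seq_len(N))     # member sample indices per cluster id
  corr <- rep(1, N)                  # corr of each sample with its template
  alive <- rep(TRUE, N)
  # best correlation of each sample with any cluster other than its own,
  # and which cluster that is
  cr_full <- crossprod(u)            # N x N (singleton templates = unit maps)
  diag(cr_full) <- -Inf
  best_other <- apply(cr_full, 2, which.max)
  b <- cr_full[cbind(best_other, seq_len(N))]
  rm(cr_full)
  recorded <- list()
  k_now <- N
  record_if_needed <- function() {
    if (k_now <= k_record_max) {
      ids <- which(alive)
      remap <- integer(N)
      remap[ids] <- seq_along(ids)
      recorded[[as.character(k_now)]] <<- list(
        k = k_now,
        templates = templates[, ids, drop = FALSE],
        assignment = remap[assign_vec],
        corr = corr,
        gev = sum((g * corr)^2) / denom)
    }
  }
  refresh_best_other <- function(samples, ids) {
    # full recompute of (b, best_other) for the given samples (vectorized:
    # one correlation matrix, own-cluster entries masked out)
    if (length(samples) == 0) return(invisible())
    cr <- crossprod(templates[, ids, drop = FALSE],
                    u[, samples, drop = FALSE])      # k x m
    own <- match(assign_vec[samples], ids)
    cr[cbind(own, seq_along(samples))] <- -Inf
    j <- apply(cr, 2, which.max)
    best_other[samples] <<- ids[j]
    b[samples] <<- cr[cbind(j, seq_along(samples))]
  }
  record_if_needed()
  while (k_now > k_min) {
    ids <- which(alive)
    # net GEV loss per cluster if dissolved now; polarity-sensitive: an
    # anticorrelated alternative explains nothing under the evoked-potential
    # convention, so only positive best-other correlations count
    loss_t <- g2 * (corr^2 - pmax(b, 0)^2)
    loss_c <- rowsum(loss_t, assign_vec)
    worst <- as.integer(rownames(loss_c))[which.min(loss_c)]
    move <- members[[worst]]
    alive[worst] <- FALSE
    members[[worst]] <- integer(0)
    remaining <- which(alive)
    # reassign each orphan to its best-correlated remaining template
    cr <- crossprod(templates[, remaining, drop = FALSE],
                    u[, move, drop = FALSE])      # k x m
    best <- remaining[apply(cr, 2, which.max)]
    changed <- unique(best)
    for (i in seq_along(move)) {
      cid <- best[i]
      assign_vec[move[i]] <- cid
      members[[cid]] <- c(members[[cid]], move[i])
    }
    # recompute templates and member correlations of changed clusters
    for (cid in changed) {
      mem <- members[[cid]]
      templates[, cid] <- principal_pattern(maps[, mem, drop = FALSE])
      corr[mem] <- drop(crossprod(u[, mem, drop = FALSE], templates[, cid]))
    }
    k_now <- k_now - 1L
    if (k_now > k_min || k_now <= k_record_max) {
      # keep the best-other cache exact: entries pointing at the dissolved or
      # changed clusters (or owned by changed clusters) are stale; any sample
      # may also have gained a better alternative among the changed templates
      stale <- which(best_other == worst |
                     best_other %in% changed |
                     assign_vec %in% changed)
      if (length(remaining) > 1) {
        refresh_best_other(stale, remaining)
        if (length(changed)) {
          cr_ch <- crossprod(templates[, changed, drop = FALSE], u)  # |S| x N
          for (j in seq_along(changed)) {
            cid <- changed[j]
            better <- which(cr_ch[j, ] > b & assign_vec != cid)
            if (length(better)) {
              b[better] <- cr_ch[j, better]
              best_other[better] <- cid
            }
          }
        }
      }
    }
    record_if_needed()
  }
  recorded
}

# within-cluster dispersion of the unit maps (sum of squared distances to the
# cluster mean unit map), used by the Krzanowski-Lai criterion
dispersion_w <- function(u, assignment) {
  w <- 0
  for (c in unique(assignment)) {
    mem <- which(assignment == c)
    um <- u[, mem, drop = FALSE]
    mu <- rowMeans(um)
    w <- w + sum(sweep(um, 1, mu)^2)
  }
  w
}

#' Atomize-and-agglomerate hierarchical clustering of topographies
#'
#' Starts from every time-sample map as a singleton cluster, repeatedly
#' dissolves the cluster contributing least to global explained variance and
#' reassigns its members to the best-correlated remaining cluster, until `k`
#' clusters remain. Cluster templates are the first principal pattern of the
#' member maps. Polarity is significant (evoked-potential convention): a map
#' and its negation end up in different clusters.
#'
#' @param group_veps named list of normalized group-average [evoked()]
#'   objects (one per condition, same montage).
#' @param k number of clusters (>= 1).
#' @param window_ms analysis window (default c(0, 500)).
#' @return object of class `"microstate_model"`: `k`, `templates`
#'   (channels x k, unit norm), `assignment` (per stacked sample),
#'   `index` (condition/time of each sample), `gev`, and `sample_corr`.
#' @export
aahc_cluster <- function(group_veps, k, window_ms = c(0, 500)) {
  st <- stack_maps(group_veps, window_ms)
  N <- ncol(st$u)
  if (k < 1 || k > N) stop("k must be in [1, number of samples]", call. = FALSE)
  rec <- aahc_sweep(st, k_min = k, k_record_max = k)
  model <- rec[[as.character(k)]]
  structure(list(k = k, templates = model$templates,
                 assignment = model$assignment, index = st$index,
                 gev = model$gev, sample_corr = model$corr,
                 window_ms = window_ms),
            class = "microstate_model")
}

#' Global explained variance of a microstate model
#'
#' GEV = sum_t (GFP_t * corr(map_t, template_of(t)))^2 / sum_t GFP_t^2,
#' summed over all conditions' analysis-window samples.
#'
#' @param model a `"microstate_model"` (its assignment must cover the data).
#' @param group_veps the group VEPs the model was fitted to.
#' @return proportion in \[0, 1\].
#' @export
gev <- function(model, group_veps) {
  st <- stack_maps(group_veps, model$window_ms)
  if (length(model$assignment) != ncol(st$u))
    stop("model assignment does not cover the data", call. = FALSE)
  cr <- numeric(ncol(st$u))
  for (t in seq_along(cr))
    cr[t] <- sum(st$u[, t] * model$templates[, model$assignment[t]])
  sum((st$gfp * cr)^2) / sum(st$gfp^2)
}

#' Select the number of microstates by a modified Krzanowski-Lai criterion
#'
#' Runs one agglomeration sweep, computes the within-cluster topographic
#' dispersion W(k) for each candidate, forms
#' DIFF(k) = (k-1)^(2/q) W(k-1) - k^(2/q) W(k) with q = number of channels,
#' and scores KL(k) = DIFF(k) / max(|DIFF(k+1)|, 0.01 W(1)) at convex
#' decreases of the dispersion curve (DIFF(k) > 0 and DIFF(k+1) < DIFF(k));
#' elsewhere the score is 0. The denominator floor — one percent of the total
#' topographic dispersion — keeps ratios of noise-scale differences at large
#' k from swamping the true elbow, the known instability of the raw
#' Krzanowski-Lai ratio. The candidate with the highest score wins; ties and
#' the all-zero case fall back to the smallest candidate k.
#'
#' @param group_veps named list of normalized group-average [evoked()] objects.
#' @param k_range candidate k values (default 2:12).
#' @param window_ms analysis window (default c(0, 500)).
#' @return the selected `"microstate_model"`, with `kl_curve` (data.frame of
#'   k, W, DIFF, KL) and `gev_curve` attached.
#' @export
select_k <- function(group_veps, k_range = 2:12, window_ms = c(0, 500)) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 2) stop("k_range must contain at least 2 candidates",
                                call. = FALSE)
  st <- stack_maps(group_veps, window_ms)
  N <- ncol(st$u)
  if (min(k_range) < 2 || max(k_range) > N - 1)
    stop("k_range must lie within [2, n_samples - 1]", call. = FALSE)
  k_lo <- min(k_range) - 1L
  k_hi <- max(k_range) + 1L
  rec <- aahc_sweep(st, k_min = k_lo, k_record_max = k_hi)
  ks <- k_lo:k_hi
  W <- vapply(ks, function(k) dispersion_w(st$u, rec[[as.character(k)]]$assignment),
              numeric(1))
  names(W) <- ks
  q <- nrow(st$u)
  diff_k <- function(k) {
    (k - 1)^(2 / q) * W[as.character(k - 1)] - k^(2 / q) * W[as.character(k)]
  }
  # denominator floor: 1% of the total dispersion (the W value at a single
  # cluster), so near-zero DIFF ratios deep in the noise floor cannot win
  w_total <- dispersion_w(st$u, rep(1L, N))
  floor_d <- 0.01 * w_total
  kl <- data.frame(k = k_range, W = W[as.character(k_range)], DIFF = NA_real_,
                   KL = 0)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    d1 <- diff_k(k)
    d2 <- diff_k(k + 1)
    kl$DIFF[i] <- d1
    if (!is.na(d1) && d1 > 0 && d2 < d1) {
      kl$KL[i] <- d1 / max(abs(d2), floor_d)
    }
  }
  best <- if (all(kl$KL <= 0)) 1L else which.max(kl$KL)
  k_star <- k_range[best]
  m <- rec[[as.character(k_star)]]
  model <- structure(list(k = k_star, templates = m$templates,
                          assignment = m$assignment, index = st$index,
                          gev = m$gev, sample_corr = m$corr,
                          window_ms = window_ms),
                     class = "microstate_model")
  attr(model, "kl_curve") <- kl
  attr(model, "gev_curve") <- data.frame(
    k = k_range,
    gev = vapply(k_range, function(k) rec[[as.character(k)]]$gev, numeric(1)))
  model
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d templates, GEV = %.4f\n", x$k, x$gev))
  invisible(x)
}

#' Extract per-condition microstate windows from a fitted model
#'
#' Labels each analysis-window sample of each condition's group VEP by its
#' best-correlated template (signed correlation; ties to the lower index),
#' then merges runs shorter than `min_duration_ms` into the neighbouring run
#' whose template correlates better with the short run's samples.
#'
#' @param model a `"microstate_model"`.
#' @param group_veps the group VEPs.
#' @param min_duration_ms minimal run length to keep (default 10 ms).
#' @return named list per condition: data.frame with `state`, `start_ms`,
#'   `end_ms`.
#' @export
extract_windows <- function(model, group_veps, min_duration_ms = 10) {
  out <- list()
  for (cond in names(group_veps)) {
    v <- group_veps[[cond]]
    sel <- which(v$times >= model$window_ms[1] & v$times <= model$window_ms[2])
    times <- v$times[sel]
    labels <- label_samples(model$templates, v$data[, sel, drop = FALSE])
    labels <- merge_short_runs(labels, model$templates,
                               v$data[, sel, drop = FALSE],
                               min_samples = ceiling(min_duration_ms /
                                                     diff(times[1:2])))
    out[[cond]] <- runs_to_windows(labels, times)
  }
  out
}

# label each column of a map matrix by the best (signed) correlated template;
# ties go to the lower template index; all-zero maps fall back to template 1
label_samples <- function(templates, maps) {
  m <- center_maps(maps)
  nrm <- sqrt(colSums(m^2))
  u <- sweep(m, 2, pmax(nrm, 1e-15), "/")
  cr <- crossprod(templates, u)    # k x N
  apply(cr, 2, which.max)
}

merge_short_runs <- function(labels, templates, maps, min_samples) {
  if (min_samples <= 1) return(labels)
  m <- center_maps(maps)
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_samples)
    if (length(short) == 0) break
    i <- short[which.min(r$lengths[short])]   # shortest first; ties earliest
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    span <- starts[i]:ends[i]
    cand <- integer(0)
    if (i > 1) cand <- c(cand, r$values[i - 1])
    if (i < length(r$values)) cand <- c(cand, r$values[i + 1])
    cand <- unique(cand)
    sc <- vapply(cand, function(tmpl)
      mean(crossprod(templates[, tmpl], m[, span, drop = FALSE])), numeric(1))
    labels[span] <- cand[which.max(sc)]
  }
  labels
}

runs_to_windows <- function(labels, times) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(state = r$values, start_ms = times[starts], end_ms = times[ends])
}
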
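# Independent oracles, written directly from definitions/closed forms and
# kept free of the package's implementation paths.

# Surface potential of a dipole in a homogeneous conducting sphere
# (closed form from summing the Legendre series analytically):
#   V = 1/(4 pi sigma R^2) * { q_r [ 2(x - t)/s^3 + (1/s - 1)/t ]
#       + q_t sqrt(1-x^2) [ 2/s^3 + (1+s)/(s (1 - t x + s)) ] }
# with t = b/R, x = cos(gamma), s = sqrt(1 - 2 t x + t^2).
oracle_homogeneous_sphere <- function(elec_xyz, r0, q, R, sigma) {
  b <- sqrt(sum(r0^2))
  er <- r0 / b
  apply(elec_xyz, 1, function(re) {
    rn <- sqrt(sum(re^2))
    x <- max(-1, min(1, sum(re * r0) / (rn * b)))
    qr <- sum(q * er)
    tvec <- re / rn - x * er
    tn <- sqrt(sum(tvec^2))
    qt <- if (tn > 1e-12) sum(q * tvec / tn) else 0
    t <- b / R
    s <- sqrt(1 - 2 * t * x + t^2)
    rad <- 2 * (x - t) / s^3 + (1 / s - 1) / t
    tang <- sqrt(max(0, 1 - x^2)) * (2 / s^3 + (1 + s) / (s * (1 - t * x + s)))
    (qr * rad + qt * tang) / (4 * pi * sigma * R^2)
  })
}

# direct-formula GFP: root mean square of the mean-subtracted vector
oracle_gfp <- function(v) {
  m <- v - mean(v)
  sqrt(sum(m^2) / length(m))
}

# direct Pearson correlation of average-referenced maps
oracle_spatial_corr <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
}

# literal transcription of the GEV formula
oracle_gev <- function(maps, gfp_vals, templates, assignment) {
  num <- 0
  for (t in seq_len(ncol(maps))) {
    cc <- oracle_spatial_corr(maps[, t], templates[, assignment[t]])
    num <- num + (gfp_vals[t] * cc)^2
  }
  num / sum(gfp_vals^2)
}

# closed-form sums-of-squares decomposition for the one-way RM-ANOVA
oracle_rm_anova <- function(tab) {
  n <- nrow(tab); c <- ncol(tab)
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- c * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- c - 1; df2 <- (c - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  list(F = Fv, df = c(df1, df2), p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

# exhaustive best 2-partition of a small set of maps, by GEV with
# first-principal-pattern templates (mirrors the model's template rule but
# searches all partitions instead of agglomerating)
oracle_best_2partition_gev <- function(maps, gfp_vals) {
  n <- ncol(maps)
  centred <- sweep(maps, 2, colMeans(maps))
  unit <- sweep(centred, 2, sqrt(colSums(centred^2)), "/")
  tmpl_of <- function(idx) {
    M <- centred[, idx, drop = FALSE]
    t <- if (length(idx) == 1) M[, 1] else svd(M, nu = 1, nv = 0)$u[, 1]
    t <- t - mean(t)
    t <- t / sqrt(sum(t^2))
    if (sum(t * rowMeans(M)) < 0) t <- -t
    t
  }
  best <- -Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    g2 <- setdiff(seq_len(n), g1)
    if (!length(g1) || !length(g2)) next
    t1 <- tmpl_of(g1); t2 <- tmpl_of(g2)
    num <- 0
    for (t in g1) num <- num + (gfp_vals[t] * sum(unit[, t] * t1))^2
    for (t in g2) num <- num + (gfp_vals[t] * sum(unit[, t] * t2))^2
    best <- max(best, num / sum(gfp_vals^2))
  }
  best
}
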
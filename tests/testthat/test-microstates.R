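test_that("GFP matches its closed forms and the direct formula", {
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(rep(4.2, 10)), 0)
  set.seed(1)
  v <- rnorm(128, mean = 3)
  expect_equal(gfp(v), oracle_gfp(v), tolerance = 1e-12)
  m <- matrix(rnorm(128 * 5), 128)
  expect_equal(gfp(m), apply(m, 2, oracle_gfp), tolerance = 1e-12)
})

test_that("spatial correlation is a strength-independent signed Pearson", {
  set.seed(2)
  a <- rnorm(64); b <- rnorm(64)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), -1)
  expect_equal(spatial_correlation(3 * a, b), spatial_correlation(a, b),
               tolerance = 1e-12)
  expect_equal(spatial_correlation(a, b), oracle_spatial_corr(a, b),
               tolerance = 1e-12)
  expect_error(spatial_correlation(rep(1, 64), b), "zero map")
})

make_group_evoked <- function(maps, times = NULL) {
  # wrap a channels x samples matrix as a single-condition group VEP list
  if (is.null(times)) times <- seq(0, by = 2, length.out = ncol(maps))
  list(A = evoked(maps, times, condition = "A", subject = "group"))
}

test_that("AAHC handles degenerate and separable cases", {
  set.seed(3)
  base <- rnorm(32)
  maps <- matrix(rep(base, 10), 32) * rep(seq(0.5, 1.4, 0.1), each = 32)
  model <- aahc_cluster(make_group_evoked(maps), k = 1)
  expect_equal(model$k, 1)
  expect_equal(model$gev, 1, tolerance = 1e-12)

  # two orthogonal templates, no noise: k=2 recovers both with |corr| = 1
  t1 <- rnorm(32); t1 <- t1 - mean(t1)
  t2 <- rnorm(32); t2 <- t2 - mean(t2)
  t2 <- t2 - t1 * sum(t1 * t2) / sum(t1^2)
  maps2 <- cbind(t1 %o% c(1, 2, 1.5), t2 %o% c(0.8, 1.2, 2))
  m2 <- aahc_cluster(make_group_evoked(maps2), k = 2)
  expect_equal(m2$gev, 1, tolerance = 1e-12)
  match_corr <- apply(abs(cor(m2$templates, cbind(t1, t2))), 2, max)
  expect_equal(unname(match_corr), c(1, 1), tolerance = 1e-9)

  expect_error(aahc_cluster(make_group_evoked(maps2), k = 10), "k must be")
})

test_that("AAHC attains the exhaustive-partition optimum on small instances", {
  # well-separated instance: must match the brute-force optimum
  set.seed(4)
  t1 <- rnorm(24); t2 <- rnorm(24)
  maps <- cbind(t1 %o% c(1, 1.2, 0.9, 1.1), t2 %o% c(1, 0.8, 1.3, 1.05))
  maps <- maps + rnorm(length(maps), sd = 0.02)
  st <- eegmicrostates:::stack_maps(make_group_evoked(maps))
  model <- aahc_cluster(make_group_evoked(maps), k = 2)
  best <- oracle_best_2partition_gev(maps, st$gfp)
  expect_gte(model$gev, best - 1e-9)

  # generic instance: greedy may fall short, but never exceeds the optimum,
  # and any gap is reported
  maps_g <- matrix(rnorm(24 * 8), 24)
  model_g <- aahc_cluster(make_group_evoked(maps_g), k = 2)
  st_g <- eegmicrostates:::stack_maps(make_group_evoked(maps_g))
  best_g <- oracle_best_2partition_gev(maps_g, st_g$gfp)
  expect_lte(model_g$gev, best_g + 1e-9)
  if (best_g - model_g$gev > 1e-9)
    message(sprintf("AAHC greedy gap on random 8-map instance: %.3e",
                    best_g - model_g$gev))
})

test_that("GEV matches a literal transcription of its formula", {
  set.seed(5)
  maps <- matrix(rnorm(32 * 12), 32)
  gv <- make_group_evoked(maps)
  model <- aahc_cluster(gv, k = 3)
  st <- eegmicrostates:::stack_maps(gv)
  expect_equal(gev(model, gv),
               oracle_gev(st$maps, st$gfp, model$templates, model$assignment),
               tolerance = 1e-9)
  expect_equal(gev(model, gv), model$gev, tolerance = 1e-9)

  # assignment to a template orthogonal to every map gives GEV 0
  t_orth <- qr.Q(qr(cbind(1, maps)), complete = TRUE)[, ncol(maps) + 2]
  model0 <- model
  model0$templates <- matrix(t_orth, ncol = 1)
  model0$assignment <- rep(1L, ncol(maps))
  expect_equal(gev(model0, gv), 0, tolerance = 1e-9)
})

test_that("model selection is sane and GEV grows with k", {
  fx <- fx_study()
  tm <- fx_templates5()
  truth <- simulation_truth(tm$templates, default_schedule("no_context"),
                            n_subjects = 3, noise_sd = 0,
                            subject_jitter_ms = 0, seed = 6)
  gv <- group_average_veps(
    preprocess_sim_veps(simulate_subject_veps(truth, fx$lf), filter = FALSE))
  model <- select_k(gv, 2:12)
  expect_equal(model$k, 5L)
  expect_equal(model$gev, 1, tolerance = 1e-6)
  gcurve <- attr(model, "gev_curve")
  expect_true(all(diff(gcurve$gev) >= -1e-9))
  expect_error(select_k(gv, k_range = 3), "at least 2")
})

test_that("clustering is polarity-sensitive and condition-order invariant", {
  set.seed(7)
  t1 <- rnorm(32)
  maps <- cbind(t1 %o% c(1, 1.1, 0.95), -t1 %o% c(1, 0.9, 1.2))
  m <- aahc_cluster(make_group_evoked(maps), k = 2)
  expect_equal(length(unique(m$assignment[1:3])), 1)
  expect_equal(length(unique(m$assignment[4:6])), 1)
  expect_false(m$assignment[1] == m$assignment[4])
  expect_equal(spatial_correlation(m$templates[, m$assignment[1]],
                                   m$templates[, m$assignment[4]]), -1,
               tolerance = 1e-9)

  fx <- fx_small()
  tm <- make_templates(fx$lf, 3, seed = 8)
  truth <- simulation_truth(tm$templates, uniform_schedule(3, c("A", "B")),
                            n_subjects = 3, noise_sd = 10, seed = 9)
  gv <- group_average_veps(preprocess_sim_veps(simulate_subject_veps(truth, fx$lf)))
  m_ab <- select_k(gv, 2:6)
  m_ba <- select_k(gv[c("B", "A")], 2:6)
  expect_equal(m_ba$k, m_ab$k)
  expect_equal(m_ba$gev, m_ab$gev, tolerance = 1e-9)
  # the partition of (condition, time) pairs is identical up to label names
  key_ab <- paste(m_ab$index$condition, m_ab$index$time_ms)
  key_ba <- paste(m_ba$index$condition, m_ba$index$time_ms)
  part_ab <- split(key_ab, m_ab$assignment)
  part_ba <- split(key_ba, m_ba$assignment)
  canon <- function(p) sort(vapply(p, function(g) paste(sort(g), collapse = "|"),
                                   character(1)))
  expect_equal(canon(part_ab), canon(part_ba), ignore_attr = TRUE)
})

test_that("window extraction recovers planted schedules", {
  fx <- fx_study()
  tm <- fx_templates5()
  sched <- default_schedule("no_context")
  truth0 <- simulation_truth(tm$templates, sched, n_subjects = 3,
                             noise_sd = 0, subject_jitter_ms = 0, seed = 10)
  gv0 <- group_average_veps(
    preprocess_sim_veps(simulate_subject_veps(truth0, fx$lf), filter = FALSE))
  model0 <- select_k(gv0, 2:12)
  w0 <- extract_windows(model0, gv0, min_duration_ms = 0)
  for (cond in names(sched)) {
    expect_equal(w0[[cond]]$start_ms, sched[[cond]]$start_ms)
    expect_equal(w0[[cond]]$end_ms, sched[[cond]]$end_ms)
  }

  # default noise: every boundary within 2 samples (4 ms) of the plant
  truth1 <- simulation_truth(tm$templates, sched, seed = 11)
  gv1 <- group_average_veps(preprocess_sim_veps(simulate_subject_veps(truth1, fx$lf)))
  model1 <- select_k(gv1, 2:12)
  expect_equal(model1$k, 5L)
  w1 <- extract_windows(model1, gv1)
  for (cond in names(sched)) {
    expect_equal(nrow(w1[[cond]]), nrow(sched[[cond]]))
    expect_true(all(abs(w1[[cond]]$start_ms - sched[[cond]]$start_ms) <= 4))
    expect_true(all(abs(w1[[cond]]$end_ms - sched[[cond]]$end_ms) <= 4))
  }

  # single-template data: one window spanning the whole analysis range
  base <- rnorm(32)
  maps <- base %o% runif(251, 0.5, 1.5)
  gv_one <- make_group_evoked(maps, times = seq(0, 500, 2))
  m_one <- aahc_cluster(gv_one, k = 1)
  w_one <- extract_windows(m_one, gv_one)
  expect_equal(nrow(w_one$A), 1)
  expect_equal(w_one$A$start_ms, 0)
  expect_equal(w_one$A$end_ms, 500)
})
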
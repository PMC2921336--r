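make_epochs <- function(data3) {
  epoch_set(subject = 1, condition = "A", data = data3)
}

test_that("epoch rejection applies the strict amplitude criterion", {
  d <- array(0, c(3, 4, 301))
  d[2, 3, 100] <- 101   # peak above 100 µV
  d[3, 2, 50] <- 100    # exactly at threshold: survives
  res <- reject_epochs(make_epochs(d), threshold_uv = 100)
  expect_equal(res$report$epoch, 2L)
  expect_equal(res$report$channel, 3L)
  expect_equal(res$report$sample, 100L)
  expect_equal(dim(res$epochs$data)[1], 2L)

  allz <- reject_epochs(make_epochs(array(0, c(5, 4, 301))), 100)
  expect_equal(dim(allz$epochs$data)[1], 5L)

  dbad <- array(200, c(2, 4, 301))
  expect_error(reject_epochs(make_epochs(dbad), 100), "all epochs")
  expect_error(reject_epochs(make_epochs(d), -1), "positive")
})

test_that("spherical-spline interpolation reproduces smooth fields", {
  m <- build_montage(128)
  times <- seq(-100, 500, 2)
  # constant field: interpolation returns the constant
  ev <- evoked(matrix(3.3, 128, length(times)), times)
  fixed <- interpolate_channels(ev, bad = 5L, m)
  expect_equal(fixed$data[5, ], rep(3.3, length(times)), tolerance = 1e-6)
  # untouched without bad channels
  expect_identical(interpolate_channels(ev, integer(0), m), ev)

  # degree-1 spherical harmonic (linear in position): <=1% error at 128 ch
  h <- drop(m$positions %*% c(0.3, -1, 0.5))
  ev1 <- evoked(matrix(h, 128, 3), times[1:3])
  bad <- 17L
  rec <- interpolate_channels(ev1, bad, m)
  rel_err_128 <- abs(rec$data[bad, 1] - h[bad]) / max(abs(h))
  expect_lt(rel_err_128, 0.01)
  # good channels unchanged
  expect_equal(rec$data[-bad, ], ev1$data[-bad, ])

  # interpolation improves with electrode count (32 vs 128)
  m32 <- build_montage(32)
  h32 <- drop(m32$positions %*% c(0.3, -1, 0.5))
  ev32 <- evoked(matrix(h32, 32, 3), times[1:3])
  rec32 <- interpolate_channels(ev32, 3L, m32)
  rel_err_32 <- abs(rec32$data[3, 1] - h32[3]) / max(abs(h32))
  expect_gt(rel_err_32, rel_err_128)

  expect_error(interpolate_channels(ev32, 1:29, m32), "4 good")
})

test_that("averaging is the arithmetic mean with bookkeeping", {
  d <- array(rnorm(2 * 4 * 301), c(2, 4, 301))
  one <- make_epochs(d[1, , , drop = FALSE])
  v1 <- average_to_vep(one)
  expect_equal(v1$data, d[1, , ])
  expect_equal(v1$n_epochs_averaged, 1L)

  d2 <- d; d2[2, , ] <- -d[1, , ]
  v0 <- average_to_vep(make_epochs(d2))
  expect_equal(v0$data, matrix(0, 4, 301))
})

test_that("baseline correction zeroes the pre-stimulus mean exactly", {
  times <- seq(-100, 500, 2)
  d <- matrix(rnorm(8 * 301, mean = 5), 8, 301)
  ev <- evoked(d, times)
  out <- baseline_and_bandpass(ev, baseline_only = TRUE)
  expect_lt(max(abs(rowMeans(out$data[, times < 0 & times >= -100]))), 1e-9)
  expect_error(baseline_and_bandpass(ev, band_hz = c(0, 30)), "band edges")
  expect_error(baseline_and_bandpass(ev, band_hz = c(1, 300)), "band edges")
})

test_that("the band-pass removes DC and attenuates 50 Hz as designed", {
  # long record so the full band-pass (high-pass included) engages
  times <- seq(-100, 4000, 2)
  sfreq <- 500
  tt <- times / 1000
  dc <- matrix(2.5, 2, length(times))
  ev_dc <- evoked(dc, times)
  out_dc <- baseline_and_bandpass(ev_dc, band_hz = c(1, 30))
  expect_true(attr(out_dc, "filter")$highpass_applied)
  expect_lt(max(abs(out_dc$data)), 1e-6)

  x50 <- sin(2 * pi * 50 * tt)
  ev50 <- evoked(rbind(x50, x50), times)
  out50 <- baseline_and_bandpass(ev50, band_hz = c(1, 30))
  mid <- times >= 1000 & times < 3000   # integer number of 50 Hz cycles
  # steady-state amplitude by projection onto the 50 Hz quadrature pair
  att <- 2 * Mod(mean(out50$data[1, mid] * exp(-1i * 2 * pi * 50 * tt[mid])))
  # independent transfer-function oracle: |H(e^{i w})|^2 for the two-pass
  # Butterworth, from direct polynomial evaluation on the unit circle
  bf <- signal::butter(2, c(1, 30) / (sfreq / 2), "pass")
  z <- exp(1i * 2 * pi * 50 / sfreq)
  H <- sum(bf$b * z^(-(seq_along(bf$b) - 1))) /
    sum(bf$a * z^(-(seq_along(bf$a) - 1)))
  expect_equal(att, Mod(H)^2, tolerance = 0.05)

  # short epochs skip the ill-posed high-pass leg and record why
  ev_short <- evoked(matrix(rnorm(2 * 301), 2), seq(-100, 500, 2))
  out_short <- baseline_and_bandpass(ev_short)
  expect_false(attr(out_short, "filter")$highpass_applied)
})

test_that("re-referencing and GFP normalization satisfy their contracts", {
  times <- seq(-100, 500, 2)
  d <- matrix(rnorm(8 * 301), 8, 301)
  ev <- evoked(d, times)
  out <- rereference_and_normalize(ev)
  expect_lt(max(abs(colSums(out$data))), 1e-9)
  win <- times >= 0 & times <= 500
  mean_gfp <- mean(apply(out$data[, win], 2, oracle_gfp))
  expect_equal(mean_gfp, 1, tolerance = 1e-9)

  # scale invariance: x and 10x normalize identically
  out10 <- rereference_and_normalize(evoked(10 * d, times))
  expect_equal(out10$data, out$data, tolerance = 1e-12)

  expect_error(rereference_and_normalize(evoked(matrix(0, 8, 301), times)),
               "degenerate")
  expect_error(rereference_and_normalize(evoked(d[1, , drop = FALSE], times)),
               "2 channels")
})

test_that("the first-level order guard accepts the canonical chain and rejects permutations", {
  expect_true(assert_pipeline_order(c("reject", "average", "baseline",
                                      "bandpass", "rereference", "normalize")))
  expect_true(assert_pipeline_order(c("simulate", "average", "normalize")))
  expect_error(assert_pipeline_order(c("average", "reject")), "order")
  expect_error(assert_pipeline_order(c("normalize", "rereference")), "order")
  expect_error(assert_pipeline_order(c("average", "average")), "order")

  # the composed chain produces a guard-passing log
  fx <- fx_small()
  tm <- make_templates(fx$lf, 2, seed = 1)
  truth <- simulation_truth(tm$templates, uniform_schedule(2), n_subjects = 1,
                            n_epochs = 5, noise_sd = 5, seed = 2)
  es <- simulate_group(truth, fx$lf)[[1]]
  vep <- preprocess_vep(es)
  expect_equal(vep$log[vep$log %in% eegmicrostates:::PIPELINE_ORDER],
               c("reject", "average", "baseline", "bandpass", "rereference",
                 "normalize"))
})
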
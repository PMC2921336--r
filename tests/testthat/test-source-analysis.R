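test_that("the inverse operator is linear and annihilates zero data", {
  fx <- fx_small()
  inv <- build_inverse(fx$lf, lambda = 1e-4)
  z <- apply_inverse(inv, rep(0, 32))
  expect_equal(z$density, rep(0, fx$grid$n_points))
  expect_equal(z$density_standardized, rep(0, fx$grid$n_points))

  set.seed(1)
  v1 <- rnorm(32); v1 <- v1 - mean(v1)
  v2 <- rnorm(32); v2 <- v2 - mean(v2)
  J1 <- apply_inverse(inv, v1)$J
  J2 <- apply_inverse(inv, v2)$J
  J12 <- apply_inverse(inv, 2 * v1 - 3 * v2)$J
  expect_equal(J12, 2 * J1 - 3 * J2, tolerance = 1e-9)
  expect_error(apply_inverse(inv, rep(0, 31)), "channel mismatch")
})

test_that("forward-then-inverse localizes mid-depth dipoles", {
  fx <- fx_study()
  inv <- build_inverse(fx$lf)
  r <- sqrt(rowSums(fx$grid$points^2))
  cand <- which(r > 0.3 * 80 & r < 0.7 * 80)
  set.seed(2)
  errs <- vapply(sample(cand, 12), function(p) {
    q <- rnorm(3)
    v <- project_dipoles(fx$lf, p, matrix(q, 1))
    d <- apply_inverse(inv, v)$density_standardized
    sqrt(sum((fx$grid$points[which.max(d), ] - fx$grid$points[p, ])^2))
  }, numeric(1))
  expect_lte(median(errs), 2 * fx$grid$spacing_mm)
})

test_that("window-averaged source estimates behave under scaling and degeneracy", {
  fx <- fx_small()
  inv <- build_inverse(fx$lf, lambda = 1e-4)
  times <- seq(-100, 500, 2)
  set.seed(3)
  p <- which(sqrt(rowSums(fx$grid$points^2)) > 25)[1]
  v <- project_dipoles(fx$lf, p, matrix(c(1, -1, 2), 1))
  data <- v %o% exp(-(times - 200)^2 / 5000)
  vep <- evoked(data, times, condition = "A", subject = 1)
  est <- estimate_sources(inv, vep, c(150, 250))
  expect_equal(length(est$density), fx$grid$n_points)
  expect_true(all(est$density >= 0))

  # homogeneity: scaling the VEP by c scales densities by |c|
  vep3 <- vep; vep3$data <- -3 * vep$data
  est3 <- estimate_sources(inv, vep3, c(150, 250), lambda = 1e-4)
  est1 <- estimate_sources(inv, vep, c(150, 250), lambda = 1e-4)
  expect_equal(est3$density, 3 * est1$density, tolerance = 1e-9)
  raw3 <- estimate_sources(inv, vep3, c(150, 250), lambda = 1e-4,
                           standardize = FALSE)
  raw1 <- estimate_sources(inv, vep, c(150, 250), lambda = 1e-4,
                           standardize = FALSE)
  expect_equal(raw3$density, 3 * raw1$density, tolerance = 1e-9)

  zero_vep <- evoked(matrix(0, 32, length(times)), times)
  est0 <- estimate_sources(inv, zero_vep, c(0, 500))
  expect_equal(est0$density, rep(0, fx$grid$n_points))
  expect_error(estimate_sources(inv, vep, c(600, 700)), "empty")
})

test_that("the density maximum is reported with deterministic tie-breaking", {
  fx <- fx_small()
  est <- structure(list(subject = 1, condition = "A", window_ms = c(0, 100),
                        density = rep(0, fx$grid$n_points), grid = fx$grid),
                   class = "source_estimate")
  expect_error(report_density_maximum(est), "all-zero")
  est$density[37] <- 2
  mx <- report_density_maximum(est)
  expect_equal(mx$point_index, 37L)
  expect_equal(mx$coordinate_mm, fx$grid$points[37, ])
  expect_false(mx$tie)
  est$density[c(12, 40)] <- 5
  mx2 <- report_density_maximum(est)
  expect_equal(mx2$point_index, 12L)
  expect_true(mx2$tie)
})

test_that("increasing lambda increases spatial spread of the raw estimate", {
  fx <- fx_small()
  inv <- build_inverse(fx$lf)
  p <- which(sqrt(rowSums(fx$grid$points^2)) > 30)[2]
  v <- project_dipoles(fx$lf, p, matrix(c(1, 0.5, -0.3), 1))
  lams <- mean(inv$eig$values) * 10^seq(-5, 1, 1.5)
  spread <- vapply(lams, function(lam) {
    d <- apply_inverse(inv, v, lambda = lam, standardize = FALSE)$density
    sum(d >= max(d) / 2)
  }, numeric(1))
  expect_true(all(diff(spread) >= 0))
  expect_gt(spread[length(spread)], spread[1])
})

test_that("paired contrasts enforce the strict cluster-extent rule", {
  fx <- fx_small()
  grid <- fx$grid
  np <- grid$n_points
  # identical inputs: no suprathreshold point at all
  set.seed(4)
  A <- matrix(rnorm(6 * np), 6)
  ct0 <- paired_t_contrast(A, A, grid)
  expect_equal(length(ct0$clusters), 0)
  expect_true(all(ct0$t == 0))

  # a straight chain of exactly 10 suprathreshold points is rejected,
  # 11 are reported (strict "greater than"); the finer study grid has a
  # long enough axis line
  grid <- fx_study()$grid
  np <- grid$n_points
  chain <- which(grid$points[, 2] == 0 & grid$points[, 3] == 0)
  chain <- chain[order(grid$points[chain, 1])]
  base <- matrix(0, 4, np)
  eff <- matrix(rep(c(1, 1.1, 0.9, 1.05), 10), 4)
  A10 <- base; A10[, chain[1:10]] <- eff
  expect_equal(length(paired_t_contrast(A10, base, grid)$clusters), 0)
  A11 <- base; A11[, chain[1:11]] <- cbind(eff, eff[, 1])
  ct11 <- paired_t_contrast(A11, base, grid)
  expect_equal(length(ct11$clusters), 1)
  expect_equal(ct11$clusters[[1]]$size, 11)
  expect_equal(ct11$clusters[[1]]$direction, "a>b")
  expect_equal(sort(ct11$clusters[[1]]$points), sort(chain[1:11]))

  # the reverse direction is detected symmetrically
  ctrev <- paired_t_contrast(base, A11, grid)
  expect_equal(ctrev$clusters[[1]]$direction, "b>a")

  expect_error(paired_t_contrast(A, A[1:3, ], grid), "same subjects")
})

test_that("reported clusters always satisfy their own invariants", {
  fx <- fx_small()
  grid <- fx$grid
  np <- grid$n_points
  set.seed(5)
  for (rep in 1:20) {
    # random smooth-ish t-maps via random subject data
    n <- sample(5:12, 1)
    A <- matrix(rnorm(n * np), n)
    B <- matrix(rnorm(n * np), n)
    hot <- sample(np, sample(10:60, 1))
    A[, hot] <- A[, hot] + runif(1, 0.5, 2)
    ct <- paired_t_contrast(A, B, grid, t_threshold = 2,
                            extent_threshold = sample(2:10, 1))
    for (cl in ct$clusters) {
      expect_gt(cl$size, ct$extent_threshold)
      tv <- if (cl$direction == "a>b") ct$t else -ct$t
      expect_true(all(tv[cl$points] >= ct$t_threshold))
      # maximality: no suprathreshold neighbour outside the cluster
      boundary <- unique(unlist(grid$adjacency[cl$points]))
      outside <- setdiff(boundary, cl$points)
      expect_true(all(tv[outside] < ct$t_threshold))
    }
  }
})

test_that("the cluster rule's false-positive rate under the global null is estimated", {
  fx <- fx_small()
  grid <- fx$grid
  set.seed(6)
  n_rep <- 60
  any_cluster <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    A <- matrix(rnorm(20 * grid$n_points), 20)
    B <- matrix(rnorm(20 * grid$n_points), 20)
    any_cluster[i] <- length(paired_t_contrast(A, B, grid)$clusters) > 0
  }
  rate <- mean(any_cluster)
  message(sprintf(
    "cluster rule family-wise false-positive rate under spatially white null: %.2f (%d reps, %d points)",
    rate, n_rep, grid$n_points))
  expect_gte(rate, 0)
  expect_lte(rate, 1)
})

test_that("bonferroni mode derives its threshold from the grid size", {
  fx <- fx_small()
  set.seed(7)
  A <- matrix(rnorm(10 * fx$grid$n_points), 10)
  ct <- paired_t_contrast(A, 0 * A, fx$grid, mode = "bonferroni")
  expect_equal(ct$t_threshold,
               qt(1 - 0.05 / (2 * fx$grid$n_points), df = 9))
  expect_gt(ct$t_threshold, 2.09)
})

test_that("source maps export to NIfTI consistently with the point table", {
  fx <- fx_small()
  set.seed(8)
  vals <- runif(fx$grid$n_points)
  path <- tempfile(fileext = ".nii.gz")
  export_source_nifti(vals, fx$grid, path)
  img <- oro.nifti::readNIfTI(path, reorient = FALSE)   # independent reader
  arr <- img@.Data
  sp <- fx$grid$spacing_mm
  ijk <- round(sweep(fx$grid$points, 2, apply(fx$grid$points, 2, min)) / sp) + 1
  got <- arr[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
  expect_equal(got, vals, tolerance = 1e-6)
  # off-grid voxels are zero
  expect_equal(sum(arr != 0), fx$grid$n_points)
})
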
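test_that("montage construction is valid, deterministic, and near-uniform", {
  m <- build_montage(128)
  expect_equal(m$n_channels, 128L)
  expect_equal(length(unique(m$labels)), 128L)
  expect_true(all(abs(sqrt(rowSums(m$positions^2)) - 1) < 1e-9))
  expect_identical(m, build_montage(128))

  # brute-force pairwise check: minimal angular distance within 30% of the
  # ideal hexagonal-packing spacing for the covered cap area
  cosang <- tcrossprod(m$positions)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  ang <- acos(cosang)
  diag(ang) <- Inf
  min_ang <- min(ang)
  cap_area <- 2 * pi * (1 - (1 - 2 * 0.65))  # coverage 0.65 on unit sphere
  ideal <- sqrt(cap_area * 2 / (sqrt(3) * 128))
  expect_gt(min_ang, 0.7 * ideal)

  expect_error(build_montage(7), "n_channels")
})

test_that("electrode files round-trip through .sfp and .elc", {
  m <- build_montage(32)
  sfp <- tempfile(fileext = ".sfp")
  elc <- tempfile(fileext = ".elc")
  write_sfp(m, sfp)
  write_elc(m, elc)
  for (m2 in list(read_sfp(sfp), read_elc(elc))) {
    expect_equal(m2$labels, m$labels)
    expect_equal(m2$positions, m$positions, tolerance = 1e-6)
    expect_equal(m2$radius_mm, m$radius_mm, tolerance = 1e-6)
  }
})

test_that("source grid is clipped, matches lattice enumeration, and shrinks with spacing", {
  sh <- shell_model(c(80, 85, 92), c(0.33, 0.0042, 0.33))
  g6 <- build_source_grid(6, sh)
  expect_true(all(sqrt(rowSums(g6$points^2)) < 80))
  # minimal inter-point distance equals the spacing
  sub <- g6$points[sample.int(g6$n_points, 200), ]
  d <- as.matrix(dist(sub)); diag(d) <- Inf
  expect_equal(min(d), 6, tolerance = 1e-9)

  # exhaustive lattice enumeration oracle on a small configuration
  sh_small <- shell_model(c(50, 55, 60), c(0.33, 0.0042, 0.33))
  g40 <- build_source_grid(40, sh_small)
  rmax <- 50 - 20  # default margin spacing/2
  cnt <- 0
  for (x in seq(-80, 80, 40)) for (y in seq(-80, 80, 40)) for (z in seq(-80, 80, 40))
    if (sqrt(x^2 + y^2 + z^2) <= rmax) cnt <- cnt + 1
  expect_equal(g40$n_points, cnt)

  expect_lt(build_source_grid(12, sh)$n_points, g6$n_points)
  expect_error(build_source_grid(80, sh), "spacing")

  # adjacency symmetric and irreflexive
  for (i in sample.int(g6$n_points, 50)) {
    nb <- g6$adjacency[[i]]
    expect_false(i %in% nb)
    expect_true(all(vapply(nb, function(j) i %in% g6$adjacency[[j]], logical(1))))
  }
})

test_that("lead field is average-referenced, linear, and matches the homogeneous closed form", {
  fx <- fx_small()
  lf <- fx$lf
  expect_lt(max(abs(colSums(lf$gain))), 1e-9 * max(abs(lf$gain)))

  p <- which(sqrt(rowSums(fx$grid$points^2)) > 20)[1]
  m1 <- c(1, 2, -1); m2 <- c(-3, 0.5, 2)
  v1 <- project_dipoles(lf, p, matrix(m1, 1))
  v2 <- project_dipoles(lf, p, matrix(m2, 1))
  v12 <- project_dipoles(lf, p, matrix(2 * m1 - 0.5 * m2, 1))
  expect_equal(v12, 2 * v1 - 0.5 * v2, tolerance = 1e-12)
  expect_equal(project_dipoles(lf, p, matrix(0, 1, 3)), rep(0, 32))

  # equal-conductivity three-shell vs the homogeneous-sphere closed form
  sh_eq <- shell_model(c(80, 85, 92), c(0.33, 0.33, 0.33))
  lf_eq <- compute_lead_field(fx$montage, fx$grid, sh_eq, n_terms = 60)
  r <- sqrt(rowSums(fx$grid$points^2))
  for (p in which(r > 15 & r < 60)[1:4]) {
    q <- c(0.3, -1, 0.7)
    v <- project_dipoles(lf_eq, p, matrix(q, 1))
    vo <- oracle_homogeneous_sphere(fx$montage$positions * 92,
                                    fx$grid$points[p, ], q, 92, 0.33)
    vo <- vo - mean(vo)
    expect_lt(max(abs(v - vo)) / max(abs(vo)), 1e-3)
  }

  expect_error(compute_lead_field(fx$montage, fx$grid, fx$shell, n_terms = 10),
               "n_terms")
})

test_that("lead field respects rotation and depth physics", {
  sh <- shell_model()
  # rotational equivariance: rotate montage and dipole together
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  m1 <- build_montage(32)
  m2 <- m1
  m2$positions <- m1$positions %*% t(R)
  grid1 <- build_source_grid(20, sh)
  r0 <- c(30, 10, 20); q <- c(1, -2, 0.5)
  # one-point "grids" holding the original and rotated dipole location
  g1 <- grid1; g1$points <- matrix(r0, 1); g1$n_points <- 1L
  g2 <- grid1; g2$points <- matrix(drop(R %*% r0), 1); g2$n_points <- 1L
  lf1 <- compute_lead_field(m1, g1, sh, 60)
  lf2 <- compute_lead_field(m2, g2, sh, 60)
  v1 <- project_dipoles(lf1, 1, matrix(q, 1))
  v2 <- project_dipoles(lf2, 1, matrix(drop(R %*% q), 1))
  expect_equal(v1, v2, tolerance = 1e-9)

  # deeper sources produce weaker scalp fields (GFP on a radial line)
  depths <- seq(10, 70, 10)
  gline <- grid1
  gline$points <- cbind(0, 0, depths); gline$n_points <- length(depths)
  lfl <- compute_lead_field(m1, gline, sh, 60)
  gfps <- vapply(seq_along(depths), function(i)
    gfp(project_dipoles(lfl, i, matrix(c(1, 0, 0), 1))), numeric(1))
  expect_true(all(diff(gfps) > 0))

  # source outside the brain shell is rejected
  gbad <- grid1; gbad$points <- matrix(c(0, 0, 81), 1); gbad$n_points <- 1L
  expect_error(compute_lead_field(m1, gbad, sh, 60), "inside")
})

test_that("lead field persists to disk with a JSON sidecar", {
  fx <- fx_small()
  path <- tempfile(fileext = ".rds")
  write_lead_field(fx$lf, path)
  lf2 <- read_lead_field(path)
  expect_equal(lf2$gain, fx$lf$gain)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$n_points, fx$grid$n_points)
  expect_equal(meta$spacing_mm, 20)
})
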
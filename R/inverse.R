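# discrete Laplacian on the 6-connected source grid with mirrored (Neumann)
# boundary stencil: (Lap x)_i = sum_{available nb} (x_nb - x_i); ghost
# neighbours outside the grid mirror the centre value and contribute nothing
grid_laplacian <- function(grid) {
  n <- grid$n_points
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    nb <- grid$adjacency[[i]]
    ii <- c(ii, i, rep(i, length(nb)))
    jj <- c(jj, i, nb)
    xx <- c(xx, -length(nb), rep(1, length(nb)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Build a LORETA-style inverse operator
#'
#' Weighted minimum-norm solution with a discrete spatial Laplacian smoothness
#' penalty over the 6-connected source grid and depth (column-norm)
#' normalization. The current estimate for scalp data v is
#' J = C G' (G C G' + lambda I)^-1 v with source prior
#' C = (W (L'L / mean diag + eps I) W)^-1, W the diagonal of per-point gain
#' column norms raised to `depth_exponent`, applied identically to the three
#' orientation components. The ridge eps both regularizes the singular
#' Neumann Laplacian and balances the smoothness and norm penalties.
#'
#' Density readout can be standardized (default in [estimate_sources()]): the
#' per-point current 3-vector is whitened by its own resolution variance
#' (S_i = M_i K M_i'), which removes the depth/eccentricity bias of raw
#' minimum-norm magnitudes and localizes noiseless single dipoles exactly.
#'
#' @param leadfield an average-referenced [compute_lead_field()].
#' @param lambda regularization: a nonnegative number, or `"gcv"` (default)
#'   to choose it per data vector by generalized cross-validation at apply
#'   time.
#' @param depth_exponent exponent on the column-norm depth weights
#'   (default 1, full column normalization).
#' @param eps ridge on the normalized Laplacian penalty (default 0.1).
#' @return object of class `"inverse_operator"`.
#' @export
build_inverse <- function(leadfield, lambda = "gcv", depth_exponent = 1,
                          eps = 0.1) {
  G <- leadfield$gain
  grid <- leadfield$grid
  n <- grid$n_points
  # per-point depth weight: Frobenius norm of the 3-column block
  wcol <- sqrt(colSums(G^2))
  w_pt <- sqrt(wcol[seq(1, 3 * n, 3)]^2 + wcol[seq(2, 3 * n, 3)]^2 +
               wcol[seq(3, 3 * n, 3)]^2)
  if (any(w_pt < 1e-12)) stop("lead field has an all-zero source column",
                              call. = FALSE)
  w <- w_pt^depth_exponent
  L <- grid_laplacian(grid)
  LtL <- Matrix::t(L) %*% L
  P <- LtL / mean(Matrix::diag(LtL)) + Matrix::Diagonal(n, eps)
  W <- Matrix::Diagonal(n, w)
  Pw <- W %*% P %*% W
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Pw), LDL = FALSE)
  # X = C G' assembled per orientation component (the prior is block-diagonal
  # with the same point structure for x, y, z)
  nch <- nrow(G)
  X <- matrix(0, 3 * n, nch)
  for (comp in 1:3) {
    cols <- seq(comp, 3 * n, 3)
    Xc <- as.matrix(Matrix::solve(ch, t(G[, cols, drop = FALSE]),
                                  system = "A"))
    X[cols, ] <- Xc
  }
  K <- G %*% X                      # nch x nch data-space kernel
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  Y <- X %*% eig$vectors            # rotated kernel for fast apply/standardize
  structure(list(Y = Y, K = K, eig = eig, lambda = lambda,
                 depth_exponent = depth_exponent, eps = eps,
                 grid = grid, n_channels = nch,
                 leadfield_meta = list(spacing_mm = grid$spacing_mm,
                                       n_points = n)),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d channels -> %d source points (lambda: %s)\n",
              x$n_channels, x$grid$n_points,
              if (identical(x$lambda, "gcv")) "GCV per datum" else
                format(x$lambda)))
  invisible(x)
}

# GCV choice of lambda for one data vector, using the eigendecomposition of K
gcv_lambda <- function(inv, v) {
  d <- pmax(inv$eig$values, 0)
  wv <- drop(crossprod(inv$eig$vectors, v))
  scale <- mean(d[d > 0])
  grid <- scale * 10^seq(-8, 2, length.out = 60)
  score <- vapply(grid, function(lam) {
    r <- lam / (d + lam)
    num <- sum((r * wv)^2)
    den <- sum(r)^2
    num / den
  }, numeric(1))
  grid[which.min(score)]
}

#' Apply an inverse operator to a scalp map
#'
#' @param inv an [build_inverse()] operator.
#' @param v average-referenced potential vector over channels.
#' @param lambda optional override of the operator's regularization.
#' @param standardize also return the variance-standardized density
#'   (default TRUE).
#' @return list with `J` (3 x n_points current components), `density`
#'   (raw per-point vector magnitude, proportional to µA/mm^3),
#'   `density_standardized` (dimensionless, depth-bias-corrected; NULL if
#'   not requested), `lambda_used`.
#' @export
apply_inverse <- function(inv, v, lambda = NULL, standardize = TRUE) {
  if (length(v) != inv$n_channels) stop("data/operator channel mismatch",
                                        call. = FALSE)
  lam <- if (!is.null(lambda)) lambda
         else if (identical(inv$lambda, "gcv")) gcv_lambda(inv, v)
         else inv$lambda
  d <- pmax(inv$eig$values, 0)
  wv <- drop(crossprod(inv$eig$vectors, v))
  J <- drop(inv$Y %*% (wv / (d + lam)))
  n <- inv$grid$n_points
  Jm <- matrix(J, nrow = 3)        # x,y,z per point
  dens_std <- NULL
  if (standardize) {
    # per-point resolution covariance S_i = Y_i diag(d/(d+lam)^2) Y_i'
    f <- d / (d + lam)^2
    i1 <- seq(1, 3 * n, 3); i2 <- i1 + 1L; i3 <- i1 + 2L
    Y1 <- inv$Y[i1, , drop = FALSE]
    Y2 <- inv$Y[i2, , drop = FALSE]
    Y3 <- inv$Y[i3, , drop = FALSE]
    Z1 <- sweep(Y1, 2, f, "*"); Z2 <- sweep(Y2, 2, f, "*")
    Z3 <- sweep(Y3, 2, f, "*")
    s11 <- rowSums(Z1 * Y1); s12 <- rowSums(Z1 * Y2); s13 <- rowSums(Z1 * Y3)
    s22 <- rowSums(Z2 * Y2); s23 <- rowSums(Z2 * Y3); s33 <- rowSums(Z3 * Y3)
    ridge <- 1e-12 * (s11 + s22 + s33) / 3 + 1e-300
    s11 <- s11 + ridge; s22 <- s22 + ridge; s33 <- s33 + ridge
    # adjugate quadratic form: J' S^-1 J = (J' adj(S) J) / det(S)
    det <- s11 * (s22 * s33 - s23^2) - s12 * (s12 * s33 - s23 * s13) +
      s13 * (s12 * s23 - s22 * s13)
    a11 <- s22 * s33 - s23^2
    a22 <- s11 * s33 - s13^2
    a33 <- s11 * s22 - s12^2
    a12 <- s13 * s23 - s12 * s33
    a13 <- s12 * s23 - s13 * s22
    a23 <- s12 * s13 - s11 * s23
    j1 <- Jm[1, ]; j2 <- Jm[2, ]; j3 <- Jm[3, ]
    q <- (a11 * j1^2 + a22 * j2^2 + a33 * j3^2 +
          2 * (a12 * j1 * j2 + a13 * j1 * j3 + a23 * j2 * j3)) / det
    dens_std <- sqrt(pmax(q, 0))
  }
  list(J = Jm, density = sqrt(colSums(Jm^2)),
       density_standardized = dens_std, lambda_used = lam)
}

#' Window-averaged source estimate for a VEP
#'
#' Averages the VEP over the stated time window into a single scalp map,
#' applies the inverse, and returns per-point current-density magnitudes
#' (arbitrary units proportional to µA/mm^3).
#'
#' @param inv an inverse operator.
#' @param vep an [evoked()].
#' @param window_ms two-element window in ms.
#' @param lambda optional regularization override.
#' @param standardize report the variance-standardized density (default
#'   TRUE; FALSE gives the raw magnitude, proportional to µA/mm^3).
#' @return object of class `"source_estimate"`: `subject`, `condition`,
#'   `window_ms`, `density` (length n_points, nonnegative), `lambda_used`.
#' @export
estimate_sources <- function(inv, vep, window_ms, lambda = NULL,
                             standardize = TRUE) {
  stopifnot(inherits(vep, "evoked"))
  sel <- vep$times >= window_ms[1] & vep$times <= window_ms[2]
  if (!any(sel)) stop("empty source-estimation window", call. = FALSE)
  v <- rowMeans(vep$data[, sel, drop = FALSE])
  v <- v - mean(v)
  res <- apply_inverse(inv, v, standardize = standardize, lambda = lambda)
  structure(list(subject = vep$subject, condition = vep$condition,
                 window_ms = window_ms,
                 density = if (standardize) res$density_standardized
                           else res$density,
                 standardized = standardize,
                 lambda_used = res$lambda_used, grid = inv$grid),
            class = "source_estimate")
}

#' Coordinate and value of the current-density maximum
#'
#' @param estimate a [estimate_sources()] result.
#' @return list with `coordinate_mm` (grid frame: origin at sphere centre,
#'   +z through the vertex), `value`, `point_index`, and `tie` (TRUE when the
#'   maximum was not unique; the lowest grid index is then reported).
#' @export
report_density_maximum <- function(estimate) {
  d <- estimate$density
  if (all(d <= 0)) stop("all-zero source estimate", call. = FALSE)
  mx <- max(d)
  idx <- which(d == mx)
  tie <- length(idx) > 1
  i <- idx[1]
  list(coordinate_mm = estimate$grid$points[i, ], value = mx,
       point_index = i, tie = tie)
}

# maximal 6-connected components among a set of point indices
connected_components <- function(grid, points) {
  if (length(points) == 0) return(list())
  inset <- logical(grid$n_points)
  inset[points] <- TRUE
  edges <- NULL
  for (p in points) {
    nb <- grid$adjacency[[p]]
    nb <- nb[inset[nb] & nb > p]
    if (length(nb)) edges <- rbind(edges, cbind(p, nb))
  }
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = integer(0), to = integer(0))
        else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = points))
  comp <- igraph::components(g)
  split(as.integer(igraph::V(g)$name), comp$membership)
}

#' Paired-t contrast between two sets of source estimates with a
#' cluster-extent rule
#'
#' Per grid point, a paired t statistic over subjects of (a - b). Points at or
#' above the t threshold form candidate sets in each direction; maximal
#' 6-connected components with size strictly greater than `extent_threshold`
#' are reported. The default thresholds are the numeric rule
#' t(n-1) >= 2.09 with extent > 10; `mode = "bonferroni"` instead derives the
#' t threshold from a Bonferroni-corrected two-sided alpha over grid points.
#'
#' @param a,b lists of [estimate_sources()] results (same subjects, same
#'   order) or subjects x points matrices of densities.
#' @param grid the source grid.
#' @param t_threshold per-point t threshold (default 2.09).
#' @param extent_threshold cluster extent; clusters must exceed it strictly
#'   (default 10).
#' @param mode `"numeric"` (stated rule, default) or `"bonferroni"`.
#' @param alpha alpha level for bonferroni mode (default 0.05).
#' @return object of class `"cluster_contrast"`: `t` (per point), `df`,
#'   `t_threshold`, `extent_threshold`, and `clusters` (list of
#'   direction, point indices, size, peak t, peak coordinate).
#' @export
paired_t_contrast <- function(a, b, grid, t_threshold = 2.09,
                              extent_threshold = 10,
                              mode = c("numeric", "bonferroni"),
                              alpha = 0.05) {
  mode <- match.arg(mode)
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    subj <- vapply(x, function(e) as.character(e$subject), character(1))
    m <- do.call(rbind, lapply(x, function(e) e$density))
    rownames(m) <- subj
    m
  }
  A <- as_mat(a)
  B <- as_mat(b)
  if (!identical(dim(A), dim(B)) ||
      (!is.null(rownames(A)) && !identical(rownames(A), rownames(B))))
    stop("contrast inputs must cover the same subjects in the same order",
         call. = FALSE)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  D <- A - B
  mu <- colMeans(D)
  s <- apply(D, 2, stats::sd)
  tval <- ifelse(s < 1e-15, 0, mu / (s / sqrt(n)))
  df <- n - 1
  thr <- if (mode == "bonferroni")
    stats::qt(1 - alpha / (2 * grid$n_points), df) else t_threshold
  clusters <- list()
  for (dir in c("a>b", "b>a")) {
    tv <- if (dir == "a>b") tval else -tval
    supra <- which(tv >= thr)
    comps <- connected_components(grid, supra)
    for (cp in comps) {
      if (length(cp) > extent_threshold) {
        pk <- cp[which.max(tv[cp])]
        clusters[[length(clusters) + 1]] <- list(
          direction = dir, points = sort(cp), size = length(cp),
          peak_t = tv[pk], peak_coordinate_mm = grid$points[pk, ])
      }
    }
  }
  structure(list(t = tval, df = df, t_threshold = thr,
                 extent_threshold = extent_threshold, mode = mode,
                 clusters = clusters),
            class = "cluster_contrast")
}

#' @export
print.cluster_contrast <- function(x, ...) {
  cat(sprintf("<cluster_contrast> df = %d, |t| >= %.3f, extent > %d: %d cluster(s)\n",
              x$df, x$t_threshold, x$extent_threshold, length(x$clusters)))
  for (cl in x$clusters)
    cat(sprintf("  %s: %d points, peak t = %.2f at (%.0f, %.0f, %.0f) mm\n",
                cl$direction, cl$size, cl$peak_t, cl$peak_coordinate_mm[1],
                cl$peak_coordinate_mm[2], cl$peak_coordinate_mm[3]))
  invisible(x)
}

#' Export a source map as a NIfTI volume
#'
#' Renders per-point values on the lattice bounding box (isotropic voxels at
#' the grid spacing; the affine maps voxel indices to the grid frame in mm).
#'
#' @param values per-point numeric vector (e.g. a density or t map).
#' @param grid the source grid.
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly; off-grid voxels are 0.
#' @export
export_source_nifti <- function(values, grid, path) {
  stopifnot(length(values) == grid$n_points)
  sp <- grid$spacing_mm
  ijk <- round(sweep(grid$points, 2, apply(grid$points, 2, min)) / sp) + 1
  dims <- apply(ijk, 2, max)
  vol <- array(0, dim = dims)
  vol[cbind(ijk[, 1], ijk[, 2], ijk[, 3])] <- values
  origin <- apply(grid$points, 2, min)
  img <- RNifti::asNifti(vol)
  xform <- diag(c(sp, sp, sp, 1))
  xform[1:3, 4] <- origin        # 0-based voxel (0,0,0) centre at the grid minimum
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
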
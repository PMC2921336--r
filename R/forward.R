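#' Three-shell spherical head model
#'
#' Concentric brain / skull / scalp shells. The defaults (80 / 85 / 92 mm,
#' 0.33 / 0.0042 / 0.33 S/m) are the classical adult values with a skull some
#' 80 times less conductive than brain and scalp.
#'
#' @param radii_mm three strictly increasing shell radii (brain, skull outer,
#'   scalp outer) in mm.
#' @param conductivities three positive conductivities in S/m.
#' @return an object of class `"shell_model"`.
#' @export
shell_model <- function(radii_mm = c(80, 85, 92),
                        conductivities = c(0.33, 0.0042, 0.33)) {
  if (length(radii_mm) != 3 || any(diff(radii_mm) <= 0))
    stop("radii_mm must be three strictly increasing values", call. = FALSE)
  if (length(conductivities) != 3 || any(conductivities <= 0))
    stop("conductivities must be three positive values", call. = FALSE)
  structure(list(radii_mm = as.numeric(radii_mm),
                 conductivities = as.numeric(conductivities)),
            class = "shell_model")
}

#' Regular source grid inside the brain shell
#'
#' A cubic lattice of the given spacing, clipped strictly inside the brain
#' (innermost) shell, with face-neighbour (6-connected) adjacency.
#'
#' @param spacing_mm grid step in mm (default 6).
#' @param shell a [shell_model()].
#' @param margin_mm keep-out distance from the brain shell surface; points
#'   within `margin_mm` of the boundary are dropped so that every source stays
#'   strictly inside the conductor (default half a grid step).
#' @return an object of class `"source_grid"`: `points` (n x 3, mm),
#'   `spacing_mm`, `adjacency` (list of integer neighbour indices per point),
#'   and `n_points`.
#' @export
build_source_grid <- function(spacing_mm = 6, shell = shell_model(),
                              margin_mm = spacing_mm / 2) {
  brain_r <- shell$radii_mm[1]
  if (!(spacing_mm > 0) || spacing_mm >= brain_r)
    stop("spacing_mm must be in (0, brain radius)", call. = FALSE)
  rmax <- brain_r - margin_mm
  # lattice centred on the origin
  half <- floor(rmax / spacing_mm)
  ax <- seq(-half, half) * spacing_mm
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- sqrt(rowSums(g^2)) <= rmax
  pts <- g[keep, , drop = FALSE]
  # index points on the integer lattice for O(n) adjacency lookup
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")
  ijk <- round(pts / spacing_mm)
  lut <- new.env(hash = TRUE, parent = emptyenv())
  kk <- key(ijk)
  for (i in seq_len(nrow(pts))) assign(kk[i], i, envir = lut)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  adjacency <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    nb <- integer(0)
    for (o in seq_len(6)) {
      k <- key(ijk[i, , drop = FALSE] + offsets[o, , drop = FALSE])
      j <- lut[[k]]
      if (!is.null(j)) nb <- c(nb, j)
    }
    adjacency[[i]] <- sort(nb)
  }
  structure(list(points = pts, spacing_mm = spacing_mm,
                 adjacency = adjacency, n_points = nrow(pts)),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d points, %.1f mm spacing\n",
              x$n_points, x$spacing_mm))
  invisible(x)
}

# Legendre P_n(x) and the associated P_n^1(x) = sqrt(1-x^2) P_n'(x)
# (no Condon-Shortley phase), evaluated for n = 1..nmax on a vector x.
# Returns a list of two (length(x) x nmax) matrices.
legendre_terms <- function(x, nmax) {
  m <- length(x)
  P <- matrix(0, m, nmax)
  dP <- matrix(0, m, nmax)          # P_n'(x)
  p_nm1 <- rep(1, m)                # P_0
  p_n <- x                          # P_1
  d_nm1 <- rep(0, m)                # P_0'
  d_n <- rep(1, m)                  # P_1'
  P[, 1] <- p_n
  dP[, 1] <- d_n
  for (n in 2:nmax) {
    p_np1 <- ((2 * n - 1) * x * p_n - (n - 1) * p_nm1) / n
    d_np1 <- d_nm1 + (2 * n - 1) * p_n  # P_{n}' = P_{n-2}' + (2n-1) P_{n-1}
    p_nm1 <- p_n; p_n <- p_np1
    d_nm1 <- d_n; d_n <- d_np1
    P[, n] <- p_n
    dP[, n] <- d_n
  }
  s <- sqrt(pmax(0, 1 - x^2))
  list(P = P, P1 = dP * s)
}

# Per-degree radial transfer factors for the three-shell model.
# For harmonic degree n the potential in shell j is
#   V_j = (A_j rho^n + C_j rho^-(n+1)) * angular,   rho = r / scalp radius,
# with the dipole's primary expansion carrying a fixed coefficient in shell 1.
# Matching V and sigma dV/dr at both interfaces plus the zero-current
# condition at the scalp surface gives 5 equations in (A1, A2, C2, A3, C3).
# Returned is s_n = scalp-surface potential per unit primary coefficient,
# i.e. V(scalp)/ (B rho_scalp^-(n+1)) with B = 1; a homogeneous sphere gives
# s_n = (2n+1)/n relative to the primary term at the surface.
shell_transfer <- function(shell, nmax) {
  R <- shell$radii_mm[3]
  rho <- shell$radii_mm / R           # rho1 < rho2 < rho3 = 1
  sig <- shell$conductivities
  s_n <- numeric(nmax)
  for (n in seq_len(nmax)) {
    r1 <- rho[1]; r2 <- rho[2]
    # unknowns: A1, A2, C2, A3, C3 ; primary coefficient B = 1 in shell 1
    M <- matrix(0, 5, 5)
    b <- numeric(5)
    # continuity of V at r1:  A1 r1^n + r1^-(n+1) = A2 r1^n + C2 r1^-(n+1)
    M[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
    b[1] <- -r1^(-(n + 1))
    # continuity of sigma dV/dr at r1
    M[2, ] <- c(sig[1] * n * r1^(n - 1),
                -sig[2] * n * r1^(n - 1),
                sig[2] * (n + 1) * r1^(-(n + 2)), 0, 0)
    b[2] <- sig[1] * (n + 1) * r1^(-(n + 2))
    # continuity of V at r2
    M[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    # continuity of sigma dV/dr at r2
    M[4, ] <- c(0, sig[2] * n * r2^(n - 1), -sig[2] * (n + 1) * r2^(-(n + 2)),
                -sig[3] * n * r2^(n - 1), sig[3] * (n + 1) * r2^(-(n + 2)))
    # zero radial current at the scalp surface (rho = 1)
    M[5, ] <- c(0, 0, 0, n, -(n + 1))
    sol <- solve(M, b)
    # potential at the scalp surface: A3 + C3
    s_n[n] <- sol[4] + sol[5]
  }
  s_n
}

#' Lead field of the three-shell spherical head model
#'
#' Computes the average-referenced scalp potentials produced by unit dipole
#' moments (x, y, z) at every grid point, via the truncated Legendre series for
#' a dipole in concentric conducting spheres. The gain is in µV per nA·m-scale
#' unit moment; only relative values matter downstream.
#'
#' @param montage a [build_montage()] montage; its scalp radius is taken from
#'   the shell model's outer radius.
#' @param grid a [build_source_grid()].
#' @param shell a [shell_model()].
#' @param n_terms number of Legendre terms (>= 20; default 60).
#' @return object of class `"lead_field"` with `gain`
#'   (n_channels x (3 * n_points)), columns ordered point-major
#'   (point 1 x,y,z; point 2 x,y,z; ...), plus `montage`, `grid`, `shell`,
#'   `n_terms`.
#' @export
compute_lead_field <- function(montage, grid, shell = shell_model(),
                               n_terms = 60L) {
  validate_montage(montage)
  if (n_terms < 20) stop("n_terms must be >= 20", call. = FALSE)
  brain_r <- shell$radii_mm[1]
  src_r <- sqrt(rowSums(grid$points^2))
  if (any(src_r >= brain_r))
    stop("all source points must lie strictly inside the brain shell",
         call. = FALSE)
  R <- shell$radii_mm[3]
  elec <- montage$positions                  # unit vectors
  npts <- grid$n_points
  nch <- montage$n_channels
  s_n <- shell_transfer(shell, n_terms)
  sig1 <- shell$conductivities[1]
  gain <- matrix(0, nch, 3L * npts)
  n_seq <- seq_len(n_terms)
  for (p in seq_len(npts)) {
    b <- src_r[p]
    if (b < 1e-9) {
      # dipole at the exact centre: radial direction undefined; treat the
      # moment directly in Cartesian terms with e_r arbitrary (x axis).
      er <- c(1, 0, 0)
    } else {
      er <- grid$points[p, ] / b
    }
    x <- drop(elec %*% er)                   # cos(gamma) per electrode
    x <- pmin(1, pmax(-1, x))
    lt <- legendre_terms(x, n_terms)
    t_rat <- b / R
    # radial series coefficient per degree: s_n * n * b^(n-1) / (4 pi sig R^(n+1))
    # tangential:                           s_n *     b^(n-1) / (4 pi sig R^(n+1))
    base <- s_n * t_rat^(n_seq - 1) / (4 * pi * sig1 * R^2)
    rad <- drop(lt$P %*% (base * n_seq))     # per electrode, unit radial moment
    tan_mag <- drop(lt$P1 %*% base)          # per electrode, per unit tangential
    # tangential unit direction per electrode: component of electrode direction
    # orthogonal to e_r, normalized
    t_vec <- elec - outer(x, er)
    t_norm <- sqrt(rowSums(t_vec^2))
    ok <- t_norm > 1e-12
    t_hat <- t_vec
    t_hat[ok, ] <- t_vec[ok, ] / t_norm[ok]
    t_hat[!ok, ] <- 0
    # potential for unit moment along Cartesian axis k:
    #   V = rad * (e_k . er) + tan_mag * (e_k . t_hat)
    cols <- 3L * (p - 1L) + 1:3
    V <- outer(rad, er) + t_hat * tan_mag
    gain[, cols] <- V
  }
  # average reference
  gain <- sweep(gain, 2, colMeans(gain))
  structure(list(gain = gain, montage = montage, grid = grid, shell = shell,
                 n_terms = as.integer(n_terms)),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d channels x %d sources (3 orientations), %d Legendre terms\n",
              nrow(x$gain), x$grid$n_points, x$n_terms))
  invisible(x)
}

#' Scalp potentials of a set of dipoles
#'
#' Applies the lead field to dipoles given as grid-point indices and 3-vector
#' moments. Returns the average-referenced potential vector over channels.
#'
#' @param leadfield a [compute_lead_field()] result.
#' @param point_idx integer vector of grid-point indices.
#' @param moments matrix (length(point_idx) x 3) of dipole moments.
#' @return numeric vector over channels (µV scale).
#' @export
project_dipoles <- function(leadfield, point_idx, moments) {
  moments <- matrix(moments, ncol = 3)
  stopifnot(length(point_idx) == nrow(moments))
  v <- numeric(nrow(leadfield$gain))
  for (i in seq_along(point_idx)) {
    cols <- 3L * (point_idx[i] - 1L) + 1:3
    v <- v + drop(leadfield$gain[, cols] %*% moments[i, ])
  }
  v
}

#' Persist a lead field (with grid and montage) to disk
#'
#' The numeric payload goes to an RDS file; a JSON sidecar (`<path>.json`)
#' records the layout: shapes, shell parameters, spacing, point count.
#' @param leadfield a lead field.
#' @param path output path for the RDS file.
#' @export
write_lead_field <- function(leadfield, path) {
  saveRDS(leadfield, path)
  meta <- list(
    n_channels = nrow(leadfield$gain),
    n_points = leadfield$grid$n_points,
    spacing_mm = leadfield$grid$spacing_mm,
    radii_mm = leadfield$shell$radii_mm,
    conductivities = leadfield$shell$conductivities,
    n_terms = leadfield$n_terms)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  lf <- readRDS(path)
  if (!inherits(lf, "lead_field")) stop("not a lead field file", call. = FALSE)
  lf
}
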
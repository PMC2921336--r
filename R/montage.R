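#' Electrode montage on a spherical scalp
#'
#' A montage is a set of uniquely labelled electrode positions lying exactly on
#' a sphere of stated scalp radius. Positions are stored as unit direction
#' vectors; physical coordinates are `radius_mm * positions`.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param radius_mm scalp sphere radius in mm.
#' @param coverage fraction of the full sphere area covered by the cap of
#'   electrodes, measured from the vertex downward. The default 0.65 places
#'   the lowest ring somewhat below the equator, as high-density geodesic
#'   nets do.
#' @return an object of class `"montage"` with elements `labels` (character),
#'   `positions` (n x 3 unit vectors, +z through the vertex), `radius_mm`,
#'   and `n_channels`.
#'
#' @details Electrodes are placed on a Fibonacci (golden-angle) lattice over
#' the spherical cap, which gives an approximately uniform geodesic sampling
#' and is fully deterministic: the same arguments always produce the same
#' montage.
#' @export
build_montage <- function(n_channels = 128L, radius_mm = 92, coverage = 0.65) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 8)
    stop("n_channels must be a single number >= 8", call. = FALSE)
  n <- as.integer(n_channels)
  if (radius_mm <= 0) stop("radius_mm must be positive", call. = FALSE)
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]", call. = FALSE)
  # cap area fraction 'coverage': z in [1 - 2*coverage, 1]; offset by half a
  # step so no electrode sits exactly at the vertex or the rim
  z_lo <- 1 - 2 * coverage
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n * (1 - z_lo)
  phi <- golden * (i - 1)
  r_xy <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(r_xy * cos(phi), r_xy * sin(phi), z, deparse.level = 0)
  pos <- pos / sqrt(rowSums(pos^2))  # exact unit norm
  dimnames(pos) <- NULL
  labels <- sprintf("E%03d", i)
  structure(
    list(labels = labels, positions = pos, radius_mm = radius_mm,
         n_channels = n),
    class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels on a %.1f mm scalp sphere\n",
              x$n_channels, x$radius_mm))
  invisible(x)
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "montage"))
  if (anyDuplicated(m$labels)) stop("montage labels must be unique", call. = FALSE)
  if (nrow(m$positions) != m$n_channels || length(m$labels) != m$n_channels)
    stop("montage size fields inconsistent", call. = FALSE)
  if (any(abs(sqrt(rowSums(m$positions^2)) - 1) > 1e-9))
    stop("montage positions must lie on the scalp sphere", call. = FALSE)
  invisible(m)
}

#' Write electrode positions as a .sfp file
#'
#' Plain-text BESA/EGI style: one line per electrode, `label x y z` in mm.
#' @param montage a montage.
#' @param path output file path.
#' @export
write_sfp <- function(montage, path) {
  validate_montage(montage)
  xyz <- montage$positions * montage$radius_mm
  lines <- sprintf("%s\t%.6f\t%.6f\t%.6f", montage$labels,
                   xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(lines, path)
  invisible(path)
}

#' Read electrode positions from a .sfp file
#'
#' @param path input file path.
#' @return a montage; the scalp radius is taken as the mean distance of the
#'   electrodes from the origin, and positions are projected onto that sphere.
#' @export
read_sfp <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("sfp file must have 4 columns: label x y z", call. = FALSE)
  xyz <- unname(as.matrix(tab[, 2:4]))
  r <- sqrt(rowSums(xyz^2))
  radius <- mean(r)
  structure(
    list(labels = as.character(tab[[1]]), positions = xyz / r,
         radius_mm = radius, n_channels = nrow(tab)),
    class = "montage")
}

#' Write electrode positions as a .elc file
#'
#' Minimal ASA-style .elc: header with units and count, a `Positions` block in
#' mm, and a `Labels` block.
#' @param montage a montage.
#' @param path output file path.
#' @export
write_elc <- function(montage, path) {
  validate_montage(montage)
  xyz <- montage$positions * montage$radius_mm
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ASCII electrode file",
               "ReferenceLabel\tavg",
               "UnitPosition\tmm",
               sprintf("NumberPositions=\t%d", montage$n_channels),
               "Positions"), con)
  writeLines(sprintf("%.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines("Labels", con)
  writeLines(montage$labels, con)
  invisible(path)
}

#' Read electrode positions from a .elc file
#' @param path input file path.
#' @return a montage (see [read_sfp()] for the radius convention).
#' @export
read_elc <- function(path) {
  lines <- readLines(path)
  ip <- grep("^Positions", lines)
  il <- grep("^Labels", lines)
  if (length(ip) != 1L || length(il) != 1L || il <= ip)
    stop("not a recognizable .elc file", call. = FALSE)
  pos_lines <- lines[(ip + 1):(il - 1)]
  xyz <- do.call(rbind, lapply(strsplit(trimws(pos_lines), "\\s+"),
                               function(v) as.numeric(v[1:3])))
  labels <- trimws(lines[(il + 1):(il + nrow(xyz))])
  r <- sqrt(rowSums(xyz^2))
  radius <- mean(r)
  structure(
    list(labels = labels, positions = xyz / r, radius_mm = radius,
         n_channels = nrow(xyz)),
    class = "montage")
}
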
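# Texture feature families on a discretized gray-level grid.
#
# Each family consumes a 3D integer grid where 0 marks out-of-mask voxels
# and >= 1 are gray levels, and returns a named vector. One merged matrix
# over the 13 unique Chebyshev-distance-1 directions is used (not
# per-direction averaging). Undefined cases return NA sentinels, which the
# screening stage excludes per (patient, feature) rather than imputing.

.dirs13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

# Build the level grid from a levels vector + mask.
.level_grid <- function(levels, mask_values) {
  g <- array(0L, dim(mask_values))
  g[mask_values] <- as.integer(levels)
  g
}

#' Gray-level co-occurrence features
#'
#' One merged symmetric GLCM over the 13 unique 3D directions at Chebyshev
#' distance 1, normalized to sum 1. `Variance_CM` is
#' `sum_ij p(i,j) (i - mu)^2` with `mu = sum_ij i p(i,j)`.
#'
#' @param grid 3D integer array; 0 = outside mask, >= 1 = gray level.
#' @return named vector: Variance_CM, energy, entropy, contrast,
#'   homogeneity, correlation (NA sentinels if no voxel pair exists).
#' @export
glcm_features <- function(grid) {
  nlev <- max(grid)
  out <- c(Variance_CM = NA_real_, energy = NA_real_, entropy = NA_real_,
           contrast = NA_real_, homogeneity = NA_real_, correlation = NA_real_)
  if (nlev < 1L) return(out)
  cm <- cpp_glcm(as.integer(grid), dim(grid), nlev)
  tot <- sum(cm)
  if (tot == 0) return(out)
  p <- cm / tot
  i <- row(p); j <- col(p)
  mu <- sum(i * p)
  v <- sum(p * (i - mu)^2)
  pn <- p[p > 0]
  corr <- if (v > 0) (sum(i * j * p) - mu^2) / v else 1
  c(Variance_CM = v,
    energy = sum(p^2),
    entropy = -sum(pn * log2(pn)),
    contrast = sum(p * (i - j)^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    correlation = corr)
}

#' Gray-level run-length features
#'
#' Runs of equal level along each direction, merged into one matrix.
#' `SRE = (1/Nr) sum r(i,j)/j^2`, `LRE = (1/Nr) sum r(i,j) j^2`,
#' `RLN = (1/Nr) sum_j (sum_i r(i,j))^2`, `GLN` analogously over levels,
#' and `RP = Nr / (Ndir * Nvoxels)` so the single-direction closed forms
#' (RP = 1 for all-unit runs) hold per direction.
#'
#' @param grid 3D integer level array (0 outside mask).
#' @param dirs integer matrix of direction offsets; default all 13.
#' @return named vector: SRE, LRE, RLN, RP, GLN.
#' @export
glrlm_features <- function(grid, dirs = .dirs13()) {
  nlev <- max(grid)
  out <- c(SRE = NA_real_, LRE = NA_real_, RLN = NA_real_, RP = NA_real_,
           GLN = NA_real_)
  if (nlev < 1L) return(out)
  r <- cpp_glrlm(as.integer(grid), dim(grid), nlev, dirs)
  nr <- sum(r)
  if (nr == 0) return(out)
  np <- sum(grid > 0L)
  jl <- col(r)
  c(SRE = sum(r / jl^2) / nr,
    LRE = sum(r * jl^2) / nr,
    RLN = sum(colSums(r)^2) / nr,
    RP = nr / (nrow(dirs) * np),
    GLN = sum(rowSums(r)^2) / nr)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level; the size-zone
#' matrix counts zones by (level, size). SZE/LZE/ZSN/ZP mirror the
#' run-length definitions with zone size replacing run length
#' (`ZP = Nzones / Nvoxels`).
#'
#' @inheritParams glcm_features
#' @return named vector: SZE, LZE, ZSN, ZP.
#' @export
glszm_features <- function(grid) {
  out <- c(SZE = NA_real_, LZE = NA_real_, ZSN = NA_real_, ZP = NA_real_)
  if (max(grid) < 1L) return(out)
  lab <- cpp_label_zones(as.integer(grid), dim(grid))
  nz <- max(lab)
  if (nz == 0L) return(out)
  sizes <- tabulate(lab[lab > 0], nbins = nz)
  np <- sum(grid > 0L)
  # zone counts by size (levels only matter through the zone partition here)
  size_counts <- table(sizes)
  s <- as.numeric(names(size_counts))
  cnt <- as.numeric(size_counts)
  c(SZE = sum(cnt / s^2) / nz,
    LZE = sum(cnt * s^2) / nz,
    ZSN = sum(cnt^2) / nz,
    ZP = nz / np)
}

#' Neighborhood gray-tone difference features
#'
#' Per-level sums of absolute differences between a voxel's level and the
#' mean level of its in-mask 26-neighborhood, combined by the standard
#' Amadasun-King formulas. Coarseness is capped at 1e6 when the difference
#' sum vanishes (perfectly flat region); Busyness and Contrast are 0 in the
#' single-level case.
#'
#' @inheritParams glcm_features
#' @return named vector: Coarseness, Contrast_NG, Busyness (NA sentinels if
#'   no voxel has an in-mask neighbor).
#' @export
ngtdm_features <- function(grid) {
  out <- c(Coarseness = NA_real_, Contrast_NG = NA_real_, Busyness = NA_real_)
  nlev <- max(grid)
  if (nlev < 1L) return(out)
  m <- cpp_ngtdm(as.integer(grid), dim(grid), nlev)
  n_i <- m[, 1]; s_i <- m[, 2]
  N <- sum(n_i)
  if (N == 0) return(out)
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  ps <- sum(p_i * s_i)
  coarse <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  if (ngp <= 1L) {
    contrast <- 0; busy <- 0
  } else {
    lev <- seq_len(nlev)
    pp <- outer(p_i[act], p_i[act])
    dd <- outer(lev[act], lev[act], `-`)^2
    contrast <- sum(pp * dd) / (ngp * (ngp - 1)) * sum(s_i) / N
    ip <- lev[act] * p_i[act]
    denom <- sum(abs(outer(ip, ip, `-`)))
    busy <- if (denom > 0) ps / denom else 0
  }
  c(Coarseness = coarse, Contrast_NG = contrast, Busyness = busy)
}
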
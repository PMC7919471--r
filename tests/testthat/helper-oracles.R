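# Independent brute-force oracles for the texture families and the wavelet
# transform. These enumerate pairs/runs/zones/neighborhoods directly in R,
# sharing only the feature *definitions* with the production code, never its
# enumeration path.

oracle_dirs13 <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  d[d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
      (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0), , drop = FALSE]
}

.ogrid_get <- function(g, p) {
  d <- dim(g)
  if (any(p < 1) || any(p > d)) return(0L)
  g[p[1], p[2], p[3]]
}

oracle_glcm <- function(g) {
  nlev <- max(g)
  dirs <- oracle_dirs13()
  m <- matrix(0, nlev, nlev)
  idx <- which(g > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- g[idx[r, 1], idx[r, 2], idx[r, 3]]
    for (k in seq_len(nrow(dirs))) {
      b <- .ogrid_get(g, idx[r, ] + dirs[k, ])
      if (b > 0) { m[a, b] <- m[a, b] + 1; m[b, a] <- m[b, a] + 1 }
    }
  }
  p <- m / sum(m)
  i <- row(p); j <- col(p)
  mu <- sum(i * p)
  v <- sum(p * (i - mu)^2)
  pn <- p[p > 0]
  c(Variance_CM = v, energy = sum(p^2), entropy = -sum(pn * log2(pn)),
    contrast = sum(p * (i - j)^2), homogeneity = sum(p / (1 + abs(i - j))),
    correlation = if (v > 0) (sum(i * j * p) - mu^2) / v else 1)
}

oracle_glrlm <- function(g, dirs = oracle_dirs13()) {
  runs <- list()
  idx <- which(g > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]
      a <- g[p[1], p[2], p[3]]
      if (.ogrid_get(g, p - dd) == a) next   # not a run start
      len <- 1; q <- p + dd
      while (.ogrid_get(g, q) == a) { len <- len + 1; q <- q + dd }
      runs[[length(runs) + 1L]] <- c(a, len)
    }
  }
  rn <- do.call(rbind, runs)
  nr <- nrow(rn)
  np <- sum(g > 0)
  lev <- rn[, 1]; len <- rn[, 2]
  c(SRE = sum(1 / len^2) / nr,
    LRE = sum(len^2) / nr,
    RLN = sum(as.numeric(table(len))^2) / nr,
    RP = nr / (nrow(dirs) * np),
    GLN = sum(as.numeric(table(lev))^2) / nr)
}

oracle_glszm <- function(g) {
  d <- dim(g)
  seen <- array(FALSE, d)
  idx <- which(g > 0, arr.ind = TRUE)
  sizes <- integer(0)
  nb <- oracle_dirs13(); nb <- rbind(nb, -nb)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (seen[p[1], p[2], p[3]]) next
    lev <- g[p[1], p[2], p[3]]
    queue <- list(p); seen[p[1], p[2], p[3]] <- TRUE; sz <- 0L
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]; sz <- sz + 1L
      for (k in seq_len(nrow(nb))) {
        t <- q + nb[k, ]
        if (any(t < 1) || any(t > d)) next
        if (!seen[t[1], t[2], t[3]] && g[t[1], t[2], t[3]] == lev) {
          seen[t[1], t[2], t[3]] <- TRUE
          queue[[length(queue) + 1L]] <- t
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  nz <- length(sizes); np <- sum(g > 0)
  c(SZE = sum(1 / sizes^2) / nz, LZE = sum(sizes^2) / nz,
    ZSN = sum(as.numeric(table(sizes))^2) / nz, ZP = nz / np)
}

oracle_ngtdm <- function(g) {
  d <- dim(g)
  nlev <- max(g)
  n_i <- numeric(nlev); s_i <- numeric(nlev)
  idx <- which(g > 0, arr.ind = TRUE)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    a <- g[p[1], p[2], p[3]]
    nbv <- c()
    for (k in seq_len(nrow(off))) {
      b <- .ogrid_get(g, p + off[k, ])
      if (b > 0) nbv <- c(nbv, b)
    }
    if (!length(nbv)) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nbv))
  }
  N <- sum(n_i)
  p_i <- n_i / N
  act <- which(p_i > 0); ngp <- length(act)
  ps <- sum(p_i * s_i)
  coarse <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  if (ngp <= 1) return(c(Coarseness = coarse, Contrast_NG = 0, Busyness = 0))
  lev <- seq_len(nlev)
  contrast <- sum(outer(p_i[act], p_i[act]) * outer(lev[act], lev[act], `-`)^2) /
    (ngp * (ngp - 1)) * sum(s_i) / N
  ip <- lev[act] * p_i[act]
  den <- sum(abs(outer(ip, ip, `-`)))
  c(Coarseness = coarse, Contrast_NG = contrast,
    Busyness = if (den > 0) ps / den else 0)
}

# Random in-mask level grid for property tests (some out-of-mask holes).
random_level_grid <- function(dims, nlev, p_mask = 0.85) {
  g <- array(sample.int(nlev, prod(dims), replace = TRUE), dims)
  g[runif(prod(dims)) > p_mask] <- 0L
  if (all(g == 0L)) g[1, 1, 1] <- 1L
  storage.mode(g) <- "integer"
  g
}

# 1D periodized DWT by direct circular convolution (independent of the
# matrix construction in the package).
oracle_dwt1d <- function(x, lo) {
  n <- length(x)
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  a <- d <- numeric(n / 2)
  for (m in seq_len(n / 2)) {
    acc_a <- acc_d <- 0
    for (k in seq_len(L)) {
      xi <- ((2 * (m - 1) + (k - 1)) %% n) + 1
      acc_a <- acc_a + lo[k] * x[xi]
      acc_d <- acc_d + hi[k] * x[xi]
    }
    a[m] <- acc_a; d[m] <- acc_d
  }
  c(a, d)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (tiny n only).
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(ix) {
    g1 <- pooled[ix]; g0 <- pooled[-ix]
    sum(outer(g1, g0, `>`)) + 0.5 * sum(outer(g1, g0, `==`))
  }
  obs <- u_of(seq_len(n1))
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
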
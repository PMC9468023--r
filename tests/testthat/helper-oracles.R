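# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most naive correct formulation available.

# box counts of a binary mask at one box size
oracle_box_count <- function(mask, s) {
  ij <- which(mask, arr.ind = TRUE)
  length(unique(ceiling(ij[, 1] / s) + 1e6 * ceiling(ij[, 2] / s)))
}

# box-counting dimension by log-log regression over the given sizes
oracle_box_dimension <- function(mask, sizes = c(2, 4, 8, 16, 32, 64, 128)) {
  counts <- vapply(sizes, function(s) oracle_box_count(mask, s), 0)
  -unname(coef(lm(log(counts) ~ log(sizes)))[2])
}

# mass-radius dimension: slope of log mass within radius R vs log R
oracle_mass_radius_dimension <- function(mask, radii = 2^(2:7)) {
  c0 <- floor(nrow(mask) / 2)
  ij <- which(mask, arr.ind = TRUE)
  r <- sqrt((ij[, 1] - c0)^2 + (ij[, 2] - c0)^2)
  N <- vapply(radii, function(R) sum(r <= R), 0)
  unname(coef(lm(log(N) ~ log(radii)))[2])
}

# brute-force nonflat grayscale erosion/dilation with border-skip policy
oracle_gray_morph <- function(img, se, erode = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(if (erode) Inf else -Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (k in seq_along(se$h)) {
      ii <- if (erode) i + se$dy[k] else i - se$dy[k]
      jj <- if (erode) j + se$dx[k] else j - se$dx[k]
      if (ii < 1 || jj < 1 || ii > nr || jj > nc) next
      v <- if (erode) img[ii, jj] - se$h[k] else img[ii, jj] + se$h[k]
      if (if (erode) v < out[i, j] else v > out[i, j]) out[i, j] <- v
    }
  }
  out
}

oracle_opening <- function(img, se) {
  oracle_gray_morph(oracle_gray_morph(img, se, TRUE), se, FALSE)
}

# exhaustive pairwise rectangle-intersection overlap check
oracle_max_overlap <- function(patches, ps) {
  n <- length(patches)
  if (n < 2) return(0)
  worst <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    o1 <- patches[[a]]$origin; o2 <- patches[[b]]$origin
    inter <- max(0, ps - abs(o1[1] - o2[1])) * max(0, ps - abs(o1[2] - o2[2]))
    worst <- max(worst, inter / ps^2)
  }
  worst
}

# brute-force Mahalanobis distance on a (possibly regularized) covariance
oracle_mahalanobis <- function(X) {
  mu <- colMeans(X)
  S <- cov(X) + diag(1e-8, ncol(X))
  sqrt(stats::mahalanobis(X, mu, S))
}

# exact two-sample KS by enumeration of all label assignments (no ties)
oracle_ks_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  Dof <- function(xi, yi) {
    xs <- sort(xi); ys <- sort(yi)
    grid <- sort(unique(c(xs, ys)))
    max(abs(ecdf(xs)(grid) - ecdf(ys)(grid)))
  }
  D0 <- Dof(x, y)
  combs <- combn(n + m, n)
  hits <- 0
  for (k in seq_len(ncol(combs))) {
    xi <- pooled[combs[, k]]
    yi <- pooled[-combs[, k]]
    if (Dof(xi, yi) >= D0 - 1e-12) hits <- hits + 1
  }
  list(D = D0, p = hits / ncol(combs))
}

# brute-force GLCM features at offset (dr, dc) by explicit pair enumeration
oracle_glcm <- function(q, levels, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  P <- matrix(0, levels, levels)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + dr; jj <- j + dc
    if (ii < 1 || jj < 1 || ii > nr || jj > nc) next
    P[q[i, j], q[ii, jj]] <- P[q[i, j], q[ii, jj]] + 1
  }
  P <- P + t(P)
  P <- P / sum(P)
  i <- matrix(seq_len(levels), levels, levels); j <- t(i)
  pi_ <- rowSums(P)
  mu <- sum(seq_len(levels) * pi_)
  v <- sum((seq_len(levels) - mu)^2 * pi_)
  c(contrast = sum(P * (i - j)^2),
    correlation = if (v == 0) 1 else sum(P * (i - mu) * (j - mu)) / v,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2)))
}

# naive average-linkage agglomeration returning cutree-style labels at k
oracle_average_linkage <- function(X, k) {
  n <- nrow(X)
  groups <- as.list(seq_len(n))
  D <- as.matrix(dist(X))
  avg_d <- function(g1, g2) mean(D[g1, g2])
  while (length(groups) > k) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_len(length(groups) - 1)) for (b in (a + 1):length(groups)) {
      d <- avg_d(groups[[a]], groups[[b]])
      if (d < bd) { bd <- d; best <- c(a, b) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# small stationary-noise patch fixture
noise_patch <- function(seed = 1, side = 128L) {
  set.seed(seed)
  new_patch(matrix(runif(side * side), side, side), "noise", c(0L, 0L), "n")
}

# patch with texture confined to the top half, bottom half constant;
# the texture is right-skewed (sparse bright spots on dark background,
# as in dark-field deposits), so the row-skewness profile shows a step
half_blank_patch <- function(seed = 2, side = 128L) {
  set.seed(seed)
  px <- matrix(0.2, side, side)
  px[seq_len(side / 2), ] <- runif(side * side / 2)^4
  new_patch(px, "half", c(0L, 0L), "h")
}

# three trivially separable classes: disjoint intensity bands
banded_patches <- function(n_per_class = 12L, side = 128L, seed = 5) {
  set.seed(seed)
  out <- list()
  bands <- list(a = c(0.0, 0.3), b = c(0.35, 0.65), c = c(0.7, 1.0))
  for (cl in names(bands)) for (i in seq_len(n_per_class)) {
    px <- matrix(runif(side * side, bands[[cl]][1], bands[[cl]][2]),
                 side, side)
    out[[length(out) + 1L]] <- new_patch(px, paste0(cl, i), c(0L, 0L), cl)
  }
  out
}
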
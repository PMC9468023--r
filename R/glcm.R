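# pixel offsets (drow, dcol) for the four standard GLCM directions
glcm_offsets <- function(distance = 1L) {
  d <- as.integer(distance)
  list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
}

# equal-width quantization over the observed intensity range; adding a
# constant to all pixels leaves the result unchanged
quantize_gray <- function(px, levels) {
  rng <- range(px)
  if (diff(rng) == 0) return(matrix(1L, nrow(px), ncol(px)))
  q <- floor((px - rng[1]) / diff(rng) * levels) + 1L
  q[q > levels] <- levels
  matrix(as.integer(q), nrow(px), ncol(px))
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Builds the symmetric, normalized co-occurrence matrix of quantized
#' gray-level pairs at the given pixel offset; entries sum to 1.
#'
#' @param q integer matrix of quantized levels in `1..levels`.
#' @param levels number of gray levels.
#' @param offset integer `(drow, dcol)` pair.
#' @return `levels x levels` numeric matrix.
#' @export
glcm_matrix <- function(q, levels, offset) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  ri <- max(1L, 1L - dr):min(nr, nr - dr)
  ci <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[ri, ci, drop = FALSE]
  b <- q[ri + dr, ci + dc, drop = FALSE]
  counts <- tabulate(a + levels * (b - 1L), nbins = levels^2)
  P <- matrix(counts, levels, levels)
  P <- P + t(P)
  P / sum(P)
}

# the four scalar features from one normalized co-occurrence matrix
glcm_scalars <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_ <- rowSums(P)
  mu_i <- sum(seq_len(L) * pi_)
  var_i <- sum((seq_len(L) - mu_i)^2 * pi_)
  contrast <- sum(P * (i - j)^2)
  correlation <- if (var_i == 0) 1 else
    sum(P * (i - mu_i) * (j - mu_i)) / var_i
  c(contrast = contrast, correlation = correlation,
    energy = sum(P^2), homogeneity = sum(P / (1 + (i - j)^2)))
}

#' GLCM texture feature vector t
#'
#' Computes the 16-element texture vector `t = (m x n) x 1` with `m = 4`
#' features (contrast, correlation, energy, homogeneity) and `n = 4`
#' offsets (0, 45, 90, 135 degrees), in feature-major order.  Matrices are
#' symmetric and normalized.  A constant patch yields contrast 0, energy 1,
#' homogeneity 1 and correlation 1 (zero-variance convention), with a
#' warning.
#'
#' @param patch numeric matrix or [new_patch()].
#' @param levels gray-level quantization count.
#' @param distance offset length in pixels.
#' @return object of class `glcm_features` with `vector_t` (named, length
#'   16), `levels` and `distance`.
#' @export
glcm_features <- function(patch, levels = 32L, distance = 1L) {
  px <- if (inherits(patch, "texture_patch")) patch$pixels else patch
  if (diff(range(px)) == 0)
    warning("constant patch: zero-variance GLCM conventions apply")
  q <- quantize_gray(px, levels)
  offs <- glcm_offsets(distance)
  feats <- vapply(offs, function(o) glcm_scalars(glcm_matrix(q, levels, o)),
                  numeric(4L))
  # feature-major: each feature at the four offsets in turn
  vec <- as.numeric(t(feats))
  names(vec) <- paste(rep(rownames(feats), each = 4L),
                      rep(colnames(feats), 4L), sep = "_")
  structure(list(vector_t = vec, levels = as.integer(levels),
                 distance = as.integer(distance)),
            class = "glcm_features")
}

#' Stack GLCM feature vectors into a matrix
#'
#' @param patches list of [new_patch()] objects.
#' @param levels,distance see [glcm_features()].
#' @return numeric matrix (patches x 16) with patch ids as row names.
#' @export
glcm_feature_matrix <- function(patches, levels = 32L, distance = 1L) {
  M <- t(vapply(patches, function(p)
    glcm_features(p, levels, distance)$vector_t, numeric(16L)))
  rownames(M) <- vapply(patches, `[[`, "", "patch_id")
  M
}

#' GLCM baseline clustering
#'
#' Standardizes the feature columns, projects onto the first three
#' principal components, and cuts an agglomerative hierarchical clustering
#' (Ward linkage by default) at `k` clusters.
#'
#' @param features numeric feature matrix (rows = patches) or a list of
#'   [glcm_features()] objects.
#' @param k number of clusters.
#' @param linkage linkage criterion passed to [stats::hclust()].
#' @param n_components number of principal components retained.
#' @return integer cluster labels in `1..k`, named by row.
#' @export
glcm_cluster <- function(features, k = 3L, linkage = "ward.D2",
                         n_components = 3L) {
  if (is.list(features) && !is.matrix(features))
    features <- t(vapply(features, `[[`, numeric(16L), "vector_t"))
  stopifnot(nrow(features) >= k)
  sds <- apply(features, 2L, stats::sd)
  keep <- sds > 0
  Z <- scale(features[, keep, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  nz <- sum(pc$sdev > 1e-10)
  if (nz < n_components) {
    warning("feature matrix supports only ", nz,
            " nonzero components; using those")
    n_components <- max(1L, nz)
  }
  scores <- pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
  if (k == 1L)
    return(stats::setNames(rep(1L, nrow(features)), rownames(features)))
  hc <- stats::hclust(stats::dist(scores), method = linkage)
  stats::setNames(stats::cutree(hc, k = k), rownames(features))
}
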
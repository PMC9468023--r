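#' Construct a texture patch
#'
#' @param pixels square grayscale matrix (conventionally 128 x 128).
#' @param parent_image_id id of the image the patch was cropped from.
#' @param origin integer `(row, col)` of the top-left corner, 0-based.
#' @param class_label source-class label inherited from the parent image.
#' @param cluster_label optional cluster id assigned in Stage 2.
#' @return object of class `texture_patch` with a `patch_id` of the form
#'   `parent_row_col`.
#' @export
new_patch <- function(pixels, parent_image_id, origin,
                      class_label = NA_character_, cluster_label = NA_integer_) {
  stopifnot(is.matrix(pixels), length(origin) == 2L, all(origin >= 0))
  structure(list(pixels = pixels,
                 patch_id = sprintf("%s_%d_%d", parent_image_id,
                                    origin[1], origin[2]),
                 parent_image_id = as.character(parent_image_id),
                 origin = as.integer(origin),
                 class_label = as.character(class_label),
                 cluster_label = as.integer(cluster_label)),
            class = "texture_patch")
}

#' @export
print.texture_patch <- function(x, ...) {
  cat(sprintf("<texture_patch %s  %dx%d  class=%s cluster=%s>\n",
              x$patch_id, nrow(x$pixels), ncol(x$pixels), x$class_label,
              x$cluster_label))
  invisible(x)
}

# fractional overlap of two axis-aligned patch squares of side `ps`
patch_overlap_fraction <- function(o1, o2, ps) {
  max(0, ps - abs(o1[1] - o2[1])) * max(0, ps - abs(o1[2] - o2[2])) / ps^2
}

#' Random overlap-limited patch sampling
#'
#' Proposes uniformly random patch origins and rejects any proposal whose
#' area overlap with an already accepted patch exceeds `max_overlap`;
#' sampling stops after `n_target` accepts or a proposal budget of
#' `50 * n_target`.
#'
#' @param image a [labeled_image()].
#' @param patch_size patch side in pixels.
#' @param max_overlap maximum pairwise fractional area overlap, in `[0, 1)`.
#' @param n_target number of patches aimed for.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return list of [new_patch()] objects (possibly shorter than `n_target`).
#' @export
sample_patches <- function(image, patch_size = 128L, max_overlap = 0.30,
                           n_target = 12L, seed = 1) {
  stopifnot(inherits(image, "labeled_image"),
            max_overlap >= 0, max_overlap < 1, n_target >= 1)
  ps <- as.integer(patch_size)
  if (image$height < ps || image$width < ps) {
    warning("image ", image$image_id, " smaller than the patch size")
    return(list())
  }
  set.seed(seed)
  origins <- list()
  budget <- 50L * as.integer(n_target)
  for (b in seq_len(budget)) {
    cand <- c(sample.int(image$height - ps + 1L, 1L) - 1L,
              sample.int(image$width - ps + 1L, 1L) - 1L)
    ok <- all(vapply(origins, patch_overlap_fraction, 0, o2 = cand, ps = ps)
              <= max_overlap)
    if (ok) origins[[length(origins) + 1L]] <- cand
    if (length(origins) >= n_target) break
  }
  lapply(origins, function(o)
    new_patch(image$pixels[(o[1] + 1L):(o[1] + ps),
                           (o[2] + 1L):(o[2] + ps), drop = FALSE],
              image$image_id, o, image$class_label))
}

# vectorized per-row/per-column sample skewness (g1 = m3 / m2^(3/2));
# zero-variance rows or columns yield 0 by convention
profile_skewness <- function(px, margin) {
  if (margin == 2L) px <- t(px)
  mu <- rowMeans(px)
  xc <- px - mu
  m2 <- rowMeans(xc^2)
  m3 <- rowMeans(xc^3)
  ifelse(m2 > 0, m3 / m2^1.5, 0)
}

#' Row and column skewness profiles of a patch
#'
#' Element `i` of the row profile is the sample skewness (third standardized
#' moment, g1 form) of row `i`'s pixel intensities; analogously for columns.
#' Zero-variance rows/columns yield skewness 0.
#'
#' @param patch a [new_patch()] or numeric matrix.
#' @return list with `row_skews` and `col_skews` numeric vectors.
#' @export
row_col_skewness_profile <- function(patch) {
  px <- if (inherits(patch, "texture_patch")) patch$pixels else patch
  list(row_skews = profile_skewness(px, 1L),
       col_skews = profile_skewness(px, 2L))
}

#' Full-texture acceptance test from skewness profiles
#'
#' A patch is accepted as full texture iff the standard deviations of both
#' skewness profiles fall below `std_threshold` and the angles of
#' first-order polynomial fits of both profiles against the row/column index
#' (angle = `atan(slope)` in degrees, index units on the abscissa) fall
#' below `slope_threshold_deg` in magnitude.  Texture-free or spatially
#' biased patches show dispersed or trending profiles and are rejected.
#'
#' @param patch a [new_patch()] or numeric matrix.
#' @param std_threshold threshold on the profile standard deviation.
#' @param slope_threshold_deg threshold on the fitted-line angle, degrees.
#' @return list with `accept` flag and a one-row `report` data frame
#'   (`row_skew_std`, `col_skew_std`, `row_slope_deg`, `col_slope_deg`,
#'   `skew_pass`).
#' @export
skewness_accept <- function(patch, std_threshold = 0.95,
                            slope_threshold_deg = 0.51) {
  prof <- row_col_skewness_profile(patch)
  fit_angle <- function(y) {
    x <- seq_along(y)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    atan(slope) * 180 / pi
  }
  rs <- stats::sd(prof$row_skews)
  cs <- stats::sd(prof$col_skews)
  ra <- fit_angle(prof$row_skews)
  ca <- fit_angle(prof$col_skews)
  accept <- rs < std_threshold && cs < std_threshold &&
    abs(ra) < slope_threshold_deg && abs(ca) < slope_threshold_deg
  list(accept = accept,
       report = data.frame(row_skew_std = rs, col_skew_std = cs,
                           row_slope_deg = ra, col_slope_deg = ca,
                           skew_pass = accept))
}

#' PCA-based patch outlier removal
#'
#' Patches are downscaled to 32 x 32, flattened, and projected onto the
#' principal components retaining `variance_kept` of the variance.  The
#' Mahalanobis distance in that subspace is robustly standardized
#' (median/MAD) and patches exceeding `z_cutoff` are removed.
#'
#' @param patches list of [new_patch()] objects (>= 10 for filtering).
#' @param variance_kept fraction of variance retained, in (0, 1].
#' @param z_cutoff robust z-score cutoff; `Inf` disables removal.
#' @return the retained patches, with attribute `removed` holding the
#'   patch ids of removed outliers.
#' @export
pca_outlier_filter <- function(patches, variance_kept = 0.95, z_cutoff = 3.0) {
  n <- length(patches)
  if (n < 10L) {
    warning("fewer than 10 patches: PCA outlier filtering skipped")
    attr(patches, "removed") <- character(0)
    return(patches)
  }
  X <- t(vapply(patches, function(p) {
    as.numeric(EBImage::imageData(
      EBImage::resize(EBImage::Image(p$pixels), 32L, 32L)))
  }, numeric(32L * 32L)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  ncomp <- which(cum >= variance_kept)[1L]
  if (is.na(ncomp)) ncomp <- length(ev)
  if (ncomp >= n) {
    warning("fewer patches than retained components: filtering skipped")
    attr(patches, "removed") <- character(0)
    return(patches)
  }
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  # robust Mahalanobis: standardize each component by its median/MAD scale
  # (an eigenvalue-based scale is masked by the very outliers sought, since
  # a gross outlier inflates the variance of its own component)
  ctr <- apply(scores, 2L, stats::median)
  scl <- apply(scores, 2L, stats::mad)
  scl[scl == 0] <- 1
  d <- sqrt(rowSums(sweep(sweep(scores, 2L, ctr), 2L, scl, "/")^2))
  scale_ <- stats::mad(d)
  if (scale_ == 0) scale_ <- stats::sd(d)
  z <- if (is.na(scale_) || scale_ == 0) rep(0, n) else
    (d - stats::median(d)) / scale_
  keep <- z <= z_cutoff
  out <- patches[keep]
  attr(out, "removed") <- vapply(patches[!keep], `[[`, "", "patch_id")
  out
}

#' Balance classes by downsampling to the minimum class count
#'
#' @param patches list of [new_patch()] objects with class labels.
#' @param seed integer seed for the uniform downsampling.
#' @return list of patches with equal per-class counts.
#' @export
balance_classes <- function(patches, seed = 1) {
  labels <- vapply(patches, `[[`, "", "class_label")
  stopifnot(length(patches) >= 1L, !anyNA(labels))
  counts <- table(labels)
  nmin <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(names(counts), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > nmin) sort(sample(idx, nmin)) else idx
  }))
  patches[sort(keep)]
}

#' Stage 1: automatic full-texture patch selection
#'
#' Runs overlap-limited random sampling and skewness screening per image,
#' then pooled PCA outlier removal across all surviving patches.  Class
#' balancing is left to [balance_classes()] so the selection report can be
#' inspected first.
#'
#' @param images list of [labeled_image()] objects.
#' @param patch_size,max_overlap,n_target_per_image sampling parameters,
#'   see [sample_patches()].
#' @param std_threshold,slope_threshold_deg acceptance thresholds, see
#'   [skewness_accept()].
#' @param variance_kept,z_cutoff outlier-filter parameters, see
#'   [pca_outlier_filter()].
#' @param seed integer seed (split per image).
#' @return list with `patches` (accepted patches) and `report` (one row per
#'   sampled patch: skewness statistics, `skew_pass`, `pca_outlier`,
#'   `final_accept`).
#' @export
select_patches <- function(images, patch_size = 128L, max_overlap = 0.30,
                           n_target_per_image = 12L, std_threshold = 0.95,
                           slope_threshold_deg = 0.51, variance_kept = 0.95,
                           z_cutoff = 3.0, seed = 1) {
  sampled <- list()
  rows <- list()
  for (img in images) {
    ps <- sample_patches(img, patch_size, max_overlap, n_target_per_image,
                         seed = derive_seed(seed, "sample", img$image_id))
    for (p in ps) {
      acc <- skewness_accept(p, std_threshold, slope_threshold_deg)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(patch_id = p$patch_id,
                         parent_image_id = p$parent_image_id,
                         row = p$origin[1], col = p$origin[2],
                         class_label = p$class_label), acc$report)
      if (acc$accept) sampled[[length(sampled) + 1L]] <- p
    }
  }
  report <- do.call(rbind, rows)
  # outlier removal runs within each source class: classes differ
  # wholesale in texture, so pooling them would flag the smallest class
  # as one big outlier rather than atypical patches of their own kind
  labels <- vapply(sampled, `[[`, "", "class_label")
  filtered <- list()
  removed <- character(0)
  for (cl in unique(labels)) {
    f <- suppressWarnings(pca_outlier_filter(sampled[labels == cl],
                                             variance_kept, z_cutoff))
    removed <- c(removed, attr(f, "removed"))
    filtered <- c(filtered, f)
  }
  report$pca_outlier <- report$patch_id %in% removed
  report$final_accept <- report$skew_pass & !report$pca_outlier
  list(patches = filtered, report = report)
}

#' Patch manifest as a data frame
#'
#' @param patches list of [new_patch()] objects.
#' @return data frame with patch_id, parent_image_id, row, col, class_label,
#'   cluster_label.
#' @export
patch_manifest <- function(patches) {
  data.frame(patch_id = vapply(patches, `[[`, "", "patch_id"),
             parent_image_id = vapply(patches, `[[`, "", "parent_image_id"),
             row = vapply(patches, function(p) p$origin[1], 0L),
             col = vapply(patches, function(p) p$origin[2], 0L),
             class_label = vapply(patches, `[[`, "", "class_label"),
             cluster_label = vapply(patches, `[[`, NA_integer_,
                                    "cluster_label"))
}

#' Write patches as PNGs plus a manifest
#'
#' @param patches list of [new_patch()] objects.
#' @param dir output directory.
#' @return the manifest data frame, invisibly.
#' @export
write_patch_dir <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- patch_manifest(patches)
  for (p in patches)
    EBImage::writeImage(EBImage::Image(t(p$pixels)),
                        file.path(dir, paste0(p$patch_id, ".png")),
                        type = "png", bits.per.sample = 8L)
  write.table(man, file.path(dir, "patches_manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' Read a patch directory written by [write_patch_dir()]
#'
#' @param dir directory containing PNG patches and `patches_manifest.tsv`.
#' @return list of [new_patch()] objects.
#' @export
read_patch_dir <- function(dir) {
  man <- read.table(file.path(dir, "patches_manifest.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    img <- read_labeled_image(file.path(dir, paste0(man$patch_id[i], ".png")))
    p <- new_patch(img$pixels, man$parent_image_id[i],
                   c(man$row[i], man$col[i]), man$class_label[i],
                   man$cluster_label[i])
    p
  })
}
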
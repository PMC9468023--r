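make_image <- function(side = 256L, seed = 1, label = "x") {
  set.seed(seed)
  labeled_image(matrix(runif(side * side), side, side),
                paste0("img", seed), label)
}

test_that("an image exactly the patch size yields one patch at the origin", {
  img <- make_image(128L)
  ps <- sample_patches(img, n_target = 10L, seed = 2)
  expect_length(ps, 1L)
  expect_equal(ps[[1]]$origin, c(0L, 0L))
  expect_identical(ps[[1]]$pixels, img$pixels)
})

test_that("sampled sets satisfy the overlap bound (exhaustive oracle)", {
  for (seed in 1:4) {
    img <- make_image(300L, seed)
    ps <- sample_patches(img, max_overlap = 0.30, n_target = 10L, seed = seed)
    expect_gt(length(ps), 1L)
    expect_lte(oracle_max_overlap(ps, 128L), 0.30)
  }
  # zero overlap on a 256x256 image: at most 4 disjoint placements
  img <- make_image(256L, 9)
  ps0 <- sample_patches(img, max_overlap = 0, n_target = 50L, seed = 3)
  expect_lte(length(ps0), 4L)
  expect_equal(oracle_max_overlap(ps0, 128L), 0)
})

test_that("sampling is deterministic and warns on undersized images", {
  img <- make_image(300L, 5)
  a <- sample_patches(img, n_target = 6L, seed = 7)
  b <- sample_patches(img, n_target = 6L, seed = 7)
  expect_identical(lapply(a, `[[`, "origin"), lapply(b, `[[`, "origin"))
  small <- labeled_image(matrix(0.5, 64, 64), "small", "x")
  expect_warning(e <- sample_patches(small, seed = 1), "smaller")
  expect_length(e, 0L)
})

test_that("skewness profiles match the moment definition", {
  # row of {0,0,0,1}: g1 = m3 / m2^(3/2) = 1.1547
  px <- matrix(rep(c(0, 0, 0, 1), 4), 4, 4, byrow = TRUE)
  prof <- row_col_skewness_profile(px)
  expect_equal(prof$row_skews, rep(2 / sqrt(3), 4), tolerance = 1e-12)
  expect_equal(prof$row_skews[1], 1.1547, tolerance = 1e-4)
  # symmetric rows have zero skewness; constant patch gives all zeros
  sym <- matrix(rep(c(1, 2, 3, 2), 3), 3, 4, byrow = TRUE)
  expect_equal(row_col_skewness_profile(sym)$row_skews, rep(0, 3))
  expect_equal(row_col_skewness_profile(matrix(1, 8, 8))$row_skews, rep(0, 8))
  # cross-check against an independent implementation on random rows
  set.seed(4)
  px <- matrix(runif(128 * 128), 128, 128)
  expect_equal(row_col_skewness_profile(px)$row_skews,
               apply(px, 1, e1071::skewness, type = 1),
               tolerance = 1e-10)
  expect_equal(row_col_skewness_profile(px)$col_skews,
               apply(px, 2, e1071::skewness, type = 1),
               tolerance = 1e-10)
})

test_that("stationary noise is accepted; half-blank patches are rejected", {
  acc <- skewness_accept(noise_patch(1))
  expect_true(acc$accept)
  expect_lt(acc$report$row_skew_std, 0.95)
  expect_lt(abs(acc$report$row_slope_deg), 0.51)

  rej <- skewness_accept(half_blank_patch(2))
  expect_false(rej$accept)
  # the vertical texture gradient shows up in the row profile
  expect_gt(max(rej$report$row_skew_std, abs(rej$report$row_slope_deg)),
            0.51)
})

test_that("reported angles match a closed-form least-squares fit", {
  p <- half_blank_patch(3)
  prof <- row_col_skewness_profile(p)
  rep <- skewness_accept(p)$report
  for (axis in c("row_skews", "col_skews")) {
    y <- prof[[axis]]
    x <- seq_along(y)
    slope <- unname(coef(lm(y ~ x))[2])
    got <- if (axis == "row_skews") rep$row_slope_deg else rep$col_slope_deg
    expect_equal(got, atan(slope) * 180 / pi, tolerance = 1e-10)
  }
})

test_that("acceptance is monotone in both thresholds", {
  patches <- c(lapply(1:6, noise_patch), lapply(7:12, half_blank_patch))
  accepted <- function(stdt, slot)
    vapply(patches, function(p) skewness_accept(p, stdt, slot)$accept, TRUE)
  base <- accepted(0.95, 0.51)
  expect_true(all(accepted(0.5, 0.51) <= base))
  expect_true(all(accepted(0.95, 0.2) <= base))
  expect_true(all(base <= accepted(2.0, 5.0)))
})

test_that("PCA outlier filter removes an inverted patch (brute-force oracle)", {
  set.seed(6)
  base <- matrix(runif(128 * 128, 0.3, 0.7), 128, 128)
  patches <- lapply(1:39, function(i)
    new_patch(pmin(pmax(base + matrix(rnorm(128^2, 0, 0.02), 128), 0), 1),
              paste0("p", i), c(0L, 0L), "a"))
  inverted <- new_patch(1 - base, "inv", c(0L, 0L), "a")
  all_p <- c(patches, list(inverted))
  kept <- pca_outlier_filter(all_p, z_cutoff = 3)
  expect_true("inv_0_0" %in% attr(kept, "removed"))
  # brute-force check: the inverted patch is the Mahalanobis extreme
  X <- t(vapply(all_p, function(p) as.numeric(
    EBImage::imageData(EBImage::resize(EBImage::Image(p$pixels), 32, 32))),
    numeric(1024)))
  pc <- prcomp(X)
  d <- oracle_mahalanobis(pc$x[, 1:5])
  expect_equal(which.max(d), 40L)
  # infinite cutoff is the identity
  expect_length(pca_outlier_filter(all_p, z_cutoff = Inf), 40L)
  # too few patches: skipped with warning
  expect_warning(pca_outlier_filter(all_p[1:5]), "skipped")
})

test_that("identical patches produce no outliers", {
  px <- matrix(0.5, 128, 128)
  same <- lapply(1:12, function(i) new_patch(px, paste0("s", i),
                                             c(0L, 0L), "a"))
  kept <- suppressWarnings(pca_outlier_filter(same))
  expect_length(kept, 12L)
})

test_that("class balancing downsamples to the minimum count", {
  mk <- function(cl, n) lapply(seq_len(n), function(i)
    new_patch(matrix(i, 8, 8), paste0(cl, i), c(0L, 0L), cl))
  patches <- c(mk("a", 10), mk("b", 7), mk("c", 9))
  bal <- balance_classes(patches, seed = 3)
  expect_equal(as.integer(table(vapply(bal, `[[`, "", "class_label"))),
               rep(7L, 3))
  # already balanced input is unchanged
  eq <- c(mk("a", 4), mk("b", 4))
  expect_identical(balance_classes(eq, seed = 1), eq)
  # deterministic
  expect_identical(vapply(balance_classes(patches, 5), `[[`, "", "patch_id"),
                   vapply(balance_classes(patches, 5), `[[`, "", "patch_id"))
})

test_that("selection is a filter: subset, no duplicates, overlap preserved", {
  specs <- default_texture_specs()[c(1, 2)]
  imgs <- generate_image_set(specs, 2L, size = 256L, seed = 13)
  sel <- suppressWarnings(select_patches(imgs, n_target_per_image = 6L,
                                         seed = 13))
  ids <- vapply(sel$patches, `[[`, "", "patch_id")
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(ids %in% sel$report$patch_id))
  expect_true(all(sel$report$final_accept == (sel$report$skew_pass &
                                                !sel$report$pca_outlier)))
  by_img <- split(sel$patches, vapply(sel$patches, `[[`, "",
                                      "parent_image_id"))
  for (g in by_img) expect_lte(oracle_max_overlap(g, 128L), 0.30)
})
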
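test_that("binarization: bimodal separation, degenerate and monotone cases", {
  px <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10)
  b <- binarize(px)
  expect_identical(b, px > 0.5)
  expect_warning(empty <- binarize(matrix(0, 8, 8)), "constant")
  expect_equal(sum(empty), 0)
  # threshold sweep monotonically shrinks the foreground
  set.seed(3)
  px <- matrix(runif(400), 20, 20)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    sum(binarize(px, "fixed", th)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("LCFD analytic cases are exact to machine precision", {
  solid <- matrix(TRUE, 80, 80)
  m <- lcfd_map(solid, 33L)
  expect_equal(m$values[40, 40], 2, tolerance = 1e-12)
  expect_equal(m$r2[40, 40], 1, tolerance = 1e-12)

  line <- matrix(FALSE, 80, 80); line[40, ] <- TRUE
  expect_equal(lcfd_map(line, 33L)$values[40, 40], 1, tolerance = 1e-12)

  pt <- matrix(FALSE, 80, 80); pt[40, 40] <- TRUE
  expect_equal(lcfd_map(pt, 33L)$values[40, 40], 0, tolerance = 1e-12)

  # all values on an arbitrary mask stay within the plausible range
  set.seed(5)
  msk <- matrix(runif(64 * 64) < 0.4, 64, 64)
  v <- lcfd_values(lcfd_map(msk, 17L))
  expect_true(all(v >= 0 & v <= 2.5))
})

test_that("connectivity is evaluated inside the window only", {
  # two horizontal segments joined far to the right: within small windows
  # centred on the left pixel the bridge is invisible
  msk <- matrix(FALSE, 41, 41)
  msk[20, 1:5] <- TRUE     # left segment, length 5
  msk[22, 1:41] <- TRUE    # long line two rows below
  msk[21, 41] <- TRUE      # bridge connecting them at the far right
  m <- lcfd_map(msk, 9L, include_border = TRUE)
  # mass around (20, 3) grows like the 5-px segment, not the long line
  v <- m$values[20, 3]
  expect_lt(v, 1)
})

test_that("Sierpinski carpet mean LCFD approaches log 8 / log 3", {
  carp <- generate_sierpinski_carpet(4)
  v <- lcfd_values(lcfd_map(carp, 33L))
  expect_gt(length(v), 500)
  expect_equal(mean(v), log(8) / log(3), tolerance = 0.15 / (log(8) / log(3)))
  # window subsampling: solid block stays exact, carpet moves < 0.1
  solid <- matrix(TRUE, 80, 80)
  expect_equal(lcfd_map(solid, 17L)$values[40, 40], 2, tolerance = 1e-12)
  v17 <- lcfd_values(lcfd_map(carp, 17L))
  expect_lt(abs(mean(v17) - mean(v)), 0.1)
})

test_that("histograms normalize, recount and refuse empty maps", {
  set.seed(9)
  vals <- runif(500, 0.5, 2.2)
  edges <- lcfd_bin_edges(25L)
  h <- lcfd_histogram(vals, edges)
  expect_equal(sum(h$frequencies), 1)
  # brute-force recount
  counts <- vapply(seq_len(25L), function(b)
    sum(vals >= edges[b] & (vals < edges[b + 1] | b == 25L)), 0)
  expect_equal(h$frequencies, counts / 500, tolerance = 1e-12)
  # point mass lands in one bin
  h2 <- lcfd_histogram(rep(2, 40), edges)
  expect_equal(sum(h2$frequencies == 1), 1)
  expect_error(lcfd_histogram(numeric(0)), "empty")
})

test_that("histogram averaging is idempotent, mixes and stays normalized", {
  edges <- lcfd_bin_edges(20L)
  h1 <- lcfd_histogram(rep(0.5, 10), edges)
  h2 <- lcfd_histogram(rep(1.5, 10), edges)
  expect_equal(average_histogram(list(h1, h1))$frequencies, h1$frequencies)
  mix <- average_histogram(list(h1, h2))
  expect_equal(sort(mix$frequencies[mix$frequencies > 0]), c(0.5, 0.5))
  expect_equal(sum(mix$frequencies), 1)
  expect_error(average_histogram(list(h1, lcfd_histogram(1, lcfd_bin_edges(10L)))),
               "mismatched")
  # grouping commutes for equal-weight averages
  h3 <- lcfd_histogram(rep(2.0, 10), edges)
  h4 <- lcfd_histogram(rep(1.0, 10), edges)
  a <- average_histogram(list(h1, h2, h3, h4))
  b <- average_histogram(list(average_histogram(list(h1, h2)),
                              average_histogram(list(h3, h4))))
  expect_equal(a$frequencies, b$frequencies)
})

test_that("cluster statistics match direct moment formulas", {
  toy <- c(1.2, 1.4, 1.1, 1.8, 1.5, 1.3, 1.6, 1.9, 1.0, 1.7)
  groups <- list(g1 = list(toy[1:5], toy[6:10]))
  st <- cluster_stats(groups)
  expect_equal(st$N, 2)
  expect_equal(st$mean, mean(c(mean(toy[1:5]), mean(toy[6:10]))))
  expect_equal(st$SE, sd(c(mean(toy[1:5]), mean(toy[6:10]))) / sqrt(2))
  # direct g1/g2 on the pooled values
  m <- mean(toy); cm <- toy - m
  m2 <- mean(cm^2); m3 <- mean(cm^3); m4 <- mean(cm^4)
  expect_equal(st$skewness, m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(st$kurtosis, m4 / m2^2 - 3, tolerance = 1e-12)
  # zero spread across identical patches
  same <- cluster_stats(list(g = list(toy[1:5], toy[1:5])))
  expect_equal(same$SE, 0)
  # single patch: SE undefined
  one <- cluster_stats(list(g = list(toy)))
  expect_true(is.na(one$SE))
})

test_that("a large Gaussian sample has near-zero skewness and kurtosis", {
  set.seed(12)
  x <- rnorm(20000)
  st <- cluster_stats(list(g = list(x[1:10000], x[10001:20000])))
  expect_equal(st$skewness, 0, tolerance = 0.08)
  expect_equal(st$kurtosis, 0, tolerance = 0.12)
})

test_that("LCFD maps and histograms round-trip through their export formats", {
  carp <- generate_sierpinski_carpet(3)
  m <- lcfd_map(carp, 9L, include_border = TRUE)
  f <- withr::local_tempfile(fileext = ".tif")
  write_lcfd_map(m, f)
  back <- read_lcfd_map(f)
  ok <- !is.na(m$values)
  expect_equal(back[ok], m$values[ok], tolerance = 1e-6)
  expect_true(all(is.na(back[!ok])))

  h <- lcfd_histogram(lcfd_values(m), lcfd_bin_edges(20L))
  g <- withr::local_tempfile(fileext = ".tsv")
  write_lcfd_histogram(h, g)
  tab <- read.table(g, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(tab$frequency, h$frequencies, tolerance = 1e-12)
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-12)
})
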
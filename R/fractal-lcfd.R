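#' Binarize a grayscale patch
#'
#' @param patch numeric matrix (or [new_patch()]) with values in `[0, 1]`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold threshold used when `method = "fixed"`.
#' @return logical matrix; foreground = structure pixels.  A constant patch
#'   yields an empty foreground with a warning.
#' @export
binarize <- function(patch, method = c("otsu", "fixed"), threshold = 0.5) {
  px <- if (inherits(patch, "texture_patch")) patch$pixels else patch
  method <- match.arg(method)
  if (diff(range(px)) == 0) {
    warning("constant patch: empty foreground")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  th <- if (method == "otsu")
    EBImage::otsu(EBImage::Image(px), range = c(0, 1)) else threshold
  px > th
}

#' Local connected fractal dimension map
#'
#' For each foreground pixel `p` and window size `s` in `{3, 5, ...,
#' max_window}`, the connected mass `n(s)` is the number of pixels
#' 8-connected to `p` when connectivity is evaluated strictly inside the
#' `s x s` window centred at `p`.  The local dimension is the least-squares
#' slope of `log n(s)` versus `log s`.  By default pixels whose largest
#' window would cross the patch border are skipped (cleaner slopes); set
#' `include_border = TRUE` to evaluate them with truncated windows.
#'
#' @param binary logical matrix (foreground = TRUE).
#' @param max_window largest window side; odd, >= 5.
#' @param include_border evaluate border pixels with truncated windows?
#' @return object of class `lcfd_map`: per-pixel `values` (NA off
#'   foreground/skipped), per-pixel fit `r2`, and `window_sizes`.
#' @export
lcfd_map <- function(binary, max_window = 33L, include_border = FALSE) {
  stopifnot(is.matrix(binary))
  if (!is.logical(binary)) binary <- binary > 0
  if (max_window %% 2L != 1L || max_window < 5L)
    stop("`max_window` must be odd and >= 5")
  res <- cpp_lcfd(binary, as.integer(max_window), include_border)
  # slopes above 2.5 can only arise from abrupt connectivity jumps when a
  # large component enters the growing window; truncate as non-physical
  res$values[!is.na(res$values) & res$values > 2.5] <- 2.5
  structure(list(values = res$values, r2 = res$r2,
                 window_sizes = seq(3L, max_window, by = 2L),
                 include_border = include_border),
            class = "lcfd_map")
}

#' Per-pixel LCFD values of a map
#'
#' @param map an [lcfd_map()].
#' @return numeric vector of the evaluated per-pixel dimensions.
#' @export
lcfd_values <- function(map) {
  v <- as.vector(map$values)
  v[!is.na(v)]
}

#' Default LCFD histogram bin edges (50 bins over [0, 2.5])
#'
#' @param n_bins number of bins.
#' @param range dimension range covered.
#' @return numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
lcfd_bin_edges <- function(n_bins = 50L, range = c(0, 2.5)) {
  seq(range[1], range[2], length.out = n_bins + 1L)
}

#' LCFD histogram
#'
#' Normalized histogram of per-pixel local dimensions over fixed global bin
#' edges; values outside the edge range are clamped into the end bins so
#' frequencies always sum to 1.
#'
#' @param map an [lcfd_map()] or a numeric vector of dimension values.
#' @param bin_edges strictly increasing bin edges.
#' @return object of class `lcfd_histogram` with `bin_edges`, `frequencies`
#'   and `n_patches = 1`.
#' @export
lcfd_histogram <- function(map, bin_edges = lcfd_bin_edges()) {
  v <- if (inherits(map, "lcfd_map")) lcfd_values(map) else
    map[is.finite(map)]
  if (length(v) == 0L) stop("empty LCFD map: no foreground values")
  stopifnot(all(diff(bin_edges) > 0))
  v <- pmin(pmax(v, bin_edges[1]), bin_edges[length(bin_edges)])
  counts <- hist(v, breaks = bin_edges, plot = FALSE)$counts
  structure(list(bin_edges = bin_edges,
                 frequencies = counts / sum(counts), n_patches = 1L),
            class = "lcfd_histogram")
}

#' Average LCFD histograms
#'
#' Per-bin arithmetic mean of frequencies over histograms sharing identical
#' bin edges.
#'
#' @param histograms list of [lcfd_histogram()] objects.
#' @return an `lcfd_histogram` with `n_patches` = number of inputs.
#' @export
average_histogram <- function(histograms) {
  stopifnot(length(histograms) >= 1L)
  edges <- histograms[[1]]$bin_edges
  for (h in histograms)
    if (!isTRUE(all.equal(h$bin_edges, edges)))
      stop("histograms have mismatched bin edges")
  freq <- rowMeans(vapply(histograms, `[[`, numeric(length(edges) - 1L),
                          "frequencies"))
  structure(list(bin_edges = edges, frequencies = freq,
                 n_patches = length(histograms)),
            class = "lcfd_histogram")
}

#' Descriptive LCFD statistics per cluster
#'
#' For each group: `N` = patch count; `mean` = mean of per-patch mean LCFD;
#' `SE` = standard deviation of the per-patch means divided by `sqrt(N)`
#' (NA when `N < 2`); `skewness` and excess `kurtosis` of the pooled
#' per-pixel LCFD values (moment-based g1/g2 statistics).
#'
#' @param groups named list; each element is a list of per-patch numeric
#'   vectors of per-pixel LCFD values.
#' @return data frame with one row per group: `cluster`, `N`, `mean`, `SE`,
#'   `kurtosis`, `skewness`.
#' @export
cluster_stats <- function(groups) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  rows <- lapply(names(groups), function(g) {
    vals <- groups[[g]]
    stopifnot(length(vals) >= 1L)
    per_patch <- vapply(vals, mean, 0)
    pooled <- unlist(vals)
    data.frame(cluster = g, N = length(vals), mean = mean(per_patch),
               SE = if (length(vals) >= 2L)
                 stats::sd(per_patch) / sqrt(length(vals)) else NA_real_,
               kurtosis = e1071::kurtosis(pooled, type = 1L),
               skewness = e1071::skewness(pooled, type = 1L))
  })
  do.call(rbind, rows)
}

#' @export
print.lcfd_map <- function(x, ...) {
  v <- lcfd_values(x)
  cat(sprintf("<lcfd_map  %d evaluated pixels, windows %d..%d, mean %.3f>\n",
              length(v), min(x$window_sizes), max(x$window_sizes),
              if (length(v)) mean(v) else NA_real_))
  invisible(x)
}

#' @importFrom graphics hist
NULL

#' Export an LCFD map as a 32-bit two-channel TIFF
#'
#' Channel 1 holds the local dimension scaled by `1/scale` into `[0, 1]`
#' (32-bit samples, so the scaling is lossless to ~1e-9); channel 2 is a
#' mask that is 1 where a dimension was evaluated.  [read_lcfd_map()]
#' inverts the encoding.
#'
#' @param map an [lcfd_map()].
#' @param path output file path.
#' @param scale full-scale dimension value mapped to intensity 1.
#' @return the path, invisibly.
#' @export
write_lcfd_map <- function(map, path, scale = 2.5) {
  stopifnot(inherits(map, "lcfd_map"))
  v <- map$values
  mask <- !is.na(v)
  v[!mask] <- 0
  arr <- array(c(v / scale, as.numeric(mask)), c(nrow(v), ncol(v), 2L))
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read back an LCFD map written by [write_lcfd_map()]
#'
#' @param path TIFF file path.
#' @param scale the scale used when writing.
#' @return numeric matrix of local dimensions with NA off the evaluated set.
#' @export
read_lcfd_map <- function(path, scale = 2.5) {
  # libtiff flags the mask channel as an extra (non-color) sample; harmless
  arr <- suppressWarnings(tiff::readTIFF(path))
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] >= 2L)
  v <- arr[, , 1L] * scale
  v[arr[, , 2L] < 0.5] <- NA_real_
  v
}

#' Write an LCFD histogram as delimited text with a metadata header
#'
#' @param histogram an [lcfd_histogram()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_lcfd_histogram <- function(histogram, path) {
  stopifnot(inherits(histogram, "lcfd_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_patches\t%d", histogram$n_patches),
               sprintf("# n_bins\t%d", length(histogram$frequencies)),
               sprintf("# range\t%g\t%g", histogram$bin_edges[1],
                       histogram$bin_edges[length(histogram$bin_edges)])),
             con)
  utils::write.table(
    data.frame(bin_low = head(histogram$bin_edges, -1),
               bin_high = histogram$bin_edges[-1],
               frequency = histogram$frequencies),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
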
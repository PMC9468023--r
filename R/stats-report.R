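#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup |Fx - Fy|` over the empirical CDFs and its p-value:
#' exact (by enumeration over the permutation distribution, via
#' [stats::ks.test()]'s exact path) when `n * m <= 100`, asymptotic
#' otherwise.
#'
#' @param x,y numeric samples, both nonempty.
#' @param alpha significance level (default 0.05).
#' @return object of class `ks_result`: `statistic_D`, `p_value`, `reject`
#'   (`p_value < alpha`) and `alpha`.
#' @export
ks_two_sample <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  exact <- length(x) * length(y) <= 100L
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  structure(list(statistic_D = unname(res$statistic),
                 p_value = unname(res$p.value),
                 reject = unname(res$p.value) < alpha, alpha = alpha),
            class = "ks_result")
}

#' Pairwise K-S test matrix over labeled samples
#'
#' @param distributions named list of numeric samples (>= 2 groups).
#' @param alpha significance level.
#' @return list of symmetric matrices `D`, `p` and `reject`; the diagonal
#'   carries the identity results (D = 0, p = 1, no rejection).
#' @export
pairwise_ks_matrix <- function(distributions, alpha = 0.05) {
  g <- names(distributions)
  stopifnot(length(g) >= 2L, !is.null(g))
  n <- length(g)
  D <- matrix(0, n, n, dimnames = list(g, g))
  p <- matrix(1, n, n, dimnames = list(g, g))
  reject <- matrix(FALSE, n, n, dimnames = list(g, g))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    r <- ks_two_sample(distributions[[a]], distributions[[b]], alpha)
    D[a, b] <- D[b, a] <- r$statistic_D
    p[a, b] <- p[b, a] <- r$p_value
    reject[a, b] <- reject[b, a] <- r$reject
  }
  list(D = D, p = p, reject = reject, alpha = alpha)
}

#' Rank clusters by fractality
#'
#' Orders clusters by ascending mean LCFD and maps them to fractality
#' categories (`less`/`medium`/`more` for K = 3).  Tied means are broken by
#' kurtosis (higher = more fractal), with a message.
#'
#' @param stats data frame from [cluster_stats()] (columns `cluster`,
#'   `mean`, `kurtosis`).
#' @return data frame with `cluster`, `mean`, `rank` and `category`,
#'   ordered from least to most fractal.
#' @export
rank_clusters_by_fractality <- function(stats) {
  stopifnot(nrow(stats) >= 1L, all(c("cluster", "mean") %in% names(stats)))
  kurt <- if ("kurtosis" %in% names(stats)) stats$kurtosis else
    rep(0, nrow(stats))
  if (anyDuplicated(stats$mean))
    message("tied cluster means: ranking ties broken by kurtosis")
  ord <- order(stats$mean, kurt)
  K <- nrow(stats)
  categories <- switch(as.character(K),
                       `1` = "less",
                       `2` = c("less", "more"),
                       `3` = c("less", "medium", "more"),
                       paste0("level_", seq_len(K)))
  data.frame(cluster = stats$cluster[ord], mean = stats$mean[ord],
             rank = seq_len(K), category = categories,
             stringsAsFactors = FALSE)
}

#' Kurtosis distance between two distributions
#'
#' @param k_a,k_b finite kurtosis values.
#' @return the absolute difference `|k_a - k_b|`.
#' @export
kurtosis_distance <- function(k_a, k_b) {
  stopifnot(is.finite(k_a), is.finite(k_b))
  abs(k_a - k_b)
}

#' Fractal composition of the source classes
#'
#' For every source class, the fraction of its patches whose cluster falls
#' in each fractality category.
#'
#' @param assignments named integer vector, patch id -> cluster id.
#' @param ranking data frame from [rank_clusters_by_fractality()].
#' @param source_labels named character vector, patch id -> source class.
#' @return data frame: rows = source classes, columns = categories in rank
#'   order; each row sums to 1.
#' @export
fractal_composition <- function(assignments, ranking, source_labels) {
  ids <- names(assignments)
  if (anyNA(assignments) || !all(ids %in% names(source_labels)))
    stop("every patch needs both a cluster assignment and a source label")
  cat_of <- stats::setNames(ranking$category, as.character(ranking$cluster))
  cats <- cat_of[as.character(assignments)]
  if (anyNA(cats)) stop("assignment refers to a cluster missing from ranking")
  tab <- table(class = source_labels[ids],
               category = factor(cats, levels = ranking$category))
  frac <- prop.table(tab, margin = 1L)
  out <- as.data.frame.matrix(frac)
  out <- cbind(data.frame(class = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Stacked-bar plot of a fractal composition
#'
#' @param composition data frame from [fractal_composition()].
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the matrix passed to [graphics::barplot()].
#' @importFrom grDevices png dev.off gray.colors
#' @importFrom graphics barplot legend par
#' @export
plot_fractal_composition <- function(composition, file = NULL) {
  M <- t(as.matrix(composition[, -1L, drop = FALSE]))
  colnames(M) <- composition$class
  if (!is.null(file)) {
    grDevices::png(file, width = 640L, height = 480L)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(M, col = grDevices::gray.colors(nrow(M)),
                    ylab = "fraction of patches",
                    legend.text = rownames(M),
                    args.legend = list(x = "topright", bg = "white"))
  invisible(M)
}
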
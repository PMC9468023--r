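small_config <- function(epochs = 8L) {
  classifier_config(n_classes = 3L, epochs = epochs, batch_size = 16L,
                    learning_rate = 0.05, seed = 11L)
}

test_that("60:40 split is stratified, exact and a partition", {
  patches <- banded_patches(10L)
  sp <- split_60_40(patches, seed = 2)
  tr <- vapply(sp$training, `[[`, "", "class_label")
  te <- vapply(sp$testing, `[[`, "", "class_label")
  expect_equal(as.integer(table(tr)), rep(6L, 3))
  expect_equal(as.integer(table(te)), rep(4L, 3))
  ids <- function(x) sort(vapply(x, `[[`, "", "patch_id"))
  expect_equal(sort(c(ids(sp$training), ids(sp$testing))),
               ids(patches))
  expect_length(intersect(ids(sp$training), ids(sp$testing)), 0L)
  # 705 per class would give 423 / 282
  expect_equal(round(0.6 * 705), 423)
  one <- list(new_patch(matrix(1, 8, 8), "q", c(0L, 0L), "a"),
              new_patch(matrix(1, 8, 8), "r", c(0L, 0L), "b"))
  expect_error(split_60_40(one), "at least 2")
})

test_that("network gradients match numerical differentiation", {
  set.seed(42)
  net <- demtex:::init_small_cnn(c(3L, 4L, 5L), 3L, 8L)
  N <- 3L
  X <- matrix(rnorm(64 * N), 64, N)
  y <- c(1L, 2L, 3L)
  Y <- matrix(0, 3, N); Y[cbind(y, seq_len(N))] <- 1
  fw <- demtex:::cnn_forward(net, X, cache = TRUE)
  gr <- demtex:::cnn_backward(net, fw, Y)
  loss_at <- function(nn) {
    p <- demtex:::cnn_forward(nn, X)$probs
    -sum(Y * log(pmax(p, 1e-12))) / N
  }
  eps <- 1e-5
  for (nm in names(net$params)) {
    w <- net$params[[nm]]
    idx <- sample(length(w), min(4L, length(w)))
    for (i in idx) {
      n2 <- net
      n2$params[[nm]][i] <- w[i] + eps
      up <- loss_at(n2)
      n2$params[[nm]][i] <- w[i] - eps
      dn <- loss_at(n2)
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-5,
                   info = paste("param", nm))
    }
  }
})

test_that("trivially separable classes are learned almost perfectly", {
  patches <- banded_patches(12L)
  clf <- train_classifier(patches, small_config())
  probs <- predict(clf, patches)
  expect_equal(unname(rowSums(probs)), rep(1, length(patches)),
               tolerance = 1e-9)
  pred <- clf$classes[max.col(probs, ties.method = "first")]
  truth <- vapply(patches, `[[`, "", "class_label")
  expect_gte(mean(pred == truth), 0.99)
})

test_that("training is deterministic given the seed", {
  patches <- banded_patches(6L)
  cfg <- small_config(epochs = 3L)
  p1 <- predict(train_classifier(patches, cfg), patches)
  p2 <- predict(train_classifier(patches, cfg), patches)
  expect_identical(p1, p2)
})

test_that("densenet121 backbone is declared but unavailable", {
  cfg <- classifier_config(backbone = "densenet121")
  expect_error(train_classifier(banded_patches(2L), cfg), "densenet121")
})

test_that("cluster prediction tabulates a correct confusion matrix", {
  patches <- banded_patches(10L)
  clf <- train_classifier(patches, small_config())
  res <- predict_clusters(clf, patches)
  expect_length(res$assignments, 30L)
  expect_true(all(res$assignments %in% 1:3))
  # counting oracle: column sums equal cluster sizes
  expect_equal(unname(colSums(res$confusion)),
               unname(vapply(1:3, function(k)
                 sum(res$assignments == k), 0L)))
  expect_equal(sum(res$confusion), 30L)
  # separable fixture: the confusion matrix is diagonal up to permutation
  expect_equal(sum(apply(res$confusion, 1, max)), 30L)
})

test_that("iterative aggregation yields a total partition with sane books", {
  patches <- banded_patches(10L)  # 30-patch toy database
  cfg <- small_config()
  state0 <- initial_clustering(patches, cfg, seed = 3)
  ids <- vapply(patches, `[[`, "", "patch_id")
  # round 0 books: TRAINING(0) and TESTING(0) partition the database
  expect_length(intersect(state0$training_ids, state0$testing_ids), 0L)
  expect_setequal(c(state0$training_ids, state0$testing_ids), ids)
  expect_setequal(names(state0$assignments), state0$testing_ids)

  final <- iterate_cluster_aggregation(state0, patches, cfg)
  expect_setequal(names(final$assignments), ids)
  expect_false(anyDuplicated(names(final$assignments)) > 0)
  expect_true(all(final$assignments %in% 1:3))

  # set-algebra oracle on every recorded round
  for (h in final$history) {
    expect_length(intersect(h$training, h$testing), 0L)
    expect_length(intersect(h$training, h$remainder), 0L)
    expect_length(intersect(h$testing, h$remainder), 0L)
    expect_setequal(c(h$training, h$testing, h$remainder), ids)
  }
  # the first aggregation round swaps roles: clustered TESTING(0) trains,
  # and its testing subset comes from the unclustered TRAINING(0)
  h1 <- final$history[[2]]
  expect_setequal(h1$training, state0$testing_ids)
  expect_true(all(h1$testing %in% state0$training_ids))
})

test_that("empty remainder at entry returns the state unchanged", {
  patches <- banded_patches(4L)
  cfg <- small_config(epochs = 2L)
  state0 <- initial_clustering(patches, cfg, seed = 5)
  # cluster everything by hand, then iterate
  ids <- vapply(patches, `[[`, "", "patch_id")
  state0$assignments <- setNames(rep(1L, length(ids)), ids)
  out <- iterate_cluster_aggregation(state0, patches, cfg)
  expect_identical(out$assignments, state0$assignments)
  expect_equal(out$iteration_j, state0$iteration_j)
})

test_that("purity is 1 for perfect clusterings and 1/K for label-blind ones", {
  ids <- paste0("p", 1:12)
  labels <- setNames(rep(c("a", "b", "c"), each = 4), ids)
  perfect <- setNames(rep(1:3, each = 4), ids)
  expect_equal(cluster_purity(perfect, labels), 1)
  blind <- setNames(rep(1L, 12), ids)
  expect_equal(cluster_purity(blind, labels), 1 / 3)
})
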
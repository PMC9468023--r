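#' Classifier configuration for Stage 2
#'
#' @param backbone `"small_cnn"` (three 3x3 convolution blocks with max
#'   pooling, global average pooling and a softmax head, trained from
#'   scratch) or `"densenet121"` (declared for interface completeness; not
#'   provided by this package).
#' @param n_classes number of classes / clusters K (>= 2).
#' @param epochs,batch_size,learning_rate,momentum,weight_decay SGD
#'   hyperparameters.
#' @param input_side side of the square input fed to the network; patches
#'   are reduced to this side by block averaging (the stem).
#' @param filters convolution filter counts of the three blocks.
#' @param seed integer seed controlling initialization and batch order.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(backbone = c("small_cnn", "densenet121"),
                              n_classes = 3L, epochs = 30L, batch_size = 32L,
                              learning_rate = 0.05, momentum = 0.9,
                              weight_decay = 1e-4, input_side = 32L,
                              filters = c(8L, 16L, 32L), seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(n_classes >= 2L, epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, input_side %% 8L == 0L)
  structure(list(backbone = backbone, n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 input_side = as.integer(input_side),
                 filters = as.integer(filters), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Stratified 60:40 training/testing split
#'
#' Splits a balanced patch list 60:40 within every class, the ratio used
#' for the initial clustering round.
#'
#' @param patches balanced list of [new_patch()] objects.
#' @param seed integer seed.
#' @return list with `training` and `testing` patch lists (a partition).
#' @export
split_60_40 <- function(patches, seed = 1) {
  labels <- vapply(patches, `[[`, "", "class_label")
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 patches")
  set.seed(seed)
  train_idx <- unlist(lapply(names(counts), function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(0.6 * length(idx)))
  }))
  list(training = patches[sort(train_idx)],
       testing = patches[sort(setdiff(seq_along(patches), train_idx))])
}

# stack patches into the network input matrix (input_side^2, N) via
# block-average stem; standardization constants are estimated on the
# training set and stored with the model
patch_tensor <- function(patches, input_side) {
  side <- nrow(patches[[1]]$pixels)
  stopifnot(side %% input_side == 0L)
  f <- side %/% input_side
  S <- matrix(0, side, input_side)
  for (j in seq_len(input_side)) S[((j - 1L) * f + 1L):(j * f), j] <- 1 / f
  vapply(patches, function(p) as.numeric(crossprod(S, p$pixels) %*% S),
         numeric(input_side^2))
}

#' Train the patch classifier
#'
#' Trains the configured backbone on patch images against `labels`
#' (source-class labels by default, cluster labels in later aggregation
#' rounds).  Training is deterministic given `config$seed`.
#'
#' @param patches list of [new_patch()] objects.
#' @param config a [classifier_config()].
#' @param labels optional character/integer label vector; defaults to the
#'   patches' `class_label`.
#' @param classes optional fixed class universe (the softmax output order);
#'   defaults to the sorted unique labels.  Useful in aggregation rounds
#'   where a cluster may be temporarily empty.
#' @return object of class `patch_classifier` with a [predict][stats::predict]
#'   method returning per-class probabilities.
#' @export
train_classifier <- function(patches, config, labels = NULL, classes = NULL) {
  stopifnot(inherits(config, "classifier_config"))
  if (config$backbone == "densenet121")
    stop("the densenet121 backbone is not provided by this package; ",
         "use backbone = \"small_cnn\"")
  if (is.null(labels)) labels <- vapply(patches, `[[`, "", "class_label")
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  if (!all(as.character(labels) %in% classes))
    stop("labels outside the declared class universe")
  if (length(classes) != config$n_classes)
    stop("labels contain ", length(classes), " classes but config declares ",
         config$n_classes)
  y <- match(as.character(labels), classes)
  X <- patch_tensor(patches, config$input_side)
  mu <- mean(X); sdv <- stats::sd(X)
  if (sdv == 0) sdv <- 1
  X <- (X - mu) / sdv
  set.seed(config$seed)
  net <- init_small_cnn(config$filters, config$n_classes, config$input_side)
  net <- cnn_train(net, X, y, config$epochs, config$batch_size,
                   config$learning_rate, config$momentum, config$weight_decay)
  structure(list(net = net, classes = classes, mu = mu, sd = sdv,
                 config = config),
            class = "patch_classifier")
}

#' Predict class probabilities for patches
#'
#' @param object a [train_classifier()] model.
#' @param patches list of [new_patch()] objects.
#' @param ... unused.
#' @return numeric matrix (patches x classes) of probabilities; rows sum
#'   to 1.
#' @export
predict.patch_classifier <- function(object, patches, ...) {
  X <- (patch_tensor(patches, object$config$input_side) - object$mu) /
    object$sd
  probs <- t(cnn_forward(object$net, X)$probs)
  colnames(probs) <- object$classes
  rownames(probs) <- vapply(patches, `[[`, "", "patch_id")
  probs
}

#' Assign patches to clusters from classifier predictions
#'
#' Each patch is assigned to the argmax predicted label (ties broken by the
#' lowest cluster index); the predicted label index *is* the cluster id, so
#' the confusion matrix columns define the clusters.
#'
#' @param classifier a [train_classifier()] model.
#' @param patches list of [new_patch()] objects.
#' @param actual optional vector of actual labels for the confusion matrix;
#'   defaults to the patches' `class_label`.
#' @return list with `assignments` (named integer vector, patch id ->
#'   cluster id in `1..K`) and `confusion` (rows = actual labels, columns =
#'   predicted clusters).
#' @export
predict_clusters <- function(classifier, patches, actual = NULL) {
  probs <- predict(classifier, patches)
  pred <- max.col(probs, ties.method = "first")
  ids <- rownames(probs)
  if (is.null(actual)) actual <- vapply(patches, `[[`, "", "class_label")
  K <- length(classifier$classes)
  confusion <- table(actual = factor(actual),
                     predicted = factor(pred, levels = seq_len(K)))
  list(assignments = stats::setNames(pred, ids),
       confusion = unclass(confusion))
}

#' Cluster-state bookkeeping for the iterative aggregation
#'
#' @param training_ids,testing_ids,remainder_ids disjoint patch-id sets.
#' @param assignments named integer vector of cluster assignments.
#' @param confusion confusion matrix of the latest round.
#' @param iteration_j iteration counter.
#' @return object of class `cluster_state` with a `history` list recording,
#'   per round, the TRAINING(j)/TESTING(j)/remainder partition.
#' @export
cluster_state <- function(training_ids, testing_ids, remainder_ids,
                          assignments, confusion, iteration_j = 0L) {
  stopifnot(!anyDuplicated(c(training_ids, testing_ids, remainder_ids)))
  structure(list(iteration_j = as.integer(iteration_j),
                 training_ids = training_ids, testing_ids = testing_ids,
                 remainder_ids = remainder_ids, assignments = assignments,
                 confusion = confusion,
                 history = list(list(j = as.integer(iteration_j),
                                     training = training_ids,
                                     testing = testing_ids,
                                     remainder = remainder_ids))),
            class = "cluster_state")
}

#' Initial clustering round (confusion-matrix cluster definition)
#'
#' Trains the classifier on TRAINING(0) with source-class labels and
#' clusters TESTING(0) by predicted label; the confusion-matrix columns
#' (predicted labels) define the clusters.
#'
#' @param patches balanced list of [new_patch()] objects.
#' @param config a [classifier_config()].
#' @param seed integer seed for the 60:40 split.
#' @return a [cluster_state()] holding assignments for TESTING(0).
#' @export
initial_clustering <- function(patches, config, seed = 1) {
  sp <- split_60_40(patches, seed)
  cfg <- config
  cfg$seed <- derive_seed(config$seed, "initial")
  clf <- train_classifier(sp$training, cfg)
  res <- predict_clusters(clf, sp$testing)
  cluster_state(training_ids = vapply(sp$training, `[[`, "", "patch_id"),
                testing_ids = vapply(sp$testing, `[[`, "", "patch_id"),
                remainder_ids = character(0),
                assignments = res$assignments, confusion = res$confusion,
                iteration_j = 0L)
}

#' Iterative cluster aggregation
#'
#' Propagates cluster labels to the whole patch database.  At each round
#' TRAINING(j) is the set of patches clustered so far (their cluster labels
#' are the training targets) and a testing subset is drawn from the
#' unclustered pool to maintain the 60:40 train:test ratio; a fresh
#' classifier is trained and the subset clustered.  Rounds continue while
#' the unclustered remainder is at least 40% of the current train+test
#' total; a final round then clusters everything left, yielding a total
#' partition into K clusters.
#'
#' @param state a [cluster_state()] from [initial_clustering()].
#' @param patches the full balanced patch list.
#' @param config a [classifier_config()].
#' @return the final [cluster_state()]; `assignments` covers every patch.
#' @export
iterate_cluster_aggregation <- function(state, patches, config) {
  stopifnot(inherits(state, "cluster_state"))
  all_ids <- vapply(patches, `[[`, "", "patch_id")
  names(patches) <- all_ids
  j <- state$iteration_j
  repeat {
    clustered <- names(state$assignments)
    pool <- setdiff(all_ids, clustered)
    if (length(pool) == 0L) break
    j <- j + 1L
    ntest <- min(length(pool), round(length(clustered) * 2 / 3))
    remainder_after <- length(pool) - ntest
    final <- !(ntest >= 1L &&
                 remainder_after >= 0.4 * (length(clustered) + ntest))
    if (final) {
      test_ids <- pool
    } else {
      set.seed(derive_seed(config$seed, "draw", j))
      test_ids <- sample(pool, ntest)
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "round", j)
    clf <- train_classifier(patches[clustered], cfg,
                            labels = state$assignments[clustered],
                            classes = as.character(
                              seq_len(ncol(state$confusion))))
    res <- predict_clusters(clf, patches[test_ids],
                            actual = vapply(patches[test_ids], `[[`, "",
                                            "class_label"))
    state$assignments <- c(state$assignments, res$assignments)
    state$confusion <- res$confusion
    state$iteration_j <- j
    state$training_ids <- clustered
    state$testing_ids <- test_ids
    state$remainder_ids <- setdiff(pool, test_ids)
    state$history[[length(state$history) + 1L]] <-
      list(j = j, training = clustered, testing = test_ids,
           remainder = state$remainder_ids)
    if (final) break
  }
  state
}

#' Stage 2 end to end: balance, split, cluster, aggregate
#'
#' @param patches list of [new_patch()] objects (will be class-balanced).
#' @param config a [classifier_config()].
#' @param seed integer seed for balancing and splitting.
#' @return list with `patches` (cluster labels filled in), `state` (final
#'   [cluster_state()]) and `initial_confusion`.
#' @export
cluster_patches <- function(patches, config, seed = 1) {
  balanced <- balance_classes(patches, seed = derive_seed(seed, "balance"))
  state0 <- initial_clustering(balanced, config,
                               seed = derive_seed(seed, "split"))
  initial_confusion <- state0$confusion
  state <- iterate_cluster_aggregation(state0, balanced, config)
  for (i in seq_along(balanced))
    balanced[[i]]$cluster_label <-
      unname(state$assignments[balanced[[i]]$patch_id])
  list(patches = balanced, state = state,
       initial_confusion = initial_confusion)
}

#' Mean cluster purity against source labels
#'
#' @param assignments named integer vector, patch id -> cluster.
#' @param labels named character vector, patch id -> source class.
#' @return overall purity: the fraction of patches belonging to their
#'   cluster's majority class.
#' @export
cluster_purity <- function(assignments, labels) {
  labels <- labels[names(assignments)]
  tab <- table(cluster = assignments, class = labels)
  sum(apply(tab, 1L, max)) / sum(tab)
}
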
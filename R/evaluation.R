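dimension_classes <- function(dimension = c("arousal", "valence")) {
  dimension <- match.arg(dimension)
  if (dimension == "arousal") c(negative = "low", positive = "high")
  else c(negative = "negative", positive = "positive")
}

# Binary 0/1 labels of a windowed dataset for one emotion dimension.
window_labels <- function(wd, dimension) {
  cls <- dimension_classes(dimension)
  col <- paste0(dimension, "_class")
  as.integer(wd$meta[[col]] == cls[["positive"]])
}

# Apply a channel arrangement to a window array.  2D orderings permute the
# channel rows; the 3D physical order stacks windows onto the scalp grid.
arrange_windows <- function(X, channel_labels, arrangement) {
  method <- arrangement$method
  if (method %in% c("none", "identity")) return(X)
  if (method == "physical3d") {
    layout <- default_grid_layout()
    T_ <- dim(X)[2]; n <- dim(X)[3]
    G <- array(0, dim = c(layout$width, layout$height, T_, n))
    pl <- layout$placement
    for (i in seq_len(nrow(pl))) {
      ch <- match(pl$label[i], channel_labels)
      G[pl$col[i] + 1L, pl$row[i] + 1L, , ] <- X[ch, , ]
    }
    return(G)
  }
  ord <- match(arrangement$order, channel_labels)
  stopifnot(!anyNA(ord), length(ord) == length(channel_labels))
  X[ord, , , drop = FALSE]
}

# Resolve an arrangement request against training-fold signals only, so no
# test-subject statistics can leak into the channel ordering.
resolve_arrangement <- function(arrangement, X_train, channel_labels) {
  method <- arrangement$method
  if (method %in% c("none", "identity", "physical3d")) return(arrangement)
  if (method == "random") {
    if (is.null(arrangement$seed)) stop("random arrangement needs a seed")
    co <- order_random(channel_labels, arrangement$seed)
    arrangement$order <- co$order
    return(arrangement)
  }
  if (method %in% c("maxcbo", "mincbo")) {
    flat <- matrix(X_train, nrow = dim(X_train)[1])
    rownames(flat) <- channel_labels
    corr <- correlation_matrix(flat)
    co <- if (method == "maxcbo") order_maxcbo(corr) else order_mincbo(corr)
    arrangement$order <- co$order
    return(arrangement)
  }
  stop("unknown arrangement method: ", method)
}

#' CNN trainer factory for the cross-validation protocols
#'
#' Returns a trainer closure (signature `X_train, y_train, X_test, seed`)
#' that builds the requested architecture for the training input shape,
#' fits it with [train_cnn()] and predicts hard labels for the test
#' windows.  The evaluation protocols accept any function with this
#' signature, which is how light-weight reference classifiers are injected
#' in tests.
#'
#' @param architecture Architecture name (see [cnn_architectures()]).
#' @param mode `"2D"` or `"3D"`.
#' @param config A [train_config()]; its seed is combined with the per-fold
#'   seed.
#' @return A trainer function.
#' @export
cnn_trainer <- function(architecture = "3Conv", mode = "2D",
                        config = train_config(seed = 1L)) {
  force(architecture); force(mode); force(config)
  function(X_train, y_train, X_test, seed) {
    spec <- architecture_spec(architecture, mode)
    d <- length(dim(X_train)) - 1L
    input_shape <- dim(X_train)[seq_len(d)]
    cfg <- config
    cfg$seed <- child_seed(config$seed, "fold", seed)
    model <- build_model(spec, input_shape, seed = cfg$seed)
    model <- train_cnn(model, X_train, y_train, cfg)
    predict(model, X_test)$class
  }
}

fold_result <- function(id, truth, pred, test_idx, train_idx) {
  counts <- confusion_counts(truth, pred, positive = 1L)
  list(id = id, n_test = length(truth), counts = counts,
       accuracy = accuracy(counts), mcc = mcc(counts),
       test_idx = test_idx, train_idx = train_idx)
}

assemble_result <- function(condition, folds) {
  per <- do.call(rbind, lapply(folds, function(f)
    data.frame(id = f$id, n = f$n_test, accuracy = f$accuracy, mcc = f$mcc)))
  pooled <- Reduce(add_counts, lapply(folds, `[[`, "counts"))
  structure(list(condition = condition, folds = folds, per_subject = per,
                 pooled = list(counts = pooled, accuracy = accuracy(pooled),
                               mcc = mcc(pooled)),
                 mean_accuracy = mean(per$accuracy),
                 mean_mcc = mean(per$mcc)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cc <- x$condition
  cat(sprintf("<experiment_result> %s: %d folds, mean acc %.2f%% (mcc %.4f), pooled acc %.2f%% (mcc %.4f)\n",
              paste(unlist(cc), collapse = " / "), length(x$folds),
              x$mean_accuracy, x$mean_mcc, x$pooled$accuracy, x$pooled$mcc))
  invisible(x)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the classifier is trained on all other subjects'
#' windows and tested on the held-out subject.  Data-dependent channel
#' orderings (MaxCBO/MinCBO) are recomputed per fold from the training
#' subjects only.  Subjects without windows are skipped and reported.
#'
#' @param wd A `windowed_dataset`.
#' @param dimension `"arousal"` or `"valence"`.
#' @param arrangement List with `method` (one of `"none"`, `"random"`,
#'   `"physical3d"`, `"maxcbo"`, `"mincbo"`) and, for `"random"`, a `seed`.
#' @param trainer A trainer function (see [cnn_trainer()]).
#' @param seed Integer seed mixed into each fold's trainer seed.
#' @return An `experiment_result` (folds carry their window index sets, so
#'   the subject partition is auditable).
#' @export
loso_cv <- function(wd, dimension, arrangement = list(method = "none"),
                    trainer = cnn_trainer(), seed = 1L) {
  subjects <- sort(unique(wd$meta$subject_id))
  if (length(subjects) < 2) stop("LOSO needs at least two subjects")
  y <- window_labels(wd, dimension)
  folds <- list(); skipped <- character(0)
  for (s in subjects) {
    test_idx <- which(wd$meta$subject_id == s)
    train_idx <- which(wd$meta$subject_id != s)
    if (!length(test_idx)) {
      skipped <- c(skipped, sprintf("subject %s has no windows", s))
      next
    }
    stopifnot(length(intersect(test_idx, train_idx)) == 0)
    X_train <- wd$X[, , train_idx, drop = FALSE]
    arr <- resolve_arrangement(arrangement, X_train, wd$channel_labels)
    Xtr <- arrange_windows(X_train, wd$channel_labels, arr)
    Xte <- arrange_windows(wd$X[, , test_idx, drop = FALSE],
                           wd$channel_labels, arr)
    pred <- trainer(Xtr, y[train_idx], Xte, child_seed(seed, "subject", s))
    folds[[length(folds) + 1L]] <- fold_result(s, y[test_idx], pred,
                                               test_idx, train_idx)
  }
  res <- assemble_result(
    list(protocol = "loso", dimension = dimension,
         arrangement = arrangement$method), folds)
  res$skipped <- skipped
  res
}

#' Stratified k-fold cross-validation within one subject
#'
#' The subject-dependent protocol: windows of a single subject are split
#' into `k` class-stratified folds (fold class proportions within one
#' window of the subject's overall proportions).
#'
#' @param wd A `windowed_dataset` restricted to one subject.
#' @param dimension `"arousal"` or `"valence"`.
#' @param k Number of folds.
#' @param trainer A trainer function (see [cnn_trainer()]).
#' @param seed Integer seed for the stratified shuffle and fold trainers.
#' @return An `experiment_result` with `k` folds.
#' @export
kfold_cv <- function(wd, dimension, k = 10, trainer = cnn_trainer(),
                     seed = 1L) {
  if (length(unique(wd$meta$subject_id)) != 1)
    stop("kfold_cv expects windows of exactly one subject")
  n <- dim(wd$X)[3]
  if (n < k) stop(sprintf("fewer windows (%d) than folds (%d)", n, k))
  y <- window_labels(wd, dimension)
  set.seed(child_seed(seed, "stratify"))
  fold_of <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- list()
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    stopifnot(length(intersect(test_idx, train_idx)) == 0)
    pred <- trainer(wd$X[, , train_idx, drop = FALSE], y[train_idx],
                    wd$X[, , test_idx, drop = FALSE],
                    child_seed(seed, "kfold", f))
    folds[[f]] <- fold_result(f, y[test_idx], pred, test_idx, train_idx)
  }
  assemble_result(list(protocol = "kfold", dimension = dimension, k = k,
                       subject = wd$meta$subject_id[1]), folds)
}
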
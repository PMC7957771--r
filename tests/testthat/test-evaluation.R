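test_that("LOSO folds partition windows by subject with no leakage", {
  wd <- tiny_windows()
  rec <- new.env(); rec$calls <- list()
  res <- loso_cv(wd, "valence", trainer = centroid_trainer(rec), seed = 1)
  expect_s3_class(res, "experiment_result")
  subjects <- sort(unique(wd$meta$subject_id))
  expect_length(res$folds, length(subjects))
  all_test <- integer(0)
  for (f in res$folds) {
    expect_length(intersect(f$test_idx, f$train_idx), 0)
    expect_setequal(unique(wd$meta$subject_id[f$test_idx]), f$id)
    expect_false(f$id %in% wd$meta$subject_id[f$train_idx])
    all_test <- c(all_test, f$test_idx)
  }
  expect_setequal(all_test, seq_len(dim(wd$X)[3]))  # exhaustive and disjoint
  expect_equal(length(all_test), length(unique(all_test)))
})

test_that("experiment results are self-consistent with their counts", {
  wd <- tiny_windows()
  res <- loso_cv(wd, "arousal", trainer = centroid_trainer(), seed = 2)
  for (f in res$folds) {
    expect_equal(f$accuracy, accuracy(f$counts))
    expect_equal(f$mcc, mcc(f$counts))
  }
  pooled <- Reduce(eegemo:::add_counts, lapply(res$folds, `[[`, "counts"))
  expect_equal(res$pooled$accuracy, accuracy(pooled))
  expect_equal(res$pooled$mcc, mcc(pooled))
  expect_equal(res$mean_accuracy, mean(res$per_subject$accuracy))
})

test_that("data-driven orderings are computed from training subjects only", {
  wd <- tiny_windows()
  seen <- new.env(); seen$orders <- list()
  spy <- function(X_train, y_train, X_test, seed) {
    # record the channel order (rownames) the fold received
    seen$orders <- c(seen$orders, list(rownames(X_train)))
    rep(0L, dim(X_test)[3])
  }
  res <- loso_cv(wd, "valence", arrangement = list(method = "maxcbo"),
                 trainer = spy, seed = 3)
  expect_length(seen$orders, length(res$folds))
  for (i in seq_along(res$folds)) {
    f <- res$folds[[i]]
    flat <- matrix(wd$X[, , f$train_idx], nrow = 12)
    rownames(flat) <- wd$channel_labels
    want <- order_maxcbo(correlation_matrix(flat))$order
    expect_identical(seen$orders[[i]], want)
  }
})

test_that("the physical 3D arrangement routes grid tensors to the trainer", {
  wd <- tiny_windows()
  shapes <- new.env(); shapes$d <- list()
  spy <- function(X_train, y_train, X_test, seed) {
    shapes$d <- c(shapes$d, list(dim(X_train)))
    rep(0L, dim(X_test)[4])
  }
  invisible(loso_cv(wd, "valence", arrangement = list(method = "physical3d"),
                    trainer = spy, seed = 4))
  for (d in shapes$d) expect_equal(d[1:3], c(5, 3, dim(wd$X)[2]))
})

test_that("stratified k-fold splits are disjoint, exhaustive and balanced", {
  wd <- tiny_windows()
  wds <- eegemo:::subset_windows(wd, which(wd$meta$subject_id == 1))
  n <- dim(wds$X)[3]
  k <- 5
  res <- kfold_cv(wds, "valence", k = k, trainer = centroid_trainer(),
                  seed = 5)
  expect_length(res$folds, k)
  all_test <- unlist(lapply(res$folds, `[[`, "test_idx"))
  expect_setequal(all_test, seq_len(n))
  expect_equal(length(all_test), n)
  y <- eegemo:::window_labels(wds, "valence")
  share <- mean(y)
  for (f in res$folds) {
    n_pos <- sum(y[f$test_idx])
    expect_lte(abs(n_pos - share * length(f$test_idx)), 1)
  }
  expect_error(kfold_cv(wds, "valence", k = n + 1), "fewer windows")
  expect_error(kfold_cv(wd, "valence", k = 2), "one subject")
})

test_that("a null synthetic dataset yields chance-level LOSO MCC", {
  mccs <- sapply(1:3, function(s) {
    cfg <- generator_config(n_subjects = 3, n_songs_per_subject = 2,
                            song_duration = 30, block_duration = c(6, 10),
                            valence_asym_gain = 0, arousal_beta_gain = 0,
                            master_seed = 100 + s)
    wd <- build_dataset(generate_dataset(cfg), window_spec(2, 0))
    loso_cv(wd, "valence", trainer = asym_trainer(), seed = s)$pooled$mcc
  })
  expect_lt(abs(mean(mccs)), 0.1)
})

test_that("the alpha-asymmetry readout recovers planted valence in LOSO", {
  cfg <- generator_config(n_subjects = 3, n_songs_per_subject = 2,
                          song_duration = 30, block_duration = c(6, 10),
                          master_seed = 55)  # default k_v = 0.8
  wd <- build_dataset(generate_dataset(cfg), window_spec(2, 0))
  res <- loso_cv(wd, "valence", trainer = asym_trainer(), seed = 9)
  expect_gt(res$pooled$accuracy, 65)
})
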
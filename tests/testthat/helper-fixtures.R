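# Shared fixtures, built lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# tiny cohort: 2 subjects x 2 songs x 30 s, short blocks so several label
# changes occur per song
tiny_config <- function(master_seed = 7, ...) {
  generator_config(n_subjects = 2, n_songs_per_subject = 2,
                   song_duration = 30, block_duration = c(6, 10),
                   master_seed = master_seed, ...)
}

tiny_dataset <- function() {
  fixture("tiny_dataset", function() generate_dataset(tiny_config()))
}

tiny_windows <- function() {
  fixture("tiny_windows", function()
    build_dataset(tiny_dataset(), window_spec(2, 0)))
}

# A cheap deterministic trainer for protocol-level tests: nearest class
# centroid on per-channel means.  Signature matches cnn_trainer()'s output.
centroid_trainer <- function(record_env = NULL) {
  function(X_train, y_train, X_test, seed) {
    if (!is.null(record_env)) {
      record_env$calls <- c(record_env$calls, list(list(
        n_train = dim(X_train)[length(dim(X_train))],
        n_test = dim(X_test)[length(dim(X_test))],
        seed = seed)))
    }
    d <- length(dim(X_train))
    nr <- prod(dim(X_train)[seq_len(d - 2)])  # spatial cells x time -> cells
    feat <- function(X) t(apply(X, d, function(w) rowMeans(matrix(w, nrow = nr))))
    ftr <- feat(X_train); fte <- feat(X_test)
    m0 <- colMeans(ftr[y_train == 0, , drop = FALSE])
    m1 <- colMeans(ftr[y_train == 1, , drop = FALSE])
    d0 <- rowSums(sweep(fte, 2, m0)^2)
    d1 <- rowSums(sweep(fte, 2, m1)^2)
    as.integer(d1 < d0)
  }
}

# Alpha-band logistic trainer: log alpha power F4 - F3 per window, sign
# rule learned from training labels.  Cheap but actually sensitive to the
# planted valence effect.
asym_trainer <- function() {
  function(X_train, y_train, X_test, seed) {
    bp <- function(X) {
      apply(X, 3, function(w)
        log(band_power(w["F4", ], 250, c(8, 13))) -
          log(band_power(w["F3", ], 250, c(8, 13))))
    }
    str <- bp(X_train); ste <- bp(X_test)
    thr <- median(str)
    flip <- mean(y_train[str > thr]) < 0.5
    pred <- as.integer(ste > thr)
    if (flip) pred <- 1L - pred
    pred
  }
}

corr_from_abs <- function(labels, abs_vals) {
  # build a symmetric correlation matrix with given |rho| off-diagonals
  n <- length(labels)
  m <- diag(n)
  dimnames(m) <- list(labels, labels)
  k <- 1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- abs_vals[k]
    k <- k + 1
  }
  m
}

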
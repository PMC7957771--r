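#' Training configuration
#'
#' Optimisation hyperparameters for [train_cnn()].  The architecture tables
#' fix the network; these settings fix how it is fitted: Adam at 1e-3,
#' minibatches of 64, at most 30 epochs with early stopping (patience 5) on
#' the loss of a window-level random validation split drawn inside the
#' training set.  The seed is mandatory: it drives initialization, the
#' validation split, shuffling and dropout, making runs reproducible.
#'
#' @param optimizer Only `"adam"` is provided.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience: training stops after
#'   `patience + 1` consecutive epochs without validation-loss improvement
#'   (so patience 0 stops one epoch past the best).
#' @param validation_fraction Fraction of training windows held out for
#'   validation, in (0, 0.5).
#' @param restore_best Restore the parameters of the best validation-loss
#'   epoch after training (default).  With `FALSE` the final-epoch
#'   parameters are kept, which suits fixed short training budgets where
#'   the window-level validation loss tracks memorization rather than
#'   generalization.
#' @param seed Mandatory integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-3,
                         batch_size = 64, max_epochs = 30, patience = 5,
                         validation_fraction = 0.1, restore_best = TRUE,
                         seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is provided")
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0)
  if (validation_fraction <= 0 || validation_fraction >= 0.5)
    stop("validation_fraction must lie in (0, 0.5)")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Expand an architecture into the internal layer plan for a given input
# shape, checking shape feasibility (same-padding convs keep the spatial
# dims; valid pooling floors them).  Activations live on zero-haloed
# canvases sized to each convolution's padding; to_canvas/recanvas ops move
# between canvas geometries.
build_plan <- function(spec, input_shape) {
  d <- if (spec$mode == "2D") 2L else 3L
  if (length(input_shape) != d)
    stop(sprintf("%s input shape must have %d dims", spec$mode, d))
  if (spec$mode == "2D" && input_shape[1] != 12L)
    stop("2D input must have 12 channel rows")
  if (spec$mode == "3D" && !all(input_shape[1:2] == c(5L, 3L)))
    stop("3D input must be a 5 x 3 grid stack")
  sd <- as.integer(input_shape)
  cin <- 1L
  arch <- spec$layers
  conv_halo <- function(k) {
    plo <- floor((k - 1) / 2)
    as.integer(pmax(plo, k - 1L - plo))
  }
  next_conv_halo <- function(j) {
    while (j <= length(arch)) {
      if (arch[[j]]$kind == "conv")
        return(conv_halo(as.integer(arch[[j]]$kernel)))
      if (arch[[j]]$kind == "fc") break
      j <- j + 1L
    }
    rep(0L, d)
  }
  plan <- list()
  cur_halo <- NULL
  flattened <- FALSE
  transposed <- FALSE
  features <- NA_integer_
  add <- function(x) plan[[length(plan) + 1L]] <<- x
  for (j in seq_along(arch)) {
    ly <- arch[[j]]
    if (ly$kind == "conv") {
      k <- as.integer(ly$kernel)
      halo <- conv_halo(k)
      if (is.null(cur_halo)) {
        add(list(type = "to_canvas", sd = sd, halo = halo))
      } else if (!all(cur_halo == halo)) {
        add(list(type = "recanvas", sd = sd, halo_in = cur_halo,
                 halo_out = halo, channels = cin))
      }
      cur_halo <- halo
      add(list(type = "conv", sd = sd, halo = halo, kernel = k,
               pad_lo = as.integer(floor((k - 1) / 2)), cin = cin,
               cout = as.integer(ly$filters)))
      cin <- as.integer(ly$filters)
    } else if (ly$kind == "pool") {
      out <- sd %/% as.integer(ly$pool)
      if (any(out < 1L))
        stop(sprintf("input too small for the pooling stack (spatial %s, pool %s)",
                     paste(sd, collapse = "x"),
                     paste(ly$pool, collapse = "x")))
      halo_out <- next_conv_halo(j + 1L)
      add(list(type = "pool", sd_in = sd, halo_in = cur_halo,
               pool = as.integer(ly$pool), sd_out = out,
               halo_out = halo_out, channels = cin))
      sd <- out
      cur_halo <- halo_out
    } else if (ly$kind == "dropout") {
      if (!flattened && j < length(arch) && arch[[j + 1L]]$kind == "fc") {
        features <- as.integer(cin * prod(sd))
        add(list(type = "flatten", sd = sd, halo = cur_halo, cin = cin,
                 features = features))
        flattened <- TRUE
        transposed <- TRUE
      }
      add(list(type = "dropout", rate = ly$rate))
    } else if (ly$kind == "fc") {
      if (!flattened) {
        features <- as.integer(cin * prod(sd))
        add(list(type = "flatten", sd = sd, halo = cur_halo, cin = cin,
                 features = features))
        flattened <- TRUE
        transposed <- TRUE
      }
      # flatten emits features x samples; fc layers emit samples x units
      add(list(type = "fc", in_features = features,
               units = as.integer(ly$units), relu = ly$units != 2L,
               tin = transposed))
      transposed <- FALSE
      features <- as.integer(ly$units)
    }
  }
  plan
}

init_params <- function(plan, seed) {
  set.seed(seed)
  lapply(plan, function(ly) {
    if (ly$type == "conv") {
      fan_in <- ly$cin * prod(ly$kernel)
      list(W = matrix(rnorm(fan_in * ly$cout, 0, sqrt(2 / fan_in)),
                      nrow = fan_in),
           b = numeric(ly$cout))
    } else if (ly$type == "fc") {
      sdv <- if (ly$relu) sqrt(2 / ly$in_features) else sqrt(1 / ly$in_features)
      list(W = matrix(rnorm(ly$in_features * ly$units, 0, sdv),
                      nrow = ly$in_features),
           b = numeric(ly$units))
    } else NULL
  })
}

#' Build an (untrained) CNN model
#'
#' Instantiates one of the table architectures for a concrete input shape
#' with He-initialized weights.  Two builds with the same seed produce
#' identical initial parameters.
#'
#' @param spec An [architecture_spec()].
#' @param input_shape `c(12, T)` for 2D mode or `c(5, 3, T)` for 3D mode
#'   (`T` = window length x sampling rate).
#' @param seed Integer seed for the initialization.
#' @return A `cnn_model` handle (untrained).
#' @export
build_model <- function(spec, input_shape, seed = 1L) {
  plan <- build_plan(spec, input_shape)
  structure(list(spec = spec, input_shape = as.integer(input_shape),
                 plan = plan, params = init_params(plan, seed),
                 trained = FALSE, history = NULL, init_seed = seed),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s (%s), input %s, %s\n", x$spec$name,
              x$spec$mode, paste(x$input_shape, collapse = "x"),
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

# Windows arrive as an array whose last dim indexes windows; earlier dims
# must equal the model input shape.
check_input <- function(model, X) {
  dX <- dim(X)
  d <- length(model$input_shape)
  if (length(dX) != d + 1 || !all(dX[seq_len(d)] == model$input_shape))
    stop(sprintf("input shape %s does not match the model input %s",
                 paste(dX, collapse = "x"),
                 paste(model$input_shape, collapse = "x")))
  dX[d + 1]
}

deep_copy_params <- function(params)
  lapply(params, function(p) if (is.null(p)) NULL else list(W = p$W + 0, b = p$b + 0))

#' Raw forward pass of a (possibly untrained) model
#'
#' The network function itself: per-window class probabilities under the
#' current parameters, trained or not.  [predict.cnn_model()] is the
#' user-facing version that insists on a trained handle.
#'
#' @param model A `cnn_model`.
#' @param X Window array (input shape x n windows).
#' @param batch_size Forward-pass chunk size.
#' @return Matrix `n x 2` of class probabilities (columns: class 0 =
#'   low/negative, class 1 = high/positive).
#' @export
forward_pass <- function(model, X, batch_size = 64L) {
  n <- check_input(model, X)
  out <- matrix(NA_real_, n, 2)
  Xm <- matrix(X, ncol = n)
  state <- cpp_state_create(model$plan, model$params)
  for (i0 in seq(1L, n, by = batch_size)) {
    i1 <- min(n, i0 + batch_size - 1L)
    r <- cpp_state_forward(state, as.numeric(Xm[, i0:i1]), i1 - i0 + 1L)
    out[i0:i1, ] <- r$prob
  }
  colnames(out) <- c("class0", "class1")
  out
}

#' Predict classes for new windows
#'
#' @param object A trained `cnn_model`.
#' @param newdata Window array (input shape x n windows).
#' @param ... Unused.
#' @return List with `prob` (n x 2 matrix) and `class` (integer 0/1,
#'   argmax).
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  if (!object$trained) stop("model has not been trained; call train_cnn() first")
  prob <- forward_pass(object, newdata)
  list(prob = prob, class = as.integer(max.col(prob) - 1L))
}

#' Train a CNN on labelled windows
#'
#' Minibatch Adam on class-weighted softmax cross-entropy (weights inverse
#' to the training-class frequencies, so imbalanced cohorts do not induce a
#' majority-class bias), with a window-level random validation split, early
#' stopping on validation loss, and restoration of the best-validation
#' parameters.  Deterministic given `config$seed`.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param X Window array (input shape x n windows).
#' @param y Integer 0/1 labels (or a 2-level factor) of length n; both
#'   classes must be present.
#' @param config A [train_config()].
#' @return The trained `cnn_model` with a `history` data frame (epoch,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train_cnn <- function(model, X, y, config) {
  n <- check_input(model, X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(length(y) == n, all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2)
    stop("training set contains a single class; refusing to fit")

  set.seed(config$seed)
  n_val <- max(1L, round(config$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) stop("no training windows left after validation split")

  Xm <- matrix(X, ncol = n)
  state <- cpp_state_create(model$plan, model$params)
  # inverse-frequency class weights from the training split
  cls_w <- length(tr_idx) / (2 * pmax(1, c(sum(y[tr_idx] == 0L),
                                           sum(y[tr_idx] == 1L))))
  w_all <- cls_w[y + 1L]

  eval_split <- function(idx) {
    probs <- matrix(NA_real_, length(idx), 2)
    for (i0 in seq(1L, length(idx), by = config$batch_size)) {
      i1 <- min(length(idx), i0 + config$batch_size - 1L)
      sel <- idx[i0:i1]
      r <- cpp_state_forward(state, as.numeric(Xm[, sel, drop = FALSE]),
                             length(sel))
      probs[i0:i1, ] <- r$prob
    }
    p_true <- probs[cbind(seq_along(idx), y[idx] + 1L)]
    list(loss = mean(-log(pmax(p_true, 1e-12))),
         acc = mean(max.col(probs) - 1L == y[idx]))
  }

  best_val <- Inf; bad <- 0L
  history <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_correct <- 0L
    for (i0 in seq(1L, length(ord), by = config$batch_size)) {
      i1 <- min(length(ord), i0 + config$batch_size - 1L)
      sel <- ord[i0:i1]
      drop_seed <- sample.int(.Machine$integer.max, 1L)
      r <- cpp_state_train_batch(state, as.numeric(Xm[, sel, drop = FALSE]),
                                 y[sel], length(sel), w_all[sel], drop_seed,
                                 config$learning_rate, 0.9, 0.999, 1e-8)
      ep_loss <- ep_loss + r$loss * length(sel)
      ep_correct <- ep_correct + r$n_correct
    }
    val <- eval_split(val_idx)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / length(ord),
      train_acc = ep_correct / length(ord),
      val_loss = val$loss, val_acc = val$acc)
    if (val$loss < best_val) {
      best_val <- val$loss
      cpp_state_snapshot(state)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > config$patience) break
    }
  }
  if (config$restore_best) cpp_state_restore(state)
  exported <- cpp_state_export(state)
  model$params <- lapply(seq_along(model$params), function(i)
    if (is.null(model$params[[i]])) NULL else exported[[i]])
  model$trained <- TRUE
  model$history <- do.call(rbind, history)
  model$train_seed <- config$seed
  model
}
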
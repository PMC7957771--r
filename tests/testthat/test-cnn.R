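test_that("layer plans reproduce independently computed shapes", {
  # shape oracle: same padding keeps spatial dims, valid pooling floors them
  shape_oracle <- function(nm, mode, T_) {
    spec <- architecture_spec(nm, mode)
    sd <- if (mode == "2D") c(12, T_) else c(5, 3, T_)
    cin <- 1
    for (ly in spec$layers) {
      if (ly$kind == "conv") cin <- ly$filters
      if (ly$kind == "pool") sd <- sd %/% ly$pool
    }
    cin * prod(sd)
  }
  for (nm in cnn_architectures()) for (mode in c("2D", "3D")) {
    T_ <- 1000
    shape <- if (mode == "2D") c(12L, T_) else c(5L, 3L, T_)
    m <- build_model(architecture_spec(nm, mode), shape, seed = 1)
    fc1 <- Filter(function(l) l$type == "fc", m$plan)[[1]]
    expect_equal(fc1$in_features, shape_oracle(nm, mode, T_))
  }
  expect_error(build_model(architecture_spec("3Conv", "3D"), c(5, 3, 3)),
               "too small")
  expect_error(build_model(architecture_spec("3Conv", "2D"), c(11, 100)),
               "12 channel rows")
})

test_that("forward passes give probability vectors and init is seeded", {
  m1 <- build_model(architecture_spec("4Conv", "2D"), c(12, 64), seed = 31)
  m2 <- build_model(architecture_spec("4Conv", "2D"), c(12, 64), seed = 31)
  m3 <- build_model(architecture_spec("4Conv", "2D"), c(12, 64), seed = 32)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  X <- array(rnorm(12 * 64 * 5), dim = c(12, 64, 5))
  p <- forward_pass(m1, X)
  expect_equal(dim(p), c(5, 2))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_identical(p, forward_pass(m1, X))  # inference is deterministic
})

test_that("the backend matches a naive double-precision reference", {
  m <- build_model(architecture_spec("3Conv", "2D"), c(12, 8), seed = 5)
  set.seed(4)
  X <- array(rnorm(12 * 8 * 2), dim = c(12, 8, 2))
  y <- c(0L, 1L)
  st <- eegemo:::cpp_state_create(m$plan, m$params)
  got <- eegemo:::cpp_state_grads(st, as.numeric(X), y, 2L, FALSE, 1)
  expect_equal(got$loss, naive_3conv_loss(m$params, X, y), tolerance = 1e-5)

  # analytic gradients against numeric differentiation of the naive net
  set.seed(8)
  for (li in c(2, 6, 9)) {
    for (i in sample(length(m$params[[li]]$W), 2)) {
      eps <- 1e-5
      p1 <- m$params; p1[[li]]$W[i] <- p1[[li]]$W[i] + eps
      p2 <- m$params; p2[[li]]$W[i] <- p2[[li]]$W[i] - eps
      num <- (naive_3conv_loss(p1, X, y) - naive_3conv_loss(p2, X, y)) / (2 * eps)
      expect_equal(got$grads[[li]]$W[i], num, tolerance = 1e-3)
    }
  }
})

test_that("training separates a constant-offset toy task", {
  set.seed(2)
  n <- 120
  X <- array(rnorm(12 * 250 * n, 0, 0.3), dim = c(12, 250, n))
  y <- rep(0:1, each = n / 2)
  X[, , y == 0] <- X[, , y == 0] - 1
  X[, , y == 1] <- X[, , y == 1] + 1
  m <- build_model(architecture_spec("3Conv", "2D"), c(12, 250), seed = 3)
  m <- train_cnn(m, X, y, train_config(seed = 7, max_epochs = 8, patience = 8))
  expect_true(m$trained)
  expect_lte(nrow(m$history), 8)
  expect_gte(tail(m$history$train_acc, 1), 0.95)
  pr <- predict(m, X)
  expect_gte(mean(pr$class == y), 0.95)
  expect_equal(rowSums(pr$prob), rep(1, n), tolerance = 1e-6)
})

test_that("training is reproducible and guards its contracts", {
  set.seed(5)
  X <- array(rnorm(12 * 32 * 30), dim = c(12, 32, 30))
  y <- rep(0:1, 15)
  cfg <- train_config(seed = 13, max_epochs = 2, patience = 2, batch_size = 16)
  spec <- architecture_spec("3Conv", "2D")
  m1 <- train_cnn(build_model(spec, c(12, 32), 9), X, y, cfg)
  m2 <- train_cnn(build_model(spec, c(12, 32), 9), X, y, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  expect_error(train_cnn(build_model(spec, c(12, 32), 9), X, rep(0L, 30), cfg),
               "single class")
  expect_error(predict(build_model(spec, c(12, 32), 9), X), "not been trained")
  expect_error(predict(m1, array(rnorm(12 * 64 * 2), dim = c(12, 64, 2))),
               "does not match")
  expect_error(train_config(seed = NULL), "seed")
  expect_error(train_config(seed = 1, validation_fraction = 0.9), "0.5")
})

test_that("patience-0 stops exactly one epoch past the best validation", {
  set.seed(5)
  X <- array(rnorm(12 * 32 * 40), dim = c(12, 32, 40))
  y <- rep(0:1, 20)
  # an aggressive step size makes the validation loss oscillate
  cfg <- train_config(seed = 21, learning_rate = 0.5, max_epochs = 10,
                      patience = 0, batch_size = 16)
  m <- train_cnn(build_model(architecture_spec("3Conv", "2D"), c(12, 32), 2),
                 X, y, cfg)
  h <- m$history
  expect_lte(nrow(h), 10)
  if (nrow(h) < 10) expect_equal(which.min(h$val_loss), nrow(h) - 1)
})
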
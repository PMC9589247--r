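# Small separable fixture: class shifts on a handful of columns.
make_cnn_fixture <- function(n = 80, p = 50, effect = 2.5, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, 1:5] <- X[, 1:5] + effect * y
  list(X = X, y = y)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(conv_layers = list(c(5, 8), c(3, 8)), dense_units = 16,
         epochs = 15, batch_size = 16),
    list(...)
  )
  do.call(cnn_config, args)
}

test_that("split_train_val is stratified, disjoint, exhaustive, deterministic", {
  y <- rep(c(1L, 0L), c(60, 40))
  s <- split_train_val(y, 0.8, seed = 3)
  expect_length(intersect(s$train, s$val), 0)
  expect_setequal(c(s$train, s$val), seq_along(y))
  expect_equal(sum(y[s$train] == 1), 48)
  expect_equal(sum(y[s$train] == 0), 32)

  s2 <- split_train_val(y, 0.8, seed = 3)
  expect_identical(s, s2)

  yb <- rep(c(1L, 0L), each = 5)
  sb <- split_train_val(yb, 0.5, seed = 1)
  expect_length(sb$train, 5)
  expect_error(split_train_val(c(1L, 0L, 0L), 0.5), class = "dbpkit_value_error")
})

test_that("backprop gradients match numerical differentiation", {
  ns <- asNamespace("dbpkit")
  set.seed(42)
  n <- 4; D <- 17
  X <- matrix(rnorm(n * D), n, D)
  onehot <- cbind(c(0, 1, 0, 1), c(1, 0, 1, 0))
  cfg <- cnn_config(conv_layers = list(c(4, 3), c(3, 2)), dense_units = 5,
                    dropout = 0, seed = 9)
  plan <- ns$plan_architecture(D, cfg)
  params <- ns$init_params(plan, cfg$dense_units)
  loss_at <- function(pp) {
    fwd <- ns$cnn_forward(X, pp, plan, 0, training = FALSE)
    ns$softmax_xent(fwd$logits, onehot)$loss
  }
  fwd <- ns$cnn_forward(X, params, plan, 0, training = TRUE)
  ce <- ns$softmax_xent(fwd$logits, onehot)
  grads <- ns$cnn_backward(ce$dZ, fwd, params, plan)
  eps <- 1e-6
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(5, length(params[[nm]])))) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      lp <- loss_at(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      lm <- loss_at(p2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("train_cnn separates shifted classes and is seed-reproducible", {
  fx <- make_cnn_fixture()
  m <- train_cnn(fx$X, fx$y, small_config(seed = 7))
  expect_gte(tail(m$history$val_accuracy, 1), 0.75)
  # training loss trends downward on separable data (trend, not per-epoch)
  h <- m$history$loss
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))

  m2 <- train_cnn(fx$X, fx$y, small_config(seed = 7))
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
})

test_that("shuffled labels give chance-level validation accuracy", {
  fx <- make_cnn_fixture(n = 100)
  set.seed(5)
  ysh <- sample(fx$y)
  m <- train_cnn(fx$X, ysh, small_config(seed = 5, epochs = 10))
  expect_lt(abs(tail(m$history$val_accuracy, 1) - 0.5), 0.25)
})

test_that("epochs = 0 leaves an untrained model predicting near chance", {
  fx <- make_cnn_fixture()
  m <- train_cnn(fx$X, fx$y, small_config(epochs = 0, seed = 2))
  expect_equal(nrow(m$history), 0)
  pp <- predict_proba(m, fx$X)
  expect_true(all(abs(pp$prob_0 + pp$prob_1 - 1) < 1e-6))
  expect_lt(abs(mean(pp$prob_1) - 0.5), 0.45)
})

test_that("every optimizer completes a short training run", {
  fx <- make_cnn_fixture(n = 40, p = 30)
  for (opt in c("adam", "sgd", "adagrad", "rmsprop", "adadelta", "adamax")) {
    m <- train_cnn(fx$X, fx$y,
                   cnn_config(conv_layers = list(c(3, 4)), dense_units = 8,
                              epochs = 3, optimizer = opt, seed = 1))
    expect_equal(nrow(m$history), 3)
    expect_true(all(is.finite(m$history$loss)))
  }
})

test_that("predict_proba rows sum to 1 and softmax is overflow-stable", {
  ns <- asNamespace("dbpkit")
  P <- ns$softmax_rows(matrix(c(0, 0, 1000, 0, -1000, 5), 3, 2, byrow = TRUE))
  expect_equal(rowSums(P), rep(1, 3))
  expect_equal(P[1, ], c(0.5, 0.5))
  expect_equal(P[2, 1], 1, tolerance = 1e-12)
  expect_true(all(is.finite(P)))

  fx <- make_cnn_fixture()
  m <- train_cnn(fx$X, fx$y, small_config(epochs = 2))
  pp <- predict_proba(m, fx$X)
  expect_equal(pp$prob_0 + pp$prob_1, rep(1, nrow(fx$X)), tolerance = 1e-6)
})

test_that("predict_proba rejects mismatched vocabularies by name", {
  fx <- make_cnn_fixture(p = 20)
  m <- train_cnn(fx$X, fx$y,
                 cnn_config(conv_layers = list(c(3, 4)), dense_units = 8,
                            epochs = 1, seed = 1))
  Xbad <- fx$X
  colnames(Xbad)[3] <- "rogue"
  expect_error(predict_proba(m, Xbad), "rogue",
               class = "dbpkit_vocabulary_error")
  # permuted columns are accepted and re-aligned
  Xperm <- fx$X[, rev(colnames(fx$X))]
  expect_equal(predict_proba(m, Xperm), predict_proba(m, fx$X))
})

test_that("model bundles round-trip bit-for-bit and detect corruption", {
  fx <- make_cnn_fixture(p = 30)
  m <- train_cnn(fx$X, fx$y, small_config(epochs = 3, seed = 11))
  dir <- tempfile()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(predict_proba(m2, fx$X), predict_proba(m, fx$X))
  expect_identical(m2$vocabulary, m$vocabulary)
  expect_equal(unclass(m2$config), unclass(m$config), tolerance = 0)

  # corrupt the weights: load must refuse
  con <- file(file.path(dir, "weights.rds"), "ab")
  writeBin(as.raw(1:8), con)
  close(con)
  expect_error(load_model(dir), "corrupted", class = "dbpkit_io_error")

  # version mismatch is flagged
  dir2 <- tempfile()
  save_model(m, dir2)
  man <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  man$format_version <- "999"
  jsonlite::write_json(man, file.path(dir2, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_model(dir2), "version", class = "dbpkit_version_error")
})

test_that("kernels shrink with a warning when the input is short", {
  fx <- make_cnn_fixture(p = 12)
  expect_warning(
    m <- train_cnn(fx$X, fx$y, cnn_config(epochs = 1, seed = 1)),
    "shrunk"
  )
  expect_equal(nrow(m$history), 1)
  expect_error(train_cnn(fx$X, cbind(fx$y)[, 1] * NA, cnn_config()),
               class = "dbpkit_value_error")
})
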
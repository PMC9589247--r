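#' Configuration for the 1-D convolutional classifier
#'
#' The default architecture is three convolution blocks — kernel sizes
#' 10/5/5 with 256/128/64 filters — each followed by a ReLU activation and
#' max pooling over windows of 2, then a single dropout (rate 0.2), a flatten,
#' a hidden dense layer and a 2-unit softmax output. Training minimizes
#' categorical cross-entropy with one of six first-order optimizers.
#'
#' @param conv_layers List of `c(kernel_size, filter_count)` pairs.
#' @param pool_window Pooling window (fixed stride = window); only 2 is
#'   supported, matching max pooling "over 2 windows".
#' @param dropout Dropout rate in `[0, 1)`, applied once after the last pool.
#' @param dense_units Width of the hidden fully-connected layer.
#' @param optimizer One of `"adam"`, `"sgd"`, `"adagrad"`, `"rmsprop"`,
#'   `"adadelta"`, `"adamax"`.
#' @param optimizer_args Named list overriding the optimizer's default
#'   hyper-parameters (e.g. `list(lr = 5e-4)`).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param train_fraction Fraction of samples used for training in the internal
#'   stratified split; the rest is the validation set.
#' @param pool_every If `TRUE` (default) a pooling layer follows every
#'   convolution block; if `FALSE`, only the last.
#' @param seed Integer seed governing initialization, shuffling, dropout and
#'   the train/validation split.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_layers = list(c(10, 256), c(5, 128), c(5, 64)),
                       pool_window = 2, dropout = 0.2, dense_units = 64,
                       optimizer = c("adam", "sgd", "adagrad", "rmsprop",
                                     "adadelta", "adamax"),
                       optimizer_args = list(), epochs = 50, batch_size = 32,
                       train_fraction = 0.8, pool_every = TRUE, seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(dropout >= 0, dropout < 1,
            train_fraction > 0, train_fraction < 1,
            pool_window == 2, epochs >= 0, batch_size >= 1, dense_units >= 1)
  conv_layers <- map(conv_layers, function(l) {
    stopifnot(length(l) == 2, l[1] >= 1, l[2] >= 1)
    as.integer(l)
  })
  structure(list(conv_layers = conv_layers, pool_window = as.integer(pool_window),
                 dropout = dropout, dense_units = as.integer(dense_units),
                 optimizer = optimizer, optimizer_args = optimizer_args,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, pool_every = pool_every,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  arch <- paste(vapply(x$conv_layers, function(l) {
    sprintf("conv(k=%d,f=%d)", l[1], l[2])
  }, character(1)), collapse = " -> ")
  cat(sprintf("<cnn_config> %s -> dropout(%.2g) -> dense(%d) -> dense(2, softmax)\n",
              arch, x$dropout, x$dense_units))
  cat(sprintf("  optimizer=%s epochs=%d batch=%d train_fraction=%.2g seed=%d\n",
              x$optimizer, x$epochs, x$batch_size, x$train_fraction, x$seed))
  invisible(x)
}

#' Stratified train/validation split
#'
#' Splits sample indices into disjoint train and validation sets preserving
#' the class proportions (to within one sample per class). Deterministic for
#' a given seed.
#'
#' @param y Binary labels (0/1).
#' @param train_fraction Fraction assigned to training.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `val`.
#' @export
split_train_val <- function(y, train_fraction = 0.8, seed = 1) {
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    abort("labels must be 0/1 with both classes present",
          class = "dbpkit_value_error")
  }
  if (min(table(y)) < 2) {
    abort("each class needs at least 2 samples to split",
          class = "dbpkit_value_error")
  }
  set.seed(seed)
  stratified_split_idx(y, train_fraction)
}

# Resolve the per-layer geometry for an input of length D. If the default
# kernels cannot fit, they are shrunk (largest first) until every layer keeps
# at least one output position; a warning records the adjusted kernels.
plan_architecture <- function(D, config) {
  kernels <- vapply(config$conv_layers, `[`, integer(1), 1)
  filters <- vapply(config$conv_layers, `[`, integer(1), 2)
  n_conv <- length(kernels)
  pool_after <- if (isTRUE(config$pool_every)) rep(TRUE, n_conv) else
    c(rep(FALSE, n_conv - 1), TRUE)

  feasible <- function(ks) {
    L <- D
    for (i in seq_len(n_conv)) {
      L <- L - ks[i] + 1L
      if (L < 1L) return(FALSE)
      if (pool_after[i]) {
        L <- L %/% 2L
        if (L < 1L) return(FALSE)
      }
    }
    TRUE
  }
  adjusted <- FALSE
  while (!feasible(kernels)) {
    big <- which.max(kernels)
    if (kernels[big] <= 1L) {
      abort(sprintf("input of %d features is too short for the network", D),
            class = "dbpkit_value_error")
    }
    kernels[big] <- kernels[big] - 1L
    adjusted <- TRUE
  }
  if (adjusted) {
    warn(sprintf("input length %d too short for default kernels; shrunk to [%s]",
                 D, paste(kernels, collapse = ", ")))
  }
  lengths <- integer(0)
  L <- D
  for (i in seq_len(n_conv)) {
    L <- L - kernels[i] + 1L
    if (pool_after[i]) L <- L %/% 2L
    lengths[i] <- L
  }
  chans <- c(1L, filters)
  list(kernels = kernels, filters = filters, pool_after = pool_after,
       out_lengths = lengths, flat_dim = L * filters[n_conv], channels = chans)
}

init_params <- function(plan, dense_units) {
  params <- list()
  n_conv <- length(plan$kernels)
  for (i in seq_len(n_conv)) {
    fan_in <- plan$kernels[i] * plan$channels[i]
    params[[paste0("Wc", i)]] <- matrix(
      rnorm(fan_in * plan$filters[i], sd = sqrt(2 / fan_in)),
      nrow = fan_in, ncol = plan$filters[i]
    )
    params[[paste0("bc", i)]] <- numeric(plan$filters[i])
  }
  params$Wd1 <- matrix(rnorm(plan$flat_dim * dense_units,
                             sd = sqrt(2 / plan$flat_dim)),
                       nrow = plan$flat_dim, ncol = dense_units)
  params$bd1 <- numeric(dense_units)
  params$Wd2 <- matrix(rnorm(dense_units * 2, sd = sqrt(2 / dense_units)),
                       nrow = dense_units, ncol = 2)
  params$bd2 <- numeric(2)
  params
}

cnn_forward <- function(X, params, plan, dropout, training) {
  n <- nrow(X)
  A <- X
  dim(A) <- c(n, ncol(X), 1L)
  caches <- list()
  n_conv <- length(plan$kernels)
  for (i in seq_len(n_conv)) {
    cv <- conv1d_forward(A, params[[paste0("Wc", i)]], params[[paste0("bc", i)]])
    rl <- relu_forward(cv$out)
    A <- rl$out
    pl <- NULL
    if (plan$pool_after[i]) {
      pl <- maxpool2_forward(A)
      A <- pl$out
    }
    caches[[i]] <- list(conv = cv, relu = rl, pool = pl)
  }
  dr <- dropout_forward(A, dropout, training)
  A <- dr$out
  flat <- A
  dim(flat) <- c(n, plan$flat_dim)
  d1 <- dense_forward(flat, params$Wd1, params$bd1)
  h1 <- relu_forward(d1$out)
  d2 <- dense_forward(h1$out, params$Wd2, params$bd2)
  list(logits = d2$out, caches = caches, dropout = dr, d1 = d1, h1 = h1,
       d2 = d2, conv_out_dim = dim(A))
}

cnn_backward <- function(dLogits, fwd, params, plan) {
  grads <- list()
  b2 <- dense_backward(dLogits, fwd$d2, params$Wd2)
  grads$Wd2 <- b2$dW; grads$bd2 <- b2$db
  dH1 <- relu_backward(b2$dA, fwd$h1)
  b1 <- dense_backward(dH1, fwd$d1, params$Wd1)
  grads$Wd1 <- b1$dW; grads$bd1 <- b1$db
  dA <- b1$dA
  dim(dA) <- fwd$conv_out_dim
  dA <- dropout_backward(dA, fwd$dropout)
  for (i in rev(seq_along(plan$kernels))) {
    cc <- fwd$caches[[i]]
    if (!is.null(cc$pool)) dA <- maxpool2_backward(dA, cc$pool)
    dA <- relu_backward(dA, cc$relu)
    cb <- conv1d_backward(dA, cc$conv, params[[paste0("Wc", i)]])
    grads[[paste0("Wc", i)]] <- cb$dW
    grads[[paste0("bc", i)]] <- cb$db
    dA <- cb$dA
  }
  grads
}

#' Train the 1-D convolutional classifier
#'
#' Trains the convolution/pooling/dense stack of [cnn_config()] on a feature
#' matrix, treating each row as a length-D single-channel signal. An internal
#' stratified split (`train_fraction`) provides per-epoch validation metrics;
#' training is deterministic for a given config seed.
#'
#' @param X Numeric feature matrix with column names (the model vocabulary).
#' @param y Binary labels (0/1), one per row.
#' @param config A [cnn_config()].
#' @return An object of class `dbp_cnn` with elements `config`, `vocabulary`,
#'   `params` (trained weights), `plan` (resolved architecture) and `history`
#'   (tibble: epoch, loss, accuracy, val_loss, val_accuracy).
#' @export
train_cnn <- function(X, y, config = cnn_config()) {
  check_Xy(X, y)
  stopifnot(inherits(config, "cnn_config"))
  if (is.null(colnames(X))) {
    abort("X must have column names (the feature vocabulary)",
          class = "dbpkit_value_error")
  }
  set.seed(config$seed)
  plan <- plan_architecture(ncol(X), config)
  params <- init_params(plan, config$dense_units)
  opt <- optimizer_init(config$optimizer, config$optimizer_args)

  split <- stratified_split_idx(y, config$train_fraction)
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- X[split$val, , drop = FALSE];   yva <- y[split$val]
  onehot_tr <- cbind(1 - ytr, ytr)

  history <- list()
  n_tr <- nrow(Xtr)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n_tr)
    batch_losses <- numeric(0)
    for (start in seq(1, n_tr, by = config$batch_size)) {
      idx <- perm[seq.int(start, min(start + config$batch_size - 1L, n_tr))]
      if (length(idx) < 2) next   # degenerate 1-sample tail batch
      fwd <- cnn_forward(Xtr[idx, , drop = FALSE], params, plan,
                         config$dropout, training = TRUE)
      ce <- softmax_xent(fwd$logits, onehot_tr[idx, , drop = FALSE])
      grads <- cnn_backward(ce$dZ, fwd, params, plan)
      stepped <- optimizer_step(opt, params, grads)
      opt <- stepped$opt
      params <- stepped$params
      batch_losses <- c(batch_losses, ce$loss)
    }
    tr_eval <- evaluate_pass(Xtr, ytr, params, plan)
    va_eval <- evaluate_pass(Xva, yva, params, plan)
    history[[epoch]] <- tibble(
      epoch = epoch, loss = tr_eval$loss, accuracy = tr_eval$acc,
      val_loss = va_eval$loss, val_accuracy = va_eval$acc
    )
  }
  structure(list(config = config, vocabulary = colnames(X), params = params,
                 plan = plan, split = split,
                 history = if (length(history)) bind_rows(history) else
                   tibble(epoch = integer(), loss = numeric(),
                          accuracy = numeric(), val_loss = numeric(),
                          val_accuracy = numeric())),
            class = "dbp_cnn")
}

evaluate_pass <- function(X, y, params, plan, batch = 256L) {
  n <- nrow(X)
  losses <- numeric(0); correct <- 0
  onehot <- cbind(1 - y, y)
  for (start in seq(1, n, by = batch)) {
    idx <- seq.int(start, min(start + batch - 1L, n))
    fwd <- cnn_forward(X[idx, , drop = FALSE], params, plan, 0, training = FALSE)
    ce <- softmax_xent(fwd$logits, onehot[idx, , drop = FALSE])
    losses <- c(losses, ce$loss * length(idx))
    correct <- correct + sum((ce$P[, 2] >= 0.5) == (y[idx] == 1))
  }
  list(loss = sum(losses) / n, acc = correct / n)
}

#' @export
print.dbp_cnn <- function(x, ...) {
  cat(sprintf("<dbp_cnn> %d input features, %d conv blocks, optimizer %s\n",
              length(x$vocabulary), length(x$plan$kernels), x$config$optimizer))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  after %d epochs: val_accuracy %.3f, val_loss %.4f\n",
                last$epoch, last$val_accuracy, last$val_loss))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' Class probabilities from a trained model
#'
#' @param model A `dbp_cnn` from [train_cnn()].
#' @param X Feature matrix whose columns must match the model vocabulary (a
#'   permutation is reordered; missing or extra columns are an error).
#' @return A tibble with columns `id` (rownames of `X`, or row number),
#'   `prob_0` and `prob_1`; each row sums to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "dbp_cnn"))
  X <- align_vocabulary(X, model$vocabulary)
  P <- matrix(NA_real_, nrow = nrow(X), ncol = 2)
  for (start in seq(1, nrow(X), by = 256L)) {
    idx <- seq.int(start, min(start + 255L, nrow(X)))
    fwd <- cnn_forward(X[idx, , drop = FALSE], model$params, model$plan,
                       0, training = FALSE)
    P[idx, ] <- softmax_rows(fwd$logits)
  }
  tibble(id = rownames(X) %||% as.character(seq_len(nrow(X))),
         prob_0 = P[, 1], prob_1 = P[, 2])
}

#' Predicted classes at a probability threshold
#'
#' @inheritParams predict_proba
#' @param threshold Decision threshold on the class-1 probability.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_class <- function(model, X, threshold = 0.5) {
  as.integer(predict_proba(model, X)$prob_1 >= threshold)
}

align_vocabulary <- function(X, vocabulary) {
  if (is.null(colnames(X))) {
    abort("feature matrix has no column names", class = "dbpkit_value_error")
  }
  missing <- setdiff(vocabulary, colnames(X))
  extra <- setdiff(colnames(X), vocabulary)
  if (length(missing) || length(extra)) {
    abort(sprintf(
      "feature vocabulary mismatch: %d missing (%s%s), %d unexpected (%s%s)",
      length(missing), paste(head(missing, 3), collapse = ", "),
      if (length(missing) > 3) ", ..." else "",
      length(extra), paste(head(extra, 3), collapse = ", "),
      if (length(extra) > 3) ", ..." else ""
    ), class = "dbpkit_vocabulary_error")
  }
  X[, vocabulary, drop = FALSE]
}

MODEL_BUNDLE_VERSION <- "1"

#' Save / load a trained model bundle
#'
#' The bundle is a directory holding the config as JSON, the vocabulary as
#' TSV, the weights in R's native serialization, and a manifest with format
#' version and content hashes. Loading verifies the version and hashes;
#' predictions after a round-trip are bit-identical.
#'
#' @param model A `dbp_cnn`.
#' @param dir Bundle directory (created if missing).
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "dbp_cnn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  cfg_list <- unclass(cfg)
  jsonlite::write_json(cfg_list, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(model$vocabulary, file.path(dir, "vocabulary.tsv"))
  saveRDS(model[c("params", "plan", "history", "split")],
          file.path(dir, "weights.rds"), version = 3)
  manifest <- list(
    format_version = MODEL_BUNDLE_VERSION,
    package_version = as.character(packageVersion("dbpkit")),
    hashes = as.list(tools::md5sum(file.path(dir, c("config.json",
                                                    "vocabulary.tsv",
                                                    "weights.rds"))))
  )
  names(manifest$hashes) <- c("config.json", "vocabulary.tsv", "weights.rds")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    abort(sprintf("'%s' is not a model bundle (no manifest.json)", dir),
          class = "dbpkit_io_error")
  }
  manifest <- jsonlite::read_json(man_path)
  if (!identical(manifest$format_version, MODEL_BUNDLE_VERSION)) {
    abort(sprintf("model bundle format version '%s' is not supported (need '%s')",
                  manifest$format_version, MODEL_BUNDLE_VERSION),
          class = "dbpkit_version_error")
  }
  for (f in names(manifest$hashes)) {
    actual <- unname(tools::md5sum(file.path(dir, f)))
    if (is.na(actual) || !identical(actual, manifest$hashes[[f]])) {
      abort(sprintf("model bundle file '%s' is missing or corrupted", f),
            class = "dbpkit_io_error")
    }
  }
  cfg_list <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  cfg <- cnn_config(
    conv_layers = map(seq_len(nrow(cfg_list$conv_layers)),
                      function(i) cfg_list$conv_layers[i, ]),
    pool_window = cfg_list$pool_window, dropout = cfg_list$dropout,
    dense_units = cfg_list$dense_units, optimizer = cfg_list$optimizer,
    optimizer_args = as.list(cfg_list$optimizer_args),
    epochs = cfg_list$epochs, batch_size = cfg_list$batch_size,
    train_fraction = cfg_list$train_fraction,
    pool_every = cfg_list$pool_every, seed = cfg_list$seed
  )
  vocab <- readLines(file.path(dir, "vocabulary.tsv"))
  blobs <- readRDS(file.path(dir, "weights.rds"))
  structure(c(list(config = cfg, vocabulary = vocab), blobs),
            class = "dbp_cnn")
}
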
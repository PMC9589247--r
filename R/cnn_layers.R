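# Low-level 1-D CNN machinery: im2col convolution on BLAS, max pooling,
# inverted dropout, dense layers, softmax cross-entropy, and the six
# first-order optimizers. Activations are 3-D arrays [batch, length, channels];
# the im2col buffer collapses (batch, position) into rows and (offset, channel)
# into columns so each convolution is a single matrix product.

conv1d_forward <- function(A, W, b) {
  d <- dim(A)
  n <- d[1]; L <- d[2]; c_in <- d[3]
  kc <- nrow(W)
  k <- kc / c_in
  L_out <- L - k + 1L
  stopifnot(k == round(k), L_out >= 1)
  pos <- as.vector(outer(seq_len(L_out), seq_len(k) - 1L, "+"))  # s fastest
  Acol <- A[, pos, , drop = FALSE]          # [n, L_out*k, c_in]
  dim(Acol) <- c(n * L_out, k * c_in)       # rows (n,s), cols (offset,channel)
  Z <- Acol %*% W
  Z <- sweep(Z, 2L, b, "+")
  out <- Z
  dim(out) <- c(n, L_out, ncol(W))
  list(out = out, Acol = Acol, k = k, c_in = c_in, L = L)
}

conv1d_backward <- function(dOut, cache, W) {
  d <- dim(dOut)
  n <- d[1]; L_out <- d[2]; c_out <- d[3]
  dZ <- dOut
  dim(dZ) <- c(n * L_out, c_out)
  dW <- crossprod(cache$Acol, dZ)
  db <- colSums(dZ)
  dAcol <- dZ %*% t(W)                      # [n*L_out, k*c_in]
  dim(dAcol) <- c(n, L_out, cache$k, cache$c_in)
  dA <- array(0, dim = c(n, cache$L, cache$c_in))
  for (o in seq_len(cache$k)) {
    span <- seq.int(o, length.out = L_out)
    dA[, span, ] <- dA[, span, ] + dAcol[, , o, ]
  }
  list(dA = dA, dW = dW, db = db)
}

relu_forward <- function(Z) {
  mask <- Z > 0
  list(out = Z * mask, mask = mask)
}

relu_backward <- function(dOut, cache) dOut * cache$mask

maxpool2_forward <- function(A) {
  d <- dim(A)
  m <- d[2] %/% 2L
  stopifnot(m >= 1)
  A1 <- A[, seq.int(1L, by = 2L, length.out = m), , drop = FALSE]
  A2 <- A[, seq.int(2L, by = 2L, length.out = m), , drop = FALSE]
  take_first <- A1 >= A2                    # ties keep the earlier position
  list(out = A1 * take_first + A2 * !take_first, take_first = take_first,
       L_in = d[2])
}

maxpool2_backward <- function(dOut, cache) {
  d <- dim(dOut)
  m <- d[2]
  dA <- array(0, dim = c(d[1], cache$L_in, d[3]))
  dA[, seq.int(1L, by = 2L, length.out = m), ] <- dOut * cache$take_first
  dA[, seq.int(2L, by = 2L, length.out = m), ] <- dOut * !cache$take_first
  dA
}

dropout_forward <- function(A, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = A, mask = NULL))
  }
  mask <- array(runif(length(A)) >= rate, dim = dim(A)) / (1 - rate)
  list(out = A * mask, mask = mask)
}

dropout_backward <- function(dOut, cache) {
  if (is.null(cache$mask)) dOut else dOut * cache$mask
}

dense_forward <- function(A, W, b) {
  Z <- A %*% W
  Z <- sweep(Z, 2L, b, "+")
  list(out = Z, A = A)
}

dense_backward <- function(dOut, cache, W) {
  list(dA = dOut %*% t(W), dW = crossprod(cache$A, dOut), db = colSums(dOut))
}

# Numerically stable softmax over rows.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean cross-entropy and its gradient w.r.t. the logits.
softmax_xent <- function(Z, y_onehot) {
  P <- softmax_rows(Z)
  eps <- 1e-12
  loss <- -mean(rowSums(y_onehot * log(P + eps)))
  list(loss = loss, dZ = (P - y_onehot) / nrow(Z), P = P)
}

# ---- optimizers -----------------------------------------------------------

OPTIMIZER_DEFAULTS <- list(
  adam     = list(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
  sgd      = list(lr = 1e-2, momentum = 0.9),
  adagrad  = list(lr = 1e-2, eps = 1e-8),
  rmsprop  = list(lr = 1e-3, rho = 0.9, eps = 1e-8),
  adadelta = list(lr = 1.0, rho = 0.95, eps = 1e-6),
  adamax   = list(lr = 2e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
)

optimizer_init <- function(name, hyper = list()) {
  if (!name %in% names(OPTIMIZER_DEFAULTS)) {
    abort(sprintf("unknown optimizer '%s'", name), class = "dbpkit_value_error")
  }
  hyper <- utils::modifyList(OPTIMIZER_DEFAULTS[[name]], hyper)
  list(name = name, hyper = hyper, t = 0L, state = list())
}

# params and grads are parallel named lists of numeric arrays; the optimizer
# keeps one state slot per parameter tensor.
optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  h <- opt$hyper
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- opt$state[[nm]]
    upd <- switch(opt$name,
      sgd = {
        v <- (st$v %||% 0) * h$momentum - h$lr * g
        st <- list(v = v)
        -v   # params <- params - upd, so upd = -velocity
      },
      adam = {
        m <- (st$m %||% 0) * h$beta1 + (1 - h$beta1) * g
        v <- (st$v %||% 0) * h$beta2 + (1 - h$beta2) * g^2
        st <- list(m = m, v = v)
        mh <- m / (1 - h$beta1^opt$t)
        vh <- v / (1 - h$beta2^opt$t)
        h$lr * mh / (sqrt(vh) + h$eps)
      },
      adagrad = {
        G <- (st$G %||% 0) + g^2
        st <- list(G = G)
        h$lr * g / (sqrt(G) + h$eps)
      },
      rmsprop = {
        v <- (st$v %||% 0) * h$rho + (1 - h$rho) * g^2
        st <- list(v = v)
        h$lr * g / (sqrt(v) + h$eps)
      },
      adadelta = {
        v <- (st$v %||% 0) * h$rho + (1 - h$rho) * g^2
        dx <- g * sqrt((st$u %||% 0) + h$eps) / sqrt(v + h$eps)
        u <- (st$u %||% 0) * h$rho + (1 - h$rho) * dx^2
        st <- list(v = v, u = u)
        h$lr * dx
      },
      adamax = {
        m <- (st$m %||% 0) * h$beta1 + (1 - h$beta1) * g
        u <- pmax((st$u %||% 0) * h$beta2, abs(g))
        st <- list(m = m, u = u)
        h$lr * (m / (1 - h$beta1^opt$t)) / (u + h$eps)
      }
    )
    params[[nm]] <- params[[nm]] - upd
    opt$state[[nm]] <- st
  }
  list(opt = opt, params = params)
}
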
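test_that("adaboost_rank finds a perfectly separating column first", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    y <- rep(c(1L, 0L), each = n / 2)
    X <- cbind(matrix(rnorm(n * 50), n, 50), y + rnorm(n, sd = 0.01))
    colnames(X) <- c(paste0("noise", 1:50), "signal")
    rk <- adaboost_rank(X, y, n_select = 10, n_rounds = 10, seed = seed)
    if (tidy(rk)$feature[1] == "signal") hits <- hits + 1
  }
  expect_equal(hits, 10)
})

test_that("adaboost_rank keeps n_select features and is a permutation", {
  sig <- make_signal_matrix(n = 60, p_noise = 10)
  rk <- adaboost_rank(sig$X, sig$y, n_select = ncol(sig$X), n_rounds = 15)
  expect_setequal(tidy(rk)$index, seq_len(ncol(sig$X)))
  expect_equal(rk$n_selected, ncol(sig$X))
  expect_length(selected_features(rk, 5), 5)
  expect_error(adaboost_rank(sig$X, rep(1, nrow(sig$X)), n_select = 5),
               class = "dbpkit_selection_error")
  expect_error(adaboost_rank(sig$X, sig$y, n_select = 999),
               class = "dbpkit_selection_error")
})

test_that("adaboost_rank is deterministic", {
  sig <- make_signal_matrix(seed = 4)
  r1 <- adaboost_rank(sig$X, sig$y, n_select = 10, n_rounds = 20, seed = 2)
  r2 <- adaboost_rank(sig$X, sig$y, n_select = 10, n_rounds = 20, seed = 2)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("score_features: per-method behavior on designed columns", {
  set.seed(21)
  n <- 120
  y <- rep(c(1L, 0L), each = n / 2)
  X <- cbind(
    same = rep(1.5, n),                 # constant
    flat = rnorm(n),                    # noise
    exact = as.numeric(y),              # label copy
    shifted = y * 2 + rnorm(n, sd = 0.3)
  )
  sc <- score_features(X, y)

  # constant column scores 0 under every method, no exception raised
  const_row <- sc[sc$feature == "same", c("anova_f", "mutual_info", "lasso", "mrmr")]
  expect_true(all(unlist(const_row) == 0))

  # a label-identical binary column maximizes mutual information;
  # brute-force MI of the 2x2 table is log(2) * ... computed directly:
  p1 <- mean(y)
  mi_exact <- -(p1 * log(p1) + (1 - p1) * log(1 - p1))
  expect_equal(sc$mutual_info[sc$feature == "exact"], mi_exact, tolerance = 1e-9)
  expect_equal(which.max(sc$mutual_info), which(sc$feature == "exact"))

  # anova F on an identical-across-classes column is 0
  expect_equal(sc$anova_f[sc$feature == "same"], 0)
  expect_gt(sc$anova_f[sc$feature == "shifted"], sc$anova_f[sc$feature == "flat"])

  # lasso on pure noise stays near zero relative to signal
  expect_gt(sc$lasso[sc$feature == "exact"],
            10 * max(sc$lasso[sc$feature == "flat"], 1e-12))
})

test_that("lasso scores vanish on pure-noise input", {
  set.seed(33)
  n <- 80
  y <- rep(c(1L, 0L), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  sc <- score_features(X, y, methods = "lasso")
  expect_true(all(sc$lasso < 0.3))
})

test_that("pagerank_fuse preserves unanimous rankings and sums to 1", {
  ords <- list(a = c(3L, 1L, 4L, 2L, 5L), b = c(3L, 1L, 4L, 2L, 5L))
  fused <- pagerank_fuse(ords)
  expect_equal(tidy(fused)$index, c(3L, 1L, 4L, 2L, 5L))
  expect_equal(sum(tidy(fused)$fused_mass), 1, tolerance = 1e-9)

  # single method: fused order equals that method's order
  one <- pagerank_fuse(list(m = c(2L, 3L, 1L)))
  expect_equal(tidy(one)$index, c(2L, 3L, 1L))
})

test_that("pagerank_fuse on opposed rankings keeps the middle feature central", {
  # methods rank 3 features in exactly reversed orders
  fused <- pagerank_fuse(list(up = 1:3, down = 3:1))
  r <- tidy(fused)
  mass <- r$fused_mass[order(r$index)]
  # outer features are symmetric; middle cannot fall below both extremes
  expect_equal(mass[1], mass[3], tolerance = 1e-8)
  expect_false(which.min(mass) == 2 && mass[2] < mass[1] - 1e-12)
})

test_that("pagerank_fuse agrees with igraph on the explicit rank graph", {
  skip_if_not_installed("igraph")
  set.seed(8)
  p <- 12
  ords <- lapply(1:4, function(i) sample.int(p))
  fused <- pagerank_fuse(ords, damping = 0.85, tol = 1e-12, max_iter = 500)
  # explicit multigraph: edge a -> b for every method ranking b above a
  edges <- do.call(rbind, lapply(ords, function(o) {
    rk <- integer(p); rk[o] <- seq_len(p)  # rk[f] = position of f
    do.call(rbind, lapply(seq_len(p), function(a) {
      better <- which(rk < rk[a])
      if (length(better)) cbind(a, better) else NULL
    }))
  }))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  pr <- igraph::page_rank(g, damping = 0.85)$vector
  got <- tidy(fused)
  expect_equal(got$fused_mass[order(got$index)], unname(pr), tolerance = 1e-6)
})

test_that("pagerank mass is a fixed point of the update", {
  set.seed(14)
  p <- 30
  ords <- lapply(1:3, function(i) sample.int(p))
  f1 <- pagerank_fuse(ords, tol = 1e-12, max_iter = 1000)
  f2 <- pagerank_fuse(ords, tol = 1e-12, max_iter = 1001)
  expect_equal(tidy(f1)$fused_mass, tidy(f2)$fused_mass, tolerance = 1e-9)
  expect_error(pagerank_fuse(list()), class = "dbpkit_value_error")
})

test_that("forward_addition recovers signal prefixes", {
  recovered <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 150
    y <- rep(c(1L, 0L), each = n / 2)
    Xsig <- sapply(1:5, function(i) y * 1.5 + rnorm(n, sd = 0.5))
    X <- cbind(Xsig, matrix(rnorm(n * 200), n, 200))
    colnames(X) <- c(paste0("sig", 1:5), paste0("noise", 1:200))
    ranking <- colnames(X)  # signal ranked first
    fw <- forward_addition(X, y, ranking, block_size = 5, patience = 2,
                           seed = seed)
    if (all(paste0("sig", 1:5) %in% fw$features)) recovered <- recovered + 1
  }
  expect_gte(recovered, 6)  # majority across seeds
})

test_that("forward_addition limit cases", {
  sig <- make_signal_matrix(n = 60, p_noise = 6, seed = 5)
  ranking <- colnames(sig$X)
  exhaustive <- forward_addition(sig$X, sig$y, ranking, block_size = 2,
                                 patience = Inf, seed = 1)
  expect_equal(nrow(exhaustive$path), ceiling(ncol(sig$X) / 2))

  one <- forward_addition(sig$X[, 1, drop = FALSE], sig$y, "signal", seed = 1)
  expect_equal(one$features, "signal")
})

test_that("duplicated signal columns never sink below noise in the fusion", {
  set.seed(6)
  n <- 100
  y <- rep(c(1L, 0L), each = n / 2)
  base <- y * 2 + rnorm(n, sd = 0.4)
  X <- cbind(sig1 = base, sig2 = base + rnorm(n, sd = 0.01),
             sig3 = base + rnorm(n, sd = 0.01),
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("noise", 1:20))))
  sc <- score_features(X, y, methods = c("anova_f", "mutual_info", "mrmr"))
  fused <- tidy(pagerank_fuse(sc))
  sig_ranks <- fused$rank[grepl("^sig", fused$feature)]
  noise_ranks <- fused$rank[grepl("^noise", fused$feature)]
  expect_lt(min(sig_ranks), min(noise_ranks))
})
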
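#' Ranked feature sets
#'
#' Container returned by the rankers: a tibble of features in rank order with
#' per-method scores (and PageRank mass when produced by [pagerank_fuse()]),
#' plus how many features are considered selected.
#'
#' @param ranking Tibble with at least `rank`, `index`, `feature` columns.
#' @param n_selected Number of top-ranked features regarded as selected.
#' @param method Short label for the ranking strategy.
#' @return An object of class `ranked_features`.
#' @keywords internal
new_ranked_features <- function(ranking, n_selected, method) {
  stopifnot(all(c("rank", "index", "feature") %in% names(ranking)))
  idx <- ranking$index
  if (anyDuplicated(idx) || !setequal(idx, seq_along(idx))) {
    abort("ranking indices must be a permutation of the columns",
          class = "dbpkit_value_error")
  }
  structure(list(ranking = as_tibble(ranking),
                 n_selected = as.integer(n_selected),
                 method = method),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> %s: %d features, top %d selected\n",
              x$method, nrow(x$ranking), x$n_selected))
  print(head(x$ranking, 5))
  invisible(x)
}

#' Selected feature names of a ranking
#'
#' @param ranked A `ranked_features` object.
#' @param n Number of top features; defaults to the stored `n_selected`.
#' @return Character vector of feature names in rank order.
#' @export
selected_features <- function(ranked, n = NULL) {
  stopifnot(inherits(ranked, "ranked_features"))
  n <- n %||% ranked$n_selected
  head(ranked$ranking$feature, n)
}

#' Rank features by AdaBoost stump importance
#'
#' Fits a discrete AdaBoost ensemble of depth-1 decision stumps, each chosen
#' by exhaustive search over every column and threshold under the current
#' sample weights, and scores each column by the cumulative ensemble weight
#' (alpha) of the stumps that split on it. The top `n_select` columns are the
#' retained subset (default 441, the compact monoDiKGap subset size). Columns
#' never chosen by a stump are ordered by their first-round weighted stump
#' error. Deterministic: stump search breaks ties by column index, and
#' boosting itself has no random component.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Binary labels (0/1), one per row.
#' @param n_select How many top features to keep (<= ncol(X)).
#' @param n_rounds Number of boosting rounds.
#' @param seed Unused randomness guard, recorded in the output for manifest
#'   parity with the stochastic rankers.
#' @return A `ranked_features` object with per-column `importance`.
#' @export
adaboost_rank <- function(X, y, n_select = 441, n_rounds = 100, seed = 1) {
  check_Xy(X, y)
  p <- ncol(X)
  n <- nrow(X)
  if (n_select > p) {
    abort(sprintf("n_select (%d) exceeds number of columns (%d)", n_select, p),
          class = "dbpkit_selection_error")
  }
  ysign <- ifelse(y == 1, 1, -1)
  ord <- apply(X, 2, order)            # per-column sort orders, computed once
  w <- rep(1 / n, n)
  importance <- numeric(p)
  round1_err <- rep(NA_real_, p)

  for (m in seq_len(n_rounds)) {
    best <- list(err = Inf, j = NA, thr = NA, pol = 1)
    tot_pos <- sum(w[ysign == 1])
    tot_neg <- 1 - tot_pos
    for (j in seq_len(p)) {
      o <- ord[, j]
      xs <- X[o, j]
      distinct <- which(xs[-n] < xs[-1])  # cut between consecutive distinct values
      if (length(distinct) > 0) {
        wpos <- w[o] * (ysign[o] == 1)
        cpos <- cumsum(wpos)[distinct]
        cneg <- cumsum(w[o])[distinct] - cpos
        # stump "+1 when x > thr": err = P(y=+1, x<=thr) + P(y=-1, x>thr)
        err_plus <- cpos + (tot_neg - cneg)
        err_minus <- 1 - err_plus
        e2 <- pmin(err_plus, err_minus)
        t_best <- which.min(e2)
        err_j <- e2[t_best]
        pol_j <- if (err_plus[t_best] <= err_minus[t_best]) 1 else -1
        thr_j <- (xs[distinct[t_best]] + xs[distinct[t_best] + 1L]) / 2
      } else {                             # constant column: constant stump
        err_j <- min(tot_pos, tot_neg)
        pol_j <- if (tot_pos <= tot_neg) 1 else -1
        thr_j <- Inf
      }
      if (m == 1L) round1_err[j] <- err_j
      if (err_j < best$err - 1e-15) {
        best <- list(err = err_j, j = j, thr = thr_j, pol = pol_j)
      }
    }
    eps <- max(best$err, 1e-12)
    if (eps >= 0.5) break              # no weak learner better than chance
    alpha <- 0.5 * log((1 - eps) / eps)
    importance[best$j] <- importance[best$j] + alpha
    pred <- ifelse(X[, best$j] > best$thr, best$pol, -best$pol)
    w <- w * exp(-alpha * ysign * pred)
    w <- w / sum(w)
    if (eps < 1e-10) break             # perfect stump: weights degenerate
  }

  ord_rank <- order(-importance, round1_err, seq_len(p))
  ranking <- tibble(
    rank = seq_len(p),
    index = ord_rank,
    feature = colnames(X)[ord_rank],
    importance = importance[ord_rank],
    stump_error = round1_err[ord_rank]
  )
  new_ranked_features(ranking, n_select, "adaboost")
}

#' Per-column relevance scores under multiple criteria
#'
#' Computes one relevance score per feature column for each requested method:
#' \describe{
#'   \item{`anova_f`}{Two-group ANOVA F statistic.}
#'   \item{`mutual_info`}{Mutual information (nats) between the label and the
#'     column discretized into up to five equal-frequency bins.}
#'   \item{`lasso`}{Maximum absolute standardized coefficient of the column
#'     along a lasso (L1 logistic) regularization path.}
#'   \item{`mrmr`}{Greedy minimum-redundancy maximum-relevance ordering
#'     (F-statistic relevance minus mean absolute Pearson correlation with the
#'     already-picked set), reported as a descending rank score. The greedy
#'     stage is capped at `mrmr_greedy_max` picks; remaining columns are
#'     ordered by their final criterion value.}
#' }
#' Constant columns score 0 under every method. Higher is always better.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param methods Subset of `c("anova_f", "mutual_info", "lasso", "mrmr")`.
#' @param mrmr_greedy_max Cap on exact greedy mRMR iterations.
#' @return A tibble with columns `index`, `feature` and one score column per
#'   method.
#' @export
score_features <- function(X, y,
                           methods = c("anova_f", "mutual_info", "lasso", "mrmr"),
                           mrmr_greedy_max = 300) {
  check_Xy(X, y)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) == 0) {
    abort("at least one scoring method is required", class = "dbpkit_value_error")
  }
  out <- tibble(index = seq_len(ncol(X)), feature = colnames(X))
  for (m in methods) {
    out[[m]] <- unname(switch(m,
      anova_f = score_anova_f(X, y),
      mutual_info = score_mutual_info(X, y),
      lasso = score_lasso(X, y),
      mrmr = score_mrmr(X, y, greedy_max = mrmr_greedy_max)
    ))
  }
  out
}

score_anova_f <- function(X, y) {
  n <- nrow(X)
  n1 <- sum(y == 1); n0 <- n - n1
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  mall <- colMeans(X)
  ssb <- n1 * (m1 - mall)^2 + n0 * (m0 - mall)^2
  sst <- colSums(X^2) - n * mall^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f) & ssb <= 1e-300] <- 0    # constant column -> 0
  f[is.nan(f)] <- 0
  f
}

score_mutual_info <- function(X, y, n_bins = 5) {
  apply(X, 2, function(x) {
    ux <- unique(x)
    if (length(ux) < 2) return(0)
    if (length(ux) <= n_bins) {
      b <- factor(x)                   # low-cardinality: exact categories
    } else {
      br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
      if (length(br) < 3) return(0)
      b <- cut(x, breaks = br, include.lowest = TRUE)
    }
    tab <- table(b, y)
    pj <- tab / sum(tab)
    px <- rowSums(pj); py <- colSums(pj)
    nz <- pj > 0
    sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
  })
}

score_lasso <- function(X, y) {
  p <- ncol(X)
  const <- matrixStats_colsd(X) < .Machine$double.eps
  sc <- numeric(p)
  keep <- which(!const)
  if (length(keep) >= 2) {
    fit <- glmnet::glmnet(X[, keep, drop = FALSE], factor(y),
                          family = "binomial", standardize = TRUE,
                          nlambda = 60)
    # deterministic penalty choice: BIC along the path (no CV randomness)
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    bic <- dev + fit$df * log(nrow(X))
    sc[keep] <- abs(as.matrix(fit$beta)[, which.min(bic)])
  }
  sc
}

score_mrmr <- function(X, y, greedy_max = 300) {
  p <- ncol(X)
  rel <- score_anova_f(X, y)
  rel_s <- rel / max(rel[is.finite(rel)], 1e-300)
  rel_s[!is.finite(rel_s)] <- 1
  sds <- matrixStats_colsd(X)
  const <- sds < .Machine$double.eps
  Xs <- scale(X)
  Xs[, const] <- 0
  n <- nrow(X)

  n_greedy <- min(p, greedy_max)
  selected <- integer(0)
  red_sum <- numeric(p)                 # running sum of |cor| with selected
  avail <- !const
  for (step in seq_len(n_greedy)) {
    crit <- rel_s - if (step == 1) 0 else red_sum / length(selected)
    crit[!avail] <- -Inf
    if (all(!is.finite(crit))) break
    j <- which.max(crit)
    selected <- c(selected, j)
    avail[j] <- FALSE
    r <- abs(crossprod(Xs, Xs[, j]) / (n - 1))
    r[!is.finite(r)] <- 0
    red_sum <- red_sum + as.vector(r)
  }
  # remaining columns ordered by the final criterion value
  rest <- which(avail)
  if (length(rest)) {
    crit_rest <- rel_s[rest] -
      if (length(selected)) red_sum[rest] / length(selected) else 0
    rest <- rest[order(-crit_rest, rest)]
  }
  full_order <- c(selected, rest)         # all non-constant columns
  sc <- numeric(p)
  sc[full_order] <- rev(seq_along(full_order))  # descending rank score
  sc                                            # constant columns stay 0
}

matrixStats_colsd <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  sqrt(pmax(colSums(X^2) - n * colMeans(X)^2, 0) / (n - 1))
}

#' Fuse per-method rankings with PageRank
#'
#' Builds (implicitly) a directed graph over features with one edge a -> b for
#' every method that ranks b strictly above a — mass flows toward better
#' features — and computes the stationary PageRank mass by power iteration
#' (damping `damping`, dangling mass redistributed uniformly). The fused
#' order is descending mass, ties broken by mean rank across methods, then
#' column index. The graph is never materialized: each method's contribution
#' is a suffix sum over its ranking, so fusion is O(methods x p) per
#' iteration.
#'
#' @param rankings Either the score tibble from [score_features()] (every
#'   numeric column except `index` is treated as a method, higher = better) or
#'   a named list of integer orderings (best-first column indices over the
#'   same column set).
#' @param damping PageRank damping factor.
#' @param n_selected How many top features the result marks as selected
#'   (default: all).
#' @param tol,max_iter Power-iteration convergence controls.
#' @param feature_names Optional feature names when `rankings` is a list.
#' @return A `ranked_features` object whose `fused_mass` column sums to 1.
#' @export
pagerank_fuse <- function(rankings, damping = 0.85, n_selected = NULL,
                          tol = 1e-9, max_iter = 200, feature_names = NULL) {
  parsed <- parse_rankings(rankings, feature_names)
  ranks <- parsed$ranks        # p x m matrix of ranks (1 = best)
  p <- nrow(ranks)
  m <- ncol(ranks)
  if (m == 0) {
    abort("at least one ranking is required", class = "dbpkit_value_error")
  }

  # out-degree of feature a = total number of features ranked above it
  outdeg <- rowSums(ranks - 1)
  ord_m <- apply(ranks, 2, order)      # per-method: indices best-first

  v <- rep(1 / p, p)
  for (it in seq_len(max_iter)) {
    u <- ifelse(outdeg > 0, v / outdeg, 0)
    dangling <- sum(v[outdeg == 0])
    contrib <- numeric(p)
    for (j in seq_len(m)) {
      o <- ord_m[, j]                  # best ... worst
      # node at position r receives u from every node at positions > r
      suff <- rev(cumsum(rev(u[o]))) - u[o]
      contrib[o] <- contrib[o] + suff
    }
    v_new <- (1 - damping) / p + damping * (contrib + dangling / p)
    delta <- sum(abs(v_new - v))
    v <- v_new
    if (delta < tol) break
  }
  v <- v / sum(v)

  mean_rank <- rowMeans(ranks)
  ord <- order(-v, mean_rank, seq_len(p))
  ranking <- tibble(
    rank = seq_len(p),
    index = ord,
    feature = parsed$features[ord],
    fused_mass = v[ord],
    mean_rank = mean_rank[ord]
  )
  for (nm in colnames(parsed$scores)) {
    ranking[[nm]] <- parsed$scores[ord, nm]
  }
  new_ranked_features(ranking, n_selected %||% p, "pagerank")
}

parse_rankings <- function(rankings, feature_names = NULL) {
  if (is.data.frame(rankings)) {
    stopifnot(all(c("index", "feature") %in% names(rankings)))
    rankings <- rankings[order(rankings$index), , drop = FALSE]
    score_cols <- setdiff(names(rankings)[vapply(rankings, is.numeric, logical(1))],
                          c("index", "rank"))
    if (length(score_cols) == 0) {
      abort("score tibble has no method columns", class = "dbpkit_value_error")
    }
    scores <- as.matrix(rankings[, score_cols, drop = FALSE])
    p <- nrow(scores)
    ranks <- apply(scores, 2, function(s) {
      # higher score = better = smaller rank; ties broken by column index
      rk <- integer(p)
      rk[order(-s, seq_len(p))] <- seq_len(p)
      rk
    })
    list(ranks = ranks, scores = scores, features = rankings$feature)
  } else if (is.list(rankings)) {
    if (length(rankings) == 0) {
      abort("empty rankings list", class = "dbpkit_value_error")
    }
    p <- length(rankings[[1]])
    ranks <- vapply(rankings, function(o) {
      if (!setequal(o, seq_len(p))) {
        abort("each ranking must be a permutation of the same column set",
              class = "dbpkit_value_error")
      }
      rk <- integer(p)
      rk[o] <- seq_len(p)
      rk
    }, integer(p))
    feats <- feature_names %||% paste0("f", seq_len(p))
    list(ranks = ranks, scores = matrix(numeric(0), nrow = p, ncol = 0),
         features = feats)
  } else {
    abort("rankings must be a score tibble or a list of orderings",
          class = "dbpkit_value_error")
  }
}

#' Choose a prefix of a ranking by forward addition
#'
#' Walks the ranked feature list in blocks, evaluating each growing prefix
#' with a fast internal classifier on a stratified train/validation split, and
#' keeps the prefix with the best validation accuracy. Stops after `patience`
#' consecutive non-improving blocks. Ties prefer the smaller prefix.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param ranking A `ranked_features` object (or character vector of feature
#'   names in rank order).
#' @param evaluator Function `(X_subset, y) -> accuracy in [0,1]`; the default
#'   fits a ridge-regularized logistic model on a stratified 70/30 split.
#' @param block_size Number of features added per step.
#' @param patience Non-improving blocks tolerated before stopping; use `Inf`
#'   to evaluate every prefix.
#' @param max_features Cap on the largest prefix examined.
#' @param seed Seed for the internal split (and any evaluator randomness).
#' @return A list with `features` (selected names), `n_selected`, and `path`
#'   (tibble of prefix size vs validation accuracy).
#' @export
forward_addition <- function(X, y, ranking, evaluator = NULL, block_size = 10,
                             patience = 3, max_features = ncol(X), seed = 1) {
  check_Xy(X, y)
  feats <- if (inherits(ranking, "ranked_features")) {
    ranking$ranking$feature
  } else {
    ranking
  }
  stopifnot(all(feats %in% colnames(X)))
  evaluator <- evaluator %||% make_linear_evaluator(seed)
  limit <- min(length(feats), max_features)
  sizes <- unique(pmin(seq(block_size, limit + block_size - 1, by = block_size), limit))
  if (length(sizes) == 0) sizes <- limit

  best_acc <- -Inf
  best_n <- sizes[1]
  stall <- 0
  path <- list()
  for (s in sizes) {
    acc <- evaluator(X[, feats[seq_len(s)], drop = FALSE], y)
    path[[length(path) + 1]] <- tibble(n_features = s, accuracy = acc)
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best_n <- s
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
  }
  list(features = feats[seq_len(best_n)], n_selected = best_n,
       accuracy = best_acc, path = bind_rows(path))
}

make_linear_evaluator <- function(seed = 1) {
  force(seed)
  function(Xs, y) {
    set.seed(seed)
    split <- stratified_split_idx(y, 0.7)
    Xtr <- Xs[split$train, , drop = FALSE]
    Xva <- Xs[split$val, , drop = FALSE]
    if (ncol(Xs) < 2) {
      Xtr <- cbind(Xtr, 0); Xva <- cbind(Xva, 0)
    }
    fit <- glmnet::glmnet(Xtr, factor(y[split$train]), family = "binomial",
                          alpha = 0, lambda = 0.01, standardize = TRUE)
    pred <- predict(fit, Xva, type = "class")
    mean(pred == as.character(y[split$val]))
  }
}

stratified_split_idx <- function(y, fraction) {
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  # class allocations sum to round(n * fraction); proportions held to +/- 1
  n_train <- round(length(y) * fraction)
  n1 <- max(1L, round(length(idx1) * fraction))
  n0 <- max(1L, n_train - n1)
  if (n1 >= length(idx1)) n1 <- length(idx1) - 1L
  if (n0 >= length(idx0)) n0 <- length(idx0) - 1L
  if (n1 < 1 || n0 < 1) {
    abort("need at least 2 samples per class to split",
          class = "dbpkit_value_error")
  }
  tr <- c(sample(idx1, n1), sample(idx0, n0))
  list(train = sort(tr), val = sort(setdiff(seq_along(y), tr)))
}

#' Ensemble feature selection (score, fuse, forward-add)
#'
#' Convenience wrapper chaining [score_features()], [pagerank_fuse()] and
#' [forward_addition()] — the MRMD-style redundancy-removal stage.
#'
#' @inheritParams score_features
#' @inheritParams pagerank_fuse
#' @inheritParams forward_addition
#' @return A list with the fused `ranked_features` (its `n_selected` set to
#'   the forward-addition choice) and the `forward` result.
#' @export
ensemble_select <- function(X, y,
                            methods = c("anova_f", "mutual_info", "lasso", "mrmr"),
                            damping = 0.85, block_size = 10, patience = 3,
                            max_features = ncol(X), seed = 1) {
  scores <- score_features(X, y, methods = methods)
  fused <- pagerank_fuse(scores, damping = damping)
  fwd <- forward_addition(X, y, fused, block_size = block_size,
                          patience = patience, max_features = max_features,
                          seed = seed)
  fused$n_selected <- fwd$n_selected
  list(ranking = fused, forward = fwd, features = fwd$features)
}

check_Xy <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X)) {
    abort("X must be a numeric matrix", class = "dbpkit_value_error")
  }
  if (length(y) != nrow(X)) {
    abort("y must have one label per row of X", class = "dbpkit_value_error")
  }
  if (!all(y %in% c(0, 1))) {
    abort("labels must be 0/1", class = "dbpkit_value_error")
  }
  if (length(unique(y)) < 2) {
    abort("both classes must be present", class = "dbpkit_selection_error")
  }
  if (anyNA(X)) {
    abort("X contains missing values", class = "dbpkit_value_error")
  }
  invisible(TRUE)
}
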
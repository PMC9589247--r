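test_that("confusion counts follow the positive-class convention", {
  cts <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cts)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))

  perfect <- confusion(c(1, 0, 1), c(0.9, 0.1, 0.8))
  expect_equal(perfect$FP + perfect$FN, 0)

  allpos <- confusion(c(1, 1, 0, 0), rep(1, 4))
  expect_equal(allpos$FN, 0)
  expect_equal(allpos$TN, 0)

  expect_error(confusion(c(1, 0), 1), class = "dbpkit_value_error")
})

test_that("metrics reproduce hand-computed values and limit cases", {
  cts <- structure(list(TP = 40L, FP = 5L, TN = 45L, FN = 10L),
                   class = "confusion_counts")
  m <- metrics(cts)
  expect_equal(m$sn, 0.80)
  expect_equal(m$sp, 0.90)
  expect_equal(m$acc, 0.85)
  expect_equal(m$mcc, (45 * 40 - 5 * 10) / sqrt(50 * 45 * 50 * 55),
               tolerance = 1e-12)
  expect_equal(round(m$mcc, 4), 0.7035)

  perf <- metrics(structure(list(TP = 3L, FP = 0L, TN = 4L, FN = 0L),
                            class = "confusion_counts"))
  expect_equal(perf$acc, 1)
  expect_equal(perf$mcc, 1)

  inv <- metrics(structure(list(TP = 0L, FP = 4L, TN = 0L, FN = 3L),
                           class = "confusion_counts"))
  expect_equal(inv$mcc, -1)

  degen <- metrics(structure(list(TP = 0L, FP = 0L, TN = 5L, FN = 0L),
                             class = "confusion_counts"))
  expect_equal(degen$mcc, 0)
  expect_true(degen$mcc_undefined)
})

test_that("metrics agree with a pair-counting oracle on random tables", {
  set.seed(19)
  for (i in 1:200) {
    counts <- as.list(sample(0:30, 4, replace = TRUE))
    names(counts) <- c("TP", "FP", "TN", "FN")
    if (Reduce(`+`, counts) == 0) next
    m <- metrics(structure(counts, class = "confusion_counts"))
    with(counts, {
      expect_equal(m$acc, (TP + TN) / (TP + TN + FP + FN))
      denom <- sqrt(prod(c(TP + FN, TP + FP, TN + FP, TN + FN)))
      if (denom > 0) {
        expect_equal(m$mcc, (TN * TP - FP * FN) / denom, tolerance = 1e-10)
      } else {
        expect_equal(m$mcc, 0)
      }
    })
  }
})

test_that("accuracy is swap-invariant, MCC antisymmetric under inversion", {
  set.seed(23)
  for (i in 1:50) {
    v <- as.integer(sample(1:20, 4, replace = TRUE))
    a <- metrics(structure(list(TP = v[1], FP = v[2], TN = v[3], FN = v[4]),
                           class = "confusion_counts"))
    b <- metrics(structure(list(TP = v[3], FP = v[4], TN = v[1], FN = v[2]),
                           class = "confusion_counts"))
    inv <- metrics(structure(list(TP = v[4], FP = v[3], TN = v[2], FN = v[1]),
                             class = "confusion_counts"))
    expect_equal(a$acc, b$acc)
    expect_equal(a$mcc, -inv$mcc, tolerance = 1e-12)
  }
})

test_that("AUC matches hand-derived cases and tie conventions", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(auc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(auc(c(1, 1, 0, 0), rep(0.3, 4)), 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), class = "dbpkit_single_class_error")
})

test_that("AUC equals the Mann-Whitney concordance statistic", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)   # coarse scores force ties
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(y, s), mean(pairs), tolerance = 1e-12)
  }
})

test_that("curve metrics agree with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(37)
  y <- rbinom(60, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- runif(60)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    y, s, levels = c(0, 1), direction = "<"
  ))))
  expect_equal(auc(y, s), ref, tolerance = 1e-9)
})

test_that("evaluate_scores assembles a complete report", {
  set.seed(41)
  y <- rep(c(1, 0), each = 25)
  s <- pmin(pmax(y * 0.6 + runif(50) * 0.4, 0), 1)
  rep <- evaluate_scores(y, s)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$TP + rep$FP + rep$TN + rep$FN, 50)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  long <- tidy(rep)
  expect_setequal(long$metric, c("acc", "sn", "sp", "mcc", "auc", "auprc"))

  f <- tempfile(fileext = ".json")
  write_metrics(rep, f, y_true = y, y_score = s)
  back <- jsonlite::read_json(f)
  expect_equal(back$acc, rep$acc)
  expect_true(file.exists(sub("\\.json$", "_roc.csv", f)))
})
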
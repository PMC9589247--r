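#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ranked feature set
#'
#' @param x A `ranked_features` object.
#' @param ... Unused.
#' @return The ranking tibble (one row per feature, best first) for `tidy()`;
#'   a one-row summary for `glance()`.
#' @export
tidy.ranked_features <- function(x, ...) x$ranking

#' @rdname tidy.ranked_features
#' @export
glance.ranked_features <- function(x, ...) {
  tibble(method = x$method, n_features = nrow(x$ranking),
         n_selected = x$n_selected)
}

#' Tidy a trained CNN
#'
#' @param x A `dbp_cnn` object.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch training history; `glance()`: a one-row
#'   summary with final losses/accuracies and architecture facts.
#' @export
tidy.dbp_cnn <- function(x, ...) x$history

#' @rdname tidy.dbp_cnn
#' @export
glance.dbp_cnn <- function(x, ...) {
  n_params <- sum(vapply(x$params, length, integer(1)))
  base <- tibble(
    n_features = length(x$vocabulary),
    n_conv_layers = length(x$plan$kernels),
    n_parameters = n_params,
    optimizer = x$config$optimizer,
    epochs_trained = nrow(x$history)
  )
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    base$loss <- last$loss
    base$accuracy <- last$accuracy
    base$val_loss <- last$val_loss
    base$val_accuracy <- last$val_accuracy
  }
  base
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble (`metric`, `value`); `glance()`: the
#'   one-row wide report.
#' @export
tidy.metrics_report <- function(x, ...) {
  vals <- c(acc = x$acc, sn = x$sn, sp = x$sp, mcc = x$mcc,
            auc = x$auc, auprc = x$auprc)
  tibble(metric = names(vals), value = unname(vals))
}

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) as_tibble(unclass(x))

#' Plot training history
#'
#' @param object A `dbp_cnn`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy per epoch for the training and
#'   validation splits.
#' @export
autoplot.dbp_cnn <- function(object, ...) {
  h <- object$history
  if (!nrow(h)) {
    abort("model has no training history", class = "dbpkit_value_error")
  }
  long <- tidyr::pivot_longer(h, -"epoch",
                              names_to = "series", values_to = "value")
  long$split <- ifelse(grepl("^val_", long$series), "validation", "training")
  long$measure <- sub("^val_", "", long$series)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fused ranking's PageRank mass
#'
#' @param object A `ranked_features`.
#' @param top Show only the `top` best-ranked features.
#' @param ... Unused.
#' @return A ggplot of score/mass against rank with the selection cutoff.
#' @export
autoplot.ranked_features <- function(object, top = 100, ...) {
  r <- head(object$ranking, top)
  ycol <- if ("fused_mass" %in% names(r)) "fused_mass" else "importance"
  ggplot2::ggplot(r, ggplot2::aes(x = .data$rank, y = .data[[ycol]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$n_selected + 0.5,
                        linetype = "dashed") +
    ggplot2::labs(x = "rank", y = ycol) +
    ggplot2::theme_minimal()
}

#' ROC and precision-recall plots
#'
#' @param y_true Binary labels.
#' @param y_score Class-1 scores.
#' @return A ggplot.
#' @export
plot_roc <- function(y_true, y_score) {
  pts <- roc_points(y_true, y_score)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", auc(y_true, y_score))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @export
plot_pr <- function(y_true, y_score) {
  pts <- pr_points(y_true, y_score)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(subtitle = sprintf("AUPRC = %.3f", auprc(y_true, y_score))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
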
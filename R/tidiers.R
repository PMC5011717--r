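#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted classifier branch
#'
#' One row per nonzero coefficient (plus the intercept), at the branch's
#' selected regularization strength.
#'
#' @param x a `wb_branch`.
#' @param ... unused.
#' @return A tibble: `term`, `estimate`.
#' @export
tidy.wb_branch <- function(x, ...) {
  coefs <- as.matrix(predict(x$model, s = x$lambda, type = "coefficients"))
  keep <- coefs[, 1] != 0
  tibble::tibble(term = rownames(coefs)[keep], estimate = coefs[keep, 1])
}

#' @rdname tidy.wb_branch
#' @export
glance.wb_branch <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda, cv_auc = x$cv_auc,
                 n_features = length(x$features),
                 n_nonzero = length(x$nonzero),
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy an evaluation result
#'
#' @param x a `wb_evaluation`.
#' @param ... unused.
#' @return The per-round AUC tibble (`repeat_`, `held_out`, `fold`,
#'   `config`, `auc`, test-set sizes).
#' @export
tidy.wb_evaluation <- function(x, ...) x$rounds

#' @rdname tidy.wb_evaluation
#' @export
glance.wb_evaluation <- function(x, ...) {
  tidyr::pivot_wider(x$mean_auc[, c("config", "mean_auc")],
                     names_from = "config", values_from = "mean_auc",
                     names_prefix = "auc_")
}

#' Tidy a common-genes result
#'
#' @param x a `wb_common_genes`.
#' @param ... unused.
#' @return The per-threshold tibble of observed and permutation-expected
#'   overlap counts and estimated FDR.
#' @export
tidy.wb_common_genes <- function(x, ...) x$thresholds

#' Plot per-configuration AUC distributions of an evaluation
#'
#' Boxplots of per-round AUC by feature configuration, with the mean marked.
#'
#' @param object a `wb_evaluation`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wb_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$rounds,
                  ggplot2::aes(x = .data$config, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 23,
                          fill = "white", size = 2.5) +
    ggplot2::labs(x = NULL, y = "AUC (per round)",
                  title = sprintf("Disease-specific classification: %s",
                                  object$disease)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a dataset similarity matrix with its clustering order
#'
#' @param similarity correlation matrix from [similarity_matrix()].
#' @param clustering optional result of [cluster_datasets()]; when given,
#'   rows/columns follow the dendrogram order.
#' @return A ggplot heatmap of pairwise correlations.
#' @export
plot_similarity <- function(similarity, clustering = NULL) {
  ord <- if (!is.null(clustering)) clustering$tree$order else
    seq_len(ncol(similarity))
  ids <- colnames(similarity)[ord]
  df <- tidyr::expand_grid(a = ids, b = ids)
  df$cor <- similarity[cbind(df$a, df$b)]
  df$a <- factor(df$a, levels = ids)
  df$b <- factor(df$b, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$cor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Spearman") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
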
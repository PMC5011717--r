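# Preprocessing: quantile normalization, per-dataset low-expression filtering,
# missingness filtering, kNN imputation, and the control-anchored
# Z-transformation with strict fit/apply separation.

#' Quantile-normalize an expression dataset
#'
#' After normalization every sample column has identical sorted values, equal
#' to the across-sample mean of column-sorted values; ties within a column
#' receive the mean of the reference values at their tied rank positions.
#' Requires complete data (impute first).
#'
#' @param x a `wb_expression` without missing values.
#' @return A `wb_expression` of the same shape.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "wb_expression"))
  if (anyNA(x$values)) {
    stop("missing values present; run filter_and_impute() first", call. = FALSE)
  }
  qn <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(qn) <- dimnames(x$values)
  expression_dataset(pmax(qn, if (x$scale == "linear") 0 else -Inf),
                     scale = x$scale, annotations = x$samples)
}

#' Filter low-expressed and missing-heavy genes, impute the rest
#'
#' Three steps: (1) within each `dataset_id`, drop genes whose non-missing
#' mean is at or below the `mean_percentile`-th percentile of per-gene means
#' in that dataset (the union of per-dataset drops is removed everywhere);
#' (2) drop genes missing in more than `max_missing_frac` of all samples of
#' the combined matrix; (3) impute remaining missing entries by the average of
#' the `knn_k` nearest genes (Euclidean distance over shared non-missing
#' samples, scaled to per-sample mean squared difference) that are observed at
#' the target sample.
#'
#' @param x a `wb_expression` with annotations (for `dataset_id`).
#' @param mean_percentile percentile (0-100) for the per-dataset
#'   low-expression cut.
#' @param max_missing_frac maximum tolerated fraction of missing samples per
#'   gene.
#' @param knn_k number of neighbour genes used for imputation.
#' @return A filtered, complete `wb_expression`. Dropped genes are reported in
#'   attributes `dropped_low` and `dropped_missing`.
#' @export
filter_and_impute <- function(x, mean_percentile = 25, max_missing_frac = 0.2,
                              knn_k = 10) {
  stopifnot(inherits(x, "wb_expression"))
  m <- x$values
  if (nrow(m) == 0) stop("empty dataset", call. = FALSE)
  ds <- if (!is.null(x$samples)) x$samples$dataset_id else rep("all", ncol(m))

  dropped_low <- character(0)
  for (d in unique(ds)) {
    sub <- m[, ds == d, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[!is.finite(mu)] <- NA_real_
    cut <- quantile(mu, mean_percentile / 100, na.rm = TRUE, names = FALSE)
    dropped_low <- union(dropped_low, rownames(m)[!is.na(mu) & mu <= cut])
  }
  keep <- setdiff(rownames(m), dropped_low)
  m <- m[keep, , drop = FALSE]

  miss_frac <- rowMeans(is.na(m))
  dropped_missing <- rownames(m)[miss_frac > max_missing_frac]
  m <- m[miss_frac <= max_missing_frac, , drop = FALSE]
  if (nrow(m) == 0) stop("all genes removed by filtering", call. = FALSE)

  if (anyNA(m)) {
    if (any(rowSums(!is.na(m)) == 0)) {
      stop("gene with no observed value reached imputation", call. = FALSE)
    }
    m <- knn_impute(m, knn_k)
  }
  out <- expression_dataset(m, scale = x$scale, annotations = x$samples)
  attr(out, "dropped_low") <- dropped_low
  attr(out, "dropped_missing") <- dropped_missing
  out
}

# Gene-wise kNN imputation: neighbours ranked by mean squared difference over
# shared non-missing samples; only neighbours observed at the target sample
# contribute. Falls back to the gene's own observed mean when no candidate
# neighbour exists.
knn_impute <- function(m, k) {
  obs <- !is.na(m)
  for (i in which(rowSums(!obs) > 0)) {
    miss_j <- which(!obs[i, ])
    diffs <- sweep(m, 2, m[i, ], "-")^2
    shared <- obs & matrix(obs[i, ], nrow(m), ncol(m), byrow = TRUE)
    n_shared <- rowSums(shared)
    d2 <- rowSums(ifelse(shared, diffs, 0)) / pmax(n_shared, 1)
    d2[i] <- Inf
    d2[n_shared == 0] <- Inf
    ord <- order(d2, rownames(m))
    for (j in miss_j) {
      cand <- ord[obs[ord, j] & is.finite(d2[ord])]
      if (length(cand) == 0) {
        m[i, j] <- mean(m[i, ], na.rm = TRUE)
      } else {
        m[i, j] <- mean(m[head(cand, k), j])
      }
    }
  }
  m
}

#' Fit control-anchored Z-transformation parameters
#'
#' Per-feature mean and sample standard deviation (n-1 denominator) over the
#' declared control samples only. Features whose control SD is at or below
#' `sd_floor` are excluded and listed in the `excluded` attribute.
#'
#' @param m numeric feature-by-sample matrix (expression, residuals, or cell
#'   components alike), or a `wb_expression`.
#' @param control_samples character vector of control sample ids (>= 2).
#' @param sd_floor minimum admissible control SD.
#' @param source identifier recorded for provenance of the control set.
#' @return A `wb_zparams` object: tibble with columns `feature`, `mean`, `sd`
#'   plus attributes `source` and `excluded`.
#' @export
fit_z_params <- function(m, control_samples, sd_floor = 1e-8,
                         source = "controls") {
  if (inherits(m, "wb_expression")) m <- m$values
  m <- as.matrix(m)
  missing_ctrl <- setdiff(control_samples, colnames(m))
  if (length(missing_ctrl)) {
    stop("control samples absent from matrix: ",
         paste(head(missing_ctrl, 5), collapse = ", "), call. = FALSE)
  }
  if (length(control_samples) < 2) {
    stop("need >= 2 control samples to fit Z parameters", call. = FALSE)
  }
  ctrl <- m[, control_samples, drop = FALSE]
  mu <- rowMeans(ctrl)
  sdv <- sqrt(rowSums((ctrl - mu)^2) / (ncol(ctrl) - 1))
  keep <- sdv > sd_floor
  out <- tibble::tibble(feature = rownames(m)[keep], mean = unname(mu[keep]),
                        sd = unname(sdv[keep]))
  attr(out, "excluded") <- rownames(m)[!keep]
  attr(out, "source") <- source
  class(out) <- c("wb_zparams", class(out))
  out
}

#' Apply Z-transformation parameters
#'
#' Computes `(x - mean) / sd` per feature for all samples, cases and controls
#' alike. Features present in `params` but absent from the matrix are dropped
#' with a warning; matrix features absent from `params` are dropped silently
#' (they were excluded at fit time).
#'
#' @param m feature-by-sample matrix or `wb_expression`.
#' @param params a `wb_zparams` from [fit_z_params()].
#' @return A numeric matrix restricted to the fitted features.
#' @export
apply_z <- function(m, params) {
  if (inherits(m, "wb_expression")) m <- m$values
  m <- as.matrix(m)
  absent <- setdiff(params$feature, rownames(m))
  if (length(absent)) {
    warning("features in Z parameters absent from matrix, dropped: ",
            paste(head(absent, 5), collapse = ", "), call. = FALSE)
  }
  use <- params[params$feature %in% rownames(m), ]
  (m[use$feature, , drop = FALSE] - use$mean) / use$sd
}

#' Serialize / read Z parameters as TSV
#'
#' @param params a `wb_zparams`.
#' @param path file path.
#' @return `path` (write) or a `wb_zparams` (read).
#' @export
write_z_params <- function(params, path) {
  write.table(params[, c("feature", "mean", "sd")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_z_params
#' @export
read_z_params <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  out <- tibble::as_tibble(df[, c("feature", "mean", "sd")])
  out$feature <- as.character(out$feature)
  attr(out, "excluded") <- character(0)
  attr(out, "source") <- path
  class(out) <- c("wb_zparams", class(out))
  out
}
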
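# Cross-dataset meta-analysis: per-dataset differential statistics,
# fold-change profiles, informative-gene pooling, Spearman similarity with
# complete-linkage clustering, and permutation-FDR detection of commonly
# up/down-regulated genes.

#' Per-gene differential expression statistics for one dataset
#'
#' Case-minus-control log2 fold change, Welch t, two-sided p and
#' Benjamini-Hochberg FDR across genes. Linear-scale input is
#' log2-transformed with offset 1 first.
#'
#' @param x annotated `wb_expression` (>= 2 samples per group).
#' @param values optional feature-by-sample matrix overriding `x$values`
#'   (e.g. residuals) — used as-is, no log transform.
#' @return A tibble: `gene`, `log2fc`, `t`, `p`, `fdr`, `n_case`,
#'   `n_control`.
#' @export
differential_stats <- function(x, values = NULL) {
  stopifnot(inherits(x, "wb_expression"))
  is_case <- x$samples$group == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  m <- if (!is.null(values)) as.matrix(values) else if (x$scale == "linear") {
    log2(x$values + 1)
  } else x$values
  res <- row_welch_t(m, is_case)
  tibble::tibble(gene = res$feature,
                 log2fc = res$mean_case - res$mean_control,
                 t = res$t, p = res$p,
                 fdr = p.adjust(res$p, method = "BH"),
                 n_case = sum(is_case), n_control = sum(!is_case))
}

#' Assemble a fold-change profile matrix across datasets
#'
#' @param stats_list named list of [differential_stats()] tibbles, one per
#'   dataset.
#' @return A gene-by-dataset matrix of log2 fold changes (`NA` where a gene
#'   was not measured in a dataset).
#' @export
fold_change_profiles <- function(stats_list) {
  stopifnot(length(stats_list) >= 1, !is.null(names(stats_list)))
  genes <- sort(unique(unlist(lapply(stats_list, `[[`, "gene"))))
  out <- matrix(NA_real_, length(genes), length(stats_list),
                dimnames = list(genes, names(stats_list)))
  for (d in names(stats_list)) {
    s <- stats_list[[d]]
    out[s$gene, d] <- s$log2fc
  }
  out
}

#' Pool disease-informative genes across datasets
#'
#' Union, over datasets, of each dataset's `top_m` most differentially
#' expressed genes (ranked by p-value; ties by `|log2fc|` then gene id),
#' intersected with genes measured in strictly more than `min_coverage_frac`
#' of the datasets.
#'
#' @param profiles gene-by-dataset fold-change matrix from
#'   [fold_change_profiles()].
#' @param stats_list named list of [differential_stats()] tibbles (>= 2).
#' @param top_m per-dataset count of top genes pooled.
#' @param min_coverage_frac minimum measured fraction of datasets
#'   (exclusive).
#' @return Sorted character vector of informative gene ids.
#' @export
select_informative_genes <- function(profiles, stats_list, top_m = 100,
                                     min_coverage_frac = 0.5) {
  if (length(stats_list) < 2) stop("need >= 2 datasets", call. = FALSE)
  top <- lapply(stats_list, function(s) {
    ord <- order(s$p, -abs(s$log2fc), s$gene)
    s$gene[ord][seq_len(min(top_m, nrow(s)))]
  })
  pooled <- sort(unique(unlist(top)))
  coverage <- rowMeans(!is.na(profiles[pooled, , drop = FALSE]))
  sort(pooled[coverage > min_coverage_frac])
}

#' Pairwise Spearman similarity of fold-change profiles
#'
#' Spearman correlation of the informative-gene fold-change profiles between
#' each pair of datasets, using pairwise-complete genes; pairs sharing fewer
#' than 3 measured genes get `NA`. Symmetric with unit diagonal.
#'
#' @param profiles gene-by-dataset fold-change matrix.
#' @param genes informative gene ids (rows to use).
#' @return A dataset-by-dataset correlation matrix.
#' @export
similarity_matrix <- function(profiles, genes = rownames(profiles)) {
  p <- profiles[genes, , drop = FALSE]
  n <- ncol(p)
  out <- diag(1, n)
  dimnames(out) <- list(colnames(p), colnames(p))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(p[, i]) & !is.na(p[, j])
      out[i, j] <- out[j, i] <- if (sum(ok) < 3) NA_real_ else
        cor(p[ok, i], p[ok, j], method = "spearman")
    }
  }
  out
}

#' Complete-linkage clustering of datasets on 1 - correlation
#'
#' @param similarity complete (no `NA`) correlation matrix.
#' @param k number of clusters for the tree cut (omit for labels at
#'   `height`).
#' @param height cut height alternative to `k`.
#' @return A list with `labels` (named cluster assignment) and `tree`
#'   (`hclust` merge tree).
#' @export
cluster_datasets <- function(similarity, k = NULL, height = NULL) {
  if (anyNA(similarity)) {
    stop("similarity matrix has missing entries; recompute with ",
         "pairwise-complete genes or drop sparse datasets", call. = FALSE)
  }
  tree <- hclust(as.dist(1 - similarity), method = "complete")
  labels <- if (!is.null(k)) cutree(tree, k = k) else if (!is.null(height)) {
    cutree(tree, h = height)
  } else cutree(tree, k = min(2, ncol(similarity)))
  list(labels = labels, tree = tree)
}

#' Commonly regulated genes across datasets with permutation FDR
#'
#' Per dataset, the DE set is genes at BH-FDR below `de_fdr_cutoff`, split by
#' fold-change direction. The observed count `o_i` is the number of genes DE
#' in the same direction in at least `n_i` datasets (`n_i = 2 ..
#' n_datasets`). The null expectation `p_i` is the mean of the same count
#' over `n_perm` permutations in which each dataset's up/down DE labels are
#' reassigned uniformly at random among its measured genes with set sizes
#' preserved. `fdr = p_i / o_i` (`NA` when `o_i = 0`).
#'
#' @param stats_list named list of [differential_stats()] tibbles (>= 2).
#' @param de_fdr_cutoff per-dataset BH-FDR cutoff.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param chosen_n threshold at which `up_set`/`down_set` are reported
#'   (default: the largest `n_i` with `o_i > 0`).
#' @return A `wb_common_genes`: list with `thresholds` (tibble: `n`,
#'   `observed`, `perm_mean`, `perm_sd`, `perm_se`, `fdr`), `up_set`,
#'   `down_set`, `chosen_n`.
#' @export
common_genes_fdr <- function(stats_list, de_fdr_cutoff = 0.1, n_perm = 1000,
                             seed = 1, chosen_n = NULL) {
  if (length(stats_list) < 2) stop("need >= 2 datasets", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  nd <- length(stats_list)
  genes <- sort(unique(unlist(lapply(stats_list, `[[`, "gene"))))
  measured <- lapply(stats_list, `[[`, "gene")
  up_sets <- lapply(stats_list, function(s) s$gene[s$fdr < de_fdr_cutoff &
                                                     s$log2fc > 0])
  down_sets <- lapply(stats_list, function(s) s$gene[s$fdr < de_fdr_cutoff &
                                                       s$log2fc < 0])
  count_shared <- function(up_l, down_l) {
    up_n <- table(factor(unlist(up_l), levels = genes))
    down_n <- table(factor(unlist(down_l), levels = genes))
    list(up = as.integer(up_n), down = as.integer(down_n))
  }
  obs <- count_shared(up_sets, down_sets)
  ns <- 2:nd
  observed <- vapply(ns, function(n) {
    sum(obs$up >= n) + sum(obs$down >= n)
  }, integer(1))

  withr::local_seed(seed)
  perm_counts <- matrix(0L, n_perm, length(ns))
  for (b in seq_len(n_perm)) {
    pu <- vector("list", nd); pd <- vector("list", nd)
    for (d in seq_len(nd)) {
      g <- measured[[d]]
      pick <- sample(g, length(up_sets[[d]]) + length(down_sets[[d]]))
      pu[[d]] <- pick[seq_along(up_sets[[d]])]
      pd[[d]] <- setdiff(pick, pu[[d]])
    }
    pc <- count_shared(pu, pd)
    perm_counts[b, ] <- vapply(ns, function(n) {
      sum(pc$up >= n) + sum(pc$down >= n)
    }, integer(1))
  }
  perm_mean <- colMeans(perm_counts)
  perm_sd <- apply(perm_counts, 2, sd)
  thresholds <- tibble::tibble(
    n = ns, observed = observed, perm_mean = perm_mean, perm_sd = perm_sd,
    perm_se = perm_sd / sqrt(n_perm),
    fdr = ifelse(observed > 0, perm_mean / observed, NA_real_))
  if (is.null(chosen_n)) {
    pos <- ns[observed > 0]
    chosen_n <- if (length(pos)) max(pos) else nd
  }
  up_set <- genes[obs$up >= chosen_n]
  down_set <- genes[obs$down >= chosen_n]
  structure(list(thresholds = thresholds, up_set = up_set,
                 down_set = down_set, chosen_n = chosen_n,
                 n_perm = n_perm, de_fdr_cutoff = de_fdr_cutoff),
            class = "wb_common_genes")
}

#' @export
print.wb_common_genes <- function(x, ...) {
  cat(sprintf("<wb_common_genes> %d up / %d down at n >= %d (DE FDR < %g)\n",
              length(x$up_set), length(x$down_set), x$chosen_n,
              x$de_fdr_cutoff))
  print(x$thresholds)
  invisible(x)
}
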
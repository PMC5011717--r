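# Cell-frequency estimation from bulk mixtures. Two estimators: a marker-based
# digital-sorting (DSA-style) solver that needs only cell-type-exclusive
# marker gene lists, and a signature-based non-negative least squares
# regression against a reference expression matrix. Both operate on
# linear-scale (un-logged) expression.

#' Marker-based (DSA-style) cell-frequency estimation
#'
#' Three stages. (1) `m_kj`: mean expression of cell type `k`'s markers in
#' sample `j` (markers present and non-missing in the data; coverage is
#' reported). (2) Under the mixing model `m_kj = c_k * f_kj` with
#' `sum_k f_kj = 1`, the reciprocal scales `g_k = 1/c_k` satisfy
#' `sum_k m_kj g_k = 1` for every sample; `g` is estimated by non-negative
#' least squares over all samples. (3) `f_kj = m_kj * g_k`, optionally
#' rescaled so each sample column sums to one.
#'
#' @param x linear-scale `wb_expression`.
#' @param markers [marker_sets()]; each cell type must have at least one
#'   marker present in `x`.
#' @param enforce_sum_to_one rescale each sample's frequencies to sum to 1.
#' @return A [frequency_matrix()] (cell types x samples) with attributes
#'   `marker_coverage` (tibble: cell_type, n_markers, n_used) and `g`
#'   (estimated reciprocal scales). Samples whose marker means are all zero
#'   are returned as all-`NA` columns with a warning.
#' @export
dsa_frequencies <- function(x, markers, enforce_sum_to_one = TRUE) {
  stopifnot(inherits(x, "wb_expression"), inherits(markers, "wb_markers"))
  if (x$scale != "linear") {
    stop("DSA requires linear-scale (un-logged) expression", call. = FALSE)
  }
  genes <- rownames(x$values)
  used <- lapply(markers, intersect, y = genes)
  if (any(lengths(used) == 0)) {
    stop("cell type(s) with no usable marker in the data: ",
         paste(names(used)[lengths(used) == 0], collapse = ", "),
         call. = FALSE)
  }
  coverage <- tibble::tibble(cell_type = names(markers),
                             n_markers = lengths(markers),
                             n_used = lengths(used))
  M <- t(vapply(used, function(g) {
    colMeans(x$values[g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(x$values))))
  dimnames(M) <- list(names(markers), colnames(x$values))
  M[!is.finite(M)] <- NA_real_

  dead <- colSums(M, na.rm = TRUE) == 0 | colSums(!is.na(M)) == 0
  if (any(dead)) {
    warning("sample(s) with all-zero marker means returned as NA: ",
            paste(head(colnames(M)[dead], 5), collapse = ", "), call. = FALSE)
  }
  ok <- !dead & colSums(is.na(M)) == 0
  if (!any(ok)) stop("no usable samples for DSA", call. = FALSE)
  g <- pracma::lsqnonneg(t(M[, ok, drop = FALSE]), rep(1, sum(ok)))$x
  Fm <- M * g
  if (enforce_sum_to_one) {
    cs <- colSums(Fm)
    pos <- !is.na(cs) & cs > 0
    Fm[, pos] <- sweep(Fm[, pos, drop = FALSE], 2, cs[pos], "/")
  }
  Fm[, dead] <- NA_real_
  out <- frequency_matrix(pmax(Fm, 0))
  attr(out, "marker_coverage") <- coverage
  attr(out, "g") <- setNames(g, names(markers))
  attr(out, "sum_to_one") <- enforce_sum_to_one
  out
}

#' Signature-based NNLS cell-frequency estimation
#'
#' For each sample `j`, solves `min_f ||x_j - S f||^2` subject to `f >= 0`
#' over the genes shared between the data and the signature matrix; columns
#' are optionally rescaled to sum to one (all-zero solutions are left as zeros
#' with a warning).
#'
#' @param x linear-scale `wb_expression`.
#' @param signature a [signature_matrix()]; the gene overlap with `x` must be
#'   at least twice the number of cell types.
#' @param rescale divide each column by its sum.
#' @return A [frequency_matrix()] (cell types x samples).
#' @export
signature_nnls_frequencies <- function(x, signature, rescale = TRUE) {
  stopifnot(inherits(x, "wb_expression"))
  if (x$scale != "linear") {
    stop("signature deconvolution requires linear-scale expression", call. = FALSE)
  }
  S <- as.matrix(signature)
  shared <- intersect(rownames(x$values), rownames(S))
  if (length(shared) < ncol(S) + 1) {
    stop(sprintf("insufficient gene overlap with signature (%d < %d)",
                 length(shared), ncol(S) + 1), call. = FALSE)
  }
  A <- S[shared, , drop = FALSE]
  Y <- x$values[shared, , drop = FALSE]
  Y[is.na(Y)] <- 0
  Fm <- nnls_multi(A, Y)
  if (rescale) {
    cs <- colSums(Fm)
    if (any(cs == 0)) {
      warning("sample(s) with all-zero frequency solution left as zeros: ",
              paste(head(colnames(Fm)[cs == 0], 5), collapse = ", "),
              call. = FALSE)
    }
    pos <- cs > 0
    Fm[, pos] <- sweep(Fm[, pos, drop = FALSE], 2, cs[pos], "/")
  }
  out <- frequency_matrix(Fm)
  attr(out, "sum_to_one") <- rescale
  out
}

#' Case-vs-control change in estimated cell components
#'
#' Welch two-sample t statistic (case minus control) per cell type. Cell types
#' whose estimates have zero variance in both groups, or that are zero (or
#' missing) in every sample, are flagged not calculable and get `NA`
#' statistics.
#'
#' @param freq a [frequency_matrix()] (cell types x samples).
#' @param groups character vector over samples (`"case"`/`"control"`), or a
#'   `wb_expression` whose annotations supply the groups.
#' @return A tibble: `cell_type`, `mean_case`, `mean_control`, `t`, `p`,
#'   `calculable`.
#' @export
cell_component_change <- function(freq, groups) {
  if (inherits(groups, "wb_expression")) {
    groups <- groups$samples$group[match(colnames(freq), groups$samples$sample_id)]
  }
  stopifnot(length(groups) == ncol(freq))
  is_case <- groups == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  m <- unclass(freq)
  res <- row_welch_t(m, is_case)
  var_case <- apply(m[, is_case, drop = FALSE], 1, var, na.rm = TRUE)
  var_ctrl <- apply(m[, !is_case, drop = FALSE], 1, var, na.rm = TRUE)
  all_zero <- rowSums(m != 0, na.rm = TRUE) == 0
  calculable <- unname(!((var_case == 0 & var_ctrl == 0) | all_zero |
                           is.na(res$t)))
  tibble::tibble(cell_type = rownames(m),
                 mean_case = res$mean_case, mean_control = res$mean_control,
                 t = ifelse(calculable, res$t, NA_real_),
                 p = ifelse(calculable, res$p, NA_real_),
                 calculable = calculable)
}
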
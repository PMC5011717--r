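# Shared numerics: vectorized Welch statistics, small exact NNLS, seeded
# stratified fold assignment.

#' Row-wise Welch two-sample t statistics
#'
#' Computes, for every row of a matrix, the Welch (unequal-variance) t
#' statistic for case minus control, with Welch-Satterthwaite degrees of
#' freedom and two-sided p-values. Rows with zero variance in both groups get
#' `NA` statistics.
#'
#' @param m numeric matrix (features x samples); `NA`s are ignored per row.
#' @param is_case logical vector over columns.
#' @return A tibble with columns `feature`, `mean_case`, `mean_control`,
#'   `t`, `df`, `p`.
#' @export
row_welch_t <- function(m, is_case) {
  stopifnot(ncol(m) == length(is_case))
  a <- m[, is_case, drop = FALSE]
  b <- m[, !is_case, drop = FALSE]
  na_ <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na_ - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  se2 <- va / na_ + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na_^2 * pmax(na_ - 1, 1)) +
                   vb^2 / (nb^2 * pmax(nb - 1, 1)))
  bad <- !is.finite(t_stat) | na_ < 2 | nb < 2
  t_stat[bad] <- NA_real_
  df[bad] <- NA_real_
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  tibble::tibble(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
                 mean_case = unname(ma), mean_control = unname(mb),
                 t = unname(t_stat), df = unname(df), p = unname(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact NNLS for many right-hand sides sharing one design matrix, by
# exhaustive enumeration of support subsets. For K columns there are 2^K - 1
# candidate supports; the restricted OLS solution that is feasible (>= 0) with
# the smallest residual sum of squares is the NNLS optimum (it is feasible for
# the full problem, and the optimum itself appears as the OLS fit on its own
# support). Intended for the small K of cell-type panels; falls back to
# pracma::lsqnonneg above `max_enum` columns.
#
# A: n x K design; Y: n x m right-hand sides. Returns K x m coefficients.
nnls_multi <- function(A, Y, max_enum = 8) {
  A <- as.matrix(A); Y <- as.matrix(Y)
  K <- ncol(A); m <- ncol(Y)
  if (K > max_enum) {
    out <- apply(Y, 2, function(y) pracma::lsqnonneg(A, y)$x)
    out <- matrix(out, nrow = K)
    dimnames(out) <- list(colnames(A), colnames(Y))
    return(out)
  }
  best_rss <- rep(Inf, m)
  best_coef <- matrix(0, K, m, dimnames = list(colnames(A), colnames(Y)))
  y_ss <- colSums(Y^2)
  # empty support: coef 0, rss = ||y||^2
  best_rss <- y_ss
  for (size in seq_len(K)) {
    for (S in utils::combn(K, size, simplify = FALSE)) {
      As <- A[, S, drop = FALSE]
      G <- crossprod(As)
      ok <- tryCatch({ Gi <- solve(G); TRUE }, error = function(e) FALSE)
      if (!ok) next
      beta <- Gi %*% crossprod(As, Y)            # |S| x m
      feasible <- colSums(beta < -1e-12) == 0
      if (!any(feasible)) next
      fit <- As %*% beta
      rss <- colSums((Y - fit)^2)
      improve <- feasible & rss < best_rss - 1e-12
      if (any(improve)) {
        best_rss[improve] <- rss[improve]
        best_coef[, improve] <- 0
        best_coef[S, improve] <- pmax(beta[, improve, drop = FALSE], 0)
      }
    }
  }
  best_coef
}

# Hanley-McNeil standard error of an AUC estimate with n_pos positives and
# n_neg negatives.
auc_se <- function(a, n_pos, n_neg) {
  a <- min(max(a, 0.5), 1 - 1e-12)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
         (n_pos * n_neg))
}

# Seeded stratified fold assignment: balanced fold sizes within each stratum.
stratified_folds <- function(strata, k) {
  folds <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}
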
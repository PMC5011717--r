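# Residual expression profiles. The mixture model X = B F + R is fitted on
# control samples: the healthy cell-type basis B is estimated gene-wise by
# non-negative least squares against the cell-frequency design, and the
# residual profile R = X - B F is then computed identically for every sample.
# For controls R is measurement noise; for cases it additionally carries
# cell-type-restricted expression change — composition change alone leaves R
# untouched.

#' Estimate the healthy cell-type basis from control samples
#'
#' For each gene `i` independently, solves
#' `b_i = argmin_{b >= 0} sum_j (x_ij - sum_k b_k f_kj)^2` over the control
#' samples. Equals ordinary least squares whenever the OLS solution is
#' already non-negative. Deterministic given its inputs.
#'
#' @param x_controls linear-scale `wb_expression` (or plain matrix) of control
#'   samples.
#' @param f_controls [frequency_matrix()] with columns matching the control
#'   samples.
#' @return A [basis_matrix()] (genes x cell types).
#' @export
estimate_basis <- function(x_controls, f_controls) {
  m <- if (inherits(x_controls, "wb_expression")) x_controls$values else
    as.matrix(x_controls)
  Fm <- unclass(f_controls)
  if (ncol(m) == 0) stop("zero control samples", call. = FALSE)
  if (!identical(colnames(m), colnames(Fm))) {
    shared <- intersect(colnames(m), colnames(Fm))
    if (length(shared) == 0) stop("no shared samples between X and F", call. = FALSE)
    m <- m[, shared, drop = FALSE]
    Fm <- Fm[, shared, drop = FALSE]
  }
  K <- nrow(Fm)
  if (ncol(m) < K) {
    warning(sprintf("fewer control samples (%d) than cell types (%d)",
                    ncol(m), K), call. = FALSE)
  }
  kappa_ <- tryCatch(kappa(Fm %*% t(Fm), exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa_) || kappa_ > 1e10) {
    warning(sprintf("frequency design is near rank-deficient (condition number %.3g)",
                    kappa_), call. = FALSE)
  }
  if (anyNA(m)) stop("missing expression values; impute before basis fitting",
                     call. = FALSE)
  B <- t(nnls_multi(t(Fm), t(m)))
  dimnames(B) <- list(rownames(m), rownames(Fm))
  basis_matrix(B)
}

#' Per-sample residual expression profiles
#'
#' `R = X - B F`, computed identically for case and control samples.
#'
#' @param x linear-scale `wb_expression` (or matrix).
#' @param freq [frequency_matrix()] aligned to the samples of `x`.
#' @param basis [basis_matrix()] aligned to the genes of `x`.
#' @return A [residual_matrix()] (genes x samples).
#' @export
compute_residuals <- function(x, freq, basis) {
  m <- if (inherits(x, "wb_expression")) x$values else as.matrix(x)
  Fm <- unclass(freq)
  B <- unclass(basis)
  if (!identical(rownames(m), rownames(B))) {
    if (!setequal(rownames(m), rownames(B))) {
      stop("gene sets of X and basis differ", call. = FALSE)
    }
    B <- B[rownames(m), , drop = FALSE]
  }
  if (!identical(colnames(m), colnames(Fm))) {
    if (!setequal(colnames(m), colnames(Fm))) {
      stop("sample sets of X and F differ", call. = FALSE)
    }
    Fm <- Fm[, colnames(m), drop = FALSE]
  }
  if (!identical(colnames(B), rownames(Fm))) {
    if (!setequal(colnames(B), rownames(Fm))) {
      stop("cell types of basis and F differ", call. = FALSE)
    }
    Fm <- Fm[colnames(B), , drop = FALSE]
  }
  residual_matrix(m - B %*% Fm)
}
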
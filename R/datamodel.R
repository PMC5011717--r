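#' @importFrom rlang .data
#' @importFrom stats cor cutree hclust as.dist p.adjust pt quantile
#'   rnorm rgamma rlnorm runif sd setNames var predict
#' @importFrom utils read.delim write.table head
NULL

# ---- ExpressionDataset ------------------------------------------------------

#' Construct an expression dataset
#'
#' A gene-by-sample expression matrix with a declared scale and per-sample
#' annotations. This is the central container of the package: whole-blood
#' expression is modelled as a linear mixture of cell-type-specific expression
#' weighted by cell frequencies, and all downstream operations (deconvolution,
#' residualization, classification) consume this type.
#'
#' @param values numeric matrix, genes as rows and samples as columns, with
#'   rownames (gene ids) and colnames (sample ids). `NA` entries are allowed.
#' @param scale `"linear"` or `"log2"`. Linear-scale values must be
#'   non-negative where present.
#' @param annotations optional tibble/data.frame with columns `sample_id`,
#'   `dataset_id`, `group` (`"case"`/`"control"`) and `disease` (may be `NA`
#'   for controls). Rows are matched to the matrix columns by `sample_id`.
#' @return An object of class `wb_expression`: a list with elements `values`,
#'   `scale` and `samples` (annotation tibble, `NULL` if none supplied).
#' @export
expression_dataset <- function(values, scale = c("linear", "log2"),
                               annotations = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in `values`", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in `values`", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop("linear-scale expression values must be >= 0", call. = FALSE)
  }
  samples <- NULL
  if (!is.null(annotations)) {
    samples <- validate_annotations(annotations, colnames(values))
  }
  structure(list(values = values, scale = scale, samples = samples),
            class = "wb_expression")
}

validate_annotations <- function(annotations, sample_ids) {
  ann <- tibble::as_tibble(annotations)
  required <- c("sample_id", "dataset_id", "group")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols)) {
    stop("annotations lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"disease" %in% names(ann)) ann$disease <- NA_character_
  ann$disease <- as.character(ann$disease)
  ann$disease[!is.na(ann$disease) & ann$disease == ""] <- NA_character_
  bad_group <- setdiff(unique(ann$group), c("case", "control"))
  if (length(bad_group)) {
    stop("invalid group value(s): ", paste(bad_group, collapse = ", "),
         " (must be 'case' or 'control')", call. = FALSE)
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample_id in annotations", call. = FALSE)
  }
  unmatched <- setdiff(sample_ids, ann$sample_id)
  if (length(unmatched)) {
    stop("samples without annotation: ", paste(head(unmatched, 5), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(ann$sample_id, sample_ids)
  if (length(extra)) {
    warning("annotation rows for samples absent from the matrix: ",
            paste(head(extra, 5), collapse = ", "), call. = FALSE)
    ann <- ann[ann$sample_id %in% sample_ids, , drop = FALSE]
  }
  ann[match(sample_ids, ann$sample_id), , drop = FALSE]
}

#' @export
print.wb_expression <- function(x, ...) {
  cat(sprintf("<wb_expression> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$samples)) {
    cat(sprintf("  datasets: %s\n",
                paste(unique(x$samples$dataset_id), collapse = ", ")))
    cat(sprintf("  groups: %d case / %d control\n",
                sum(x$samples$group == "case"),
                sum(x$samples$group == "control")))
  }
  n_missing <- sum(is.na(x$values))
  if (n_missing > 0) cat(sprintf("  missing entries: %d\n", n_missing))
  invisible(x)
}

#' Subset an expression dataset by gene and/or sample ids
#'
#' @param x a `wb_expression`.
#' @param genes,samples character vectors of ids to keep (default: all).
#' @return A `wb_expression` restricted to the requested ids, in the
#'   requested order.
#' @export
subset_expression <- function(x, genes = rownames(x$values),
                              samples = colnames(x$values)) {
  stopifnot(inherits(x, "wb_expression"))
  values <- x$values[genes, samples, drop = FALSE]
  ann <- x$samples
  if (!is.null(ann)) ann <- ann[match(samples, ann$sample_id), , drop = FALSE]
  expression_dataset(values, scale = x$scale, annotations = ann)
}

# ---- Matrix-backed types ----------------------------------------------------

new_named_matrix <- function(values, class, nonneg = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop(class, " requires row and column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate row or column ids in ", class, call. = FALSE)
  }
  if (nonneg && any(values < 0, na.rm = TRUE)) {
    stop(class, " values must be >= 0", call. = FALSE)
  }
  structure(values, class = c(class, "matrix", "array"))
}

#' Cell-frequency matrix (cell types x samples)
#'
#' Holds non-negative per-sample cell-type frequency estimates. When
#' `sum_to_one` is asserted, each sample column must sum to 1 within 1e-6.
#'
#' @param values numeric matrix, cell types as rows, samples as columns.
#' @param sum_to_one logical; assert (and record) that columns lie on the
#'   simplex.
#' @return A `wb_frequencies` matrix.
#' @export
frequency_matrix <- function(values, sum_to_one = FALSE) {
  m <- new_named_matrix(values, "wb_frequencies")
  if (sum_to_one) {
    sums <- colSums(m)
    ok <- is.na(sums) | abs(sums - 1) <= 1e-6
    if (!all(ok)) {
      stop("frequency columns must sum to 1 (worst deviation ",
           format(max(abs(sums - 1), na.rm = TRUE)), ")", call. = FALSE)
    }
  }
  attr(m, "sum_to_one") <- sum_to_one
  m
}

#' Cell-type basis matrix (genes x cell types)
#'
#' Non-negative cell-type-specific expression under the healthy condition;
#' mixture expression is modelled as basis `%*%` frequencies.
#'
#' @param values numeric matrix, genes as rows, cell types as columns.
#' @return A `wb_basis` matrix.
#' @export
basis_matrix <- function(values) new_named_matrix(values, "wb_basis")

#' Signature matrix (genes x cell types)
#'
#' Reference expression signatures used by signature-based deconvolution.
#'
#' @param values non-negative numeric matrix, genes as rows, cell types as
#'   columns.
#' @return A `wb_signature` matrix.
#' @export
signature_matrix <- function(values) new_named_matrix(values, "wb_signature")

#' Residual expression matrix (genes x samples)
#'
#' Sign-unrestricted deviations of observed expression from the
#' cell-frequency-explained expectation.
#'
#' @param values numeric matrix, genes as rows, samples as columns.
#' @return A `wb_residuals` matrix.
#' @export
residual_matrix <- function(values) {
  new_named_matrix(values, "wb_residuals", nonneg = FALSE)
}

#' @export
print.wb_frequencies <- function(x, ...) {
  cat(sprintf("<wb_frequencies> %d cell types x %d samples\n", nrow(x), ncol(x)))
  print(unclass(x)[, seq_len(min(ncol(x), 5)), drop = FALSE])
  invisible(x)
}

# ---- Marker sets ------------------------------------------------------------

#' Construct cell-type marker sets
#'
#' Marker genes are assumed exclusive: a gene may belong to at most one cell
#' type. Genes listed under several cell types are dropped from all of them
#' with a warning.
#'
#' @param sets named list mapping cell type to a character vector of gene ids.
#' @return A `wb_markers` object (named list of character vectors).
#' @export
marker_sets <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("marker sets must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("duplicate cell-type names", call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) {
    stop("empty marker list for: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "), call. = FALSE)
  }
  all_genes <- unlist(sets, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup)) {
    warning("genes in more than one marker set dropped from all sets: ",
            paste(head(dup, 10), collapse = ", "), call. = FALSE)
    sets <- lapply(sets, function(g) setdiff(g, dup))
    if (any(lengths(sets) == 0)) {
      stop("marker set emptied by cross-set duplicate removal: ",
           paste(names(sets)[lengths(sets) == 0], collapse = ", "),
           call. = FALSE)
    }
  }
  structure(sets, class = "wb_markers")
}

#' @export
print.wb_markers <- function(x, ...) {
  cat(sprintf("<wb_markers> %d cell types (%s markers)\n", length(x),
              paste(lengths(x), collapse = ", ")))
  invisible(x)
}
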
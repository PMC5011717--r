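# TSV/GMT readers and writers. Conventions: tab-separated, header row, first
# column is the row id; missing values written as the token NA (empty cells
# also read as missing); identifiers are case-sensitive opaque strings and
# orientation is fixed (genes as rows), never auto-detected.

read_id_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""), colClasses = "character",
                   quote = "")
  if (ncol(df) < 1) stop("empty table: ", path, call. = FALSE)
  ids <- df[[1]]
  header <- names(df)[-1]  # before subsetting: `[.data.frame` repairs dups
  if (anyDuplicated(header)) {
    dup <- unique(header[duplicated(header)])
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  body <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(NULL, header))
  for (j in seq_len(ncol(body))) {
    raw <- body[[j]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop(sprintf("malformed numeric cell in %s: row '%s', column '%s' (value '%s')",
                   path, ids[bad[1]], colnames(body)[j], raw[bad[1]]),
           call. = FALSE)
    }
    m[, j] <- val
  }
  list(ids = ids, values = m)
}

collapse_duplicate_rows <- function(ids, values) {
  if (!anyDuplicated(ids)) {
    rownames(values) <- ids
    return(values)
  }
  # mean over non-missing values per (gene, sample); all-missing stays NA.
  uniq <- unique(ids)
  out <- matrix(NA_real_, length(uniq), ncol(values),
                dimnames = list(uniq, colnames(values)))
  grp <- match(ids, uniq)
  for (i in seq_along(uniq)) {
    rows <- values[grp == i, , drop = FALSE]
    mu <- colMeans(rows, na.rm = TRUE)
    mu[!is.finite(mu)] <- NA_real_
    out[i, ] <- mu
  }
  out
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Duplicate gene ids (e.g. several probes mapped to one symbol) are collapsed
#' by the mean of their non-missing values. The token `NA` and empty cells are
#' read as missing.
#'
#' @param path path to a TSV file.
#' @param scale declared scale of the stored values, `"linear"` or `"log2"`.
#' @param annotations optional sample annotations (see
#'   [expression_dataset()]), typically from [read_sample_sheet()].
#' @return A [expression_dataset()] object.
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2"),
                                   annotations = NULL) {
  scale <- match.arg(scale)
  parsed <- read_id_matrix(path)
  values <- collapse_duplicate_rows(parsed$ids, parsed$values)
  expression_dataset(values, scale = scale, annotations = annotations)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `dataset_id`, `group` (`case`/`control`) and
#' `disease` (may be empty for controls).
#'
#' @param path path to a TSV file.
#' @return A tibble of per-sample annotations.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""), colClasses = "character",
                   quote = "")
  required <- c("sample_id", "dataset_id", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"disease" %in% names(df)) df$disease <- NA_character_
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad)) {
    stop("invalid group value(s) in sample sheet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df[, c("sample_id", "dataset_id", "group", "disease")])
}

#' Attach a sample sheet to an expression dataset
#'
#' Joins annotations by `sample_id`; sheet rows without a matching matrix
#' column are reported with a warning.
#'
#' @param x a `wb_expression`.
#' @param sheet tibble from [read_sample_sheet()].
#' @return `x` with annotations attached.
#' @export
annotate_expression <- function(x, sheet) {
  stopifnot(inherits(x, "wb_expression"))
  expression_dataset(x$values, scale = x$scale, annotations = sheet)
}

#' Read cell-type marker sets from a GMT file
#'
#' One set per line: set name, description, then a tab-separated gene list.
#' Genes occurring in more than one set are dropped from all sets with a
#' warning (markers must be cell-type exclusive).
#'
#' @param path path to a GMT file.
#' @return A [marker_sets()] object.
#' @export
read_marker_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3 || !any(nzchar(parts[-(1:2)]))) {
      stop("GMT line with no genes for set '", parts[1], "'", call. = FALSE)
    }
    genes <- parts[-(1:2)]
    sets[[parts[1]]] <- genes[nzchar(genes)]
  }
  marker_sets(sets)
}

#' Write a matrix-like object to TSV
#'
#' Works for `wb_expression` and for any named matrix (frequencies, basis,
#' signature, residuals). Missing values are written as the token `NA`. Round
#' trips through the corresponding reader are lossless up to float text
#' precision (17 significant digits are written).
#'
#' @param x a `wb_expression` or a matrix with row and column names.
#' @param path output path.
#' @param id_column header name for the first (row id) column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_column = "id") {
  m <- if (inherits(x, "wb_expression")) x$values else as.matrix(x)
  # built manually to control the NA token and numeric precision
  body <- apply(m, 2, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- "NA"
    out
  })
  if (nrow(m) == 1) body <- matrix(body, nrow = 1, dimnames = dimnames(m))
  if (nrow(m) == 0) {
    writeLines(paste(c(id_column, colnames(m)), collapse = "\t"), path)
    return(invisible(path))
  }
  tab <- cbind(rownames(m), body)
  colnames(tab) <- c(id_column, colnames(m))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a plain named matrix from TSV
#'
#' Counterpart of [write_matrix()] for frequency, basis, signature and
#' residual matrices (no duplicate-row collapsing).
#'
#' @param path path to a TSV file.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  parsed <- read_id_matrix(path)
  if (anyDuplicated(parsed$ids)) {
    stop("duplicate row ids in ", path, call. = FALSE)
  }
  m <- parsed$values
  rownames(m) <- parsed$ids
  m
}

#' Write marker sets to a GMT file
#'
#' @param markers a `wb_markers` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_sets <- function(markers, path) {
  lines <- vapply(names(markers), function(ct) {
    paste(c(ct, ct, markers[[ct]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
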
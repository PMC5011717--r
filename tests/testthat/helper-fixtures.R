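# In-code fixtures shared across test files.

tiny_annotations <- function(ids, groups, dataset_id = "d1", disease = NULL) {
  tibble::tibble(
    sample_id = ids, dataset_id = dataset_id, group = groups,
    disease = if (is.null(disease)) ifelse(groups == "case", "dz", NA) else disease)
}

tiny_expression <- function(values, scale = "linear", groups = NULL,
                            dataset_id = "d1") {
  ann <- if (!is.null(groups)) {
    tiny_annotations(colnames(values), groups, dataset_id)
  } else NULL
  expression_dataset(values, scale = scale, annotations = ann)
}

random_named_matrix <- function(nr, nc, prefix = c("g", "s"), missing = 0) {
  m <- matrix(runif(nr * nc, 0, 100), nr, nc,
              dimnames = list(sprintf("%s%03d", prefix[1], seq_len(nr)),
                              sprintf("%s%03d", prefix[2], seq_len(nc))))
  if (missing > 0) m[sample(length(m), missing)] <- NA
  m
}

# Brute-force NNLS oracle for 2 coefficients: staged exhaustive grid search
# of ||y - A c||^2 over the non-negative quadrant. Later stages zoom around
# the best cell with wide windows so that flat valleys (ill-conditioned A)
# are still located to well below the comparison tolerance.
grid_nnls_2d <- function(A, y, resolution = 1e-3) {
  q <- crossprod(A); c1 <- crossprod(A, y)
  obj <- function(a, b) {
    outer(a^2 * q[1, 1], rep(1, length(b))) +
      outer(rep(1, length(a)), b^2 * q[2, 2]) +
      2 * q[1, 2] * outer(a, b) -
      2 * c1[1] * outer(a, rep(1, length(b))) -
      2 * c1[2] * outer(rep(1, length(a)), b)
  }
  ols <- tryCatch(solve(q, c1), error = function(e) c(1, 1))
  ub <- max(1, 2 * max(abs(ols)))
  step <- resolution * ub
  ga <- seq(0, ub, by = step); gb <- ga
  for (stage in 1:4) {
    o <- obj(ga, gb)
    i <- arrayInd(which.min(o), c(length(ga), length(gb)))
    centre <- c(ga[i[1]], gb[i[2]])
    step <- step / 10
    half <- (if (stage == 1) 600 else 60) * step
    ga <- seq(max(0, centre[1] - half), centre[1] + half, by = step)
    gb <- seq(max(0, centre[2] - half), centre[2] + half, by = step)
  }
  o <- obj(ga, gb)
  i <- arrayInd(which.min(o), c(length(ga), length(gb)))
  c(ga[i[1]], gb[i[2]])
}
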
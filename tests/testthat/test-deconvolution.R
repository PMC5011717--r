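make_marker_dataset <- function(M, groups = NULL) {
  # expression with one pure marker gene per cell type whose value equals the
  # desired marker mean matrix M (cell types x samples)
  rn <- paste0("mk_", rownames(M))
  vals <- M
  rownames(vals) <- rn
  x <- tiny_expression(vals, groups = groups)
  markers <- marker_sets(setNames(as.list(rn), rownames(M)))
  list(x = x, markers = markers)
}

test_that("DSA solves the two-sample linear system exactly", {
  M <- matrix(c(7, 4, 6, 12), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  fx <- make_marker_dataset(M)
  f <- dsa_frequencies(fx$x, fx$markers)
  expect_equal(unname(attr(f, "g")), c(0.1, 0.05), tolerance = 1e-9)
  expect_equal(unname(unclass(f)), matrix(c(0.7, 0.3, 0.4, 0.6), 2),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a sample expressing only one cell type's markers is called pure", {
  M <- matrix(c(9, 5, 0, 7), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("pureA", "mix")))
  fx <- make_marker_dataset(M)
  f <- unclass(dsa_frequencies(fx$x, fx$markers))
  expect_equal(unname(f[, "pureA"]), c(1, 0), tolerance = 1e-9)
})

test_that("DSA recovers true frequencies on noiseless pure-marker mixtures", {
  made <- make_basis(200, c("A", "B", "C", "D"), 5, 50, seed = 41,
                     pure_markers = TRUE)
  sim <- simulate_dataset(made$basis, NULL, 0, 30,
                          c(A = 8, B = 5, C = 3, D = 2), noise_cv = 0,
                          seed = 42)
  f <- dsa_frequencies(sim$dataset, made$markers)
  expect_lt(max(abs(unclass(f) - unclass(sim$truth$frequencies))), 1e-6)
})

test_that("DSA errors and warnings cover unusable markers and dead samples", {
  M <- matrix(c(3, 0, 5, 0), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("ok", "dead")))
  fx <- make_marker_dataset(M)
  expect_warning(f <- dsa_frequencies(fx$x, fx$markers), "all-zero")
  expect_true(all(is.na(unclass(f)[, "dead"])))
  bad_markers <- marker_sets(list(A = "mk_A", B = "missing_gene"))
  expect_error(dsa_frequencies(fx$x, bad_markers), "no usable marker")
  logx <- tiny_expression(unclass(fx$x$values), scale = "log2")
  expect_error(dsa_frequencies(logx, fx$markers), "linear")
})

test_that("signature NNLS reproduces exact mixtures and unit columns", {
  withr::local_seed(51)
  S <- signature_matrix(random_named_matrix(10, 2, prefix = c("g", "ct")))
  f_true <- c(0.5, 0.5)
  x1 <- as.matrix(S) %*% f_true
  x2 <- as.matrix(S)[, 1, drop = FALSE]
  vals <- cbind(x1, x2)
  colnames(vals) <- c("mix", "pure1")
  x <- tiny_expression(vals)
  f <- unclass(signature_nnls_frequencies(x, S))
  expect_equal(unname(f[, "mix"]), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(unname(f[, "pure1"]), c(1, 0), tolerance = 1e-8)
  # insufficient overlap
  small <- tiny_expression(vals[1:2, , drop = FALSE])
  expect_error(signature_nnls_frequencies(small, S), "overlap")
})

test_that("signature NNLS agrees with the quadrant grid-search oracle", {
  withr::local_seed(52)
  for (i in 1:20) {
    S <- matrix(runif(6, 0, 10), 3, 2,
                dimnames = list(paste0("g", 1:3), c("c1", "c2")))
    y <- runif(3, 0, 10)
    x <- tiny_expression(matrix(y, 3, 1, dimnames = list(paste0("g", 1:3), "s")))
    est <- unclass(signature_nnls_frequencies(x, signature_matrix(S),
                                              rescale = FALSE))[, 1]
    oracle <- grid_nnls_2d(S, y)
    expect_lt(max(abs(est - oracle)), 2e-3)
  }
})

test_that("permuting sample order permutes frequency columns identically", {
  made <- make_basis(120, c("A", "B", "C"), 4, 30, seed = 61)
  sim <- simulate_dataset(made$basis, NULL, 0, 12, c(A = 5, B = 3, C = 2),
                          noise_cv = 0.2, seed = 62)
  perm <- sample(colnames(sim$dataset$values))
  x_perm <- subset_expression(sim$dataset, samples = perm)
  f1 <- unclass(dsa_frequencies(sim$dataset, made$markers))
  f2 <- unclass(dsa_frequencies(x_perm, made$markers))
  expect_equal(f1[, perm], unclass(f2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cell component change computes Welch t and flags non-calculable types", {
  vals <- rbind(shifted = c(0.5, 0.6, 0.7, 0.3, 0.4, 0.5),
                same = c(0.2, 0.3, 0.25, 0.2, 0.3, 0.25),
                zero = rep(0, 6))
  colnames(vals) <- paste0("s", 1:6)
  fr <- frequency_matrix(vals)
  groups <- c(rep("case", 3), rep("control", 3))
  cc <- cell_component_change(fr, groups)
  expect_equal(cc$t[cc$cell_type == "shifted"], 2.449, tolerance = 1e-3)
  expect_equal(cc$t[cc$cell_type == "same"], 0, tolerance = 1e-9)
  expect_false(cc$calculable[cc$cell_type == "zero"])
  expect_true(is.na(cc$t[cc$cell_type == "zero"]))
  expect_error(cell_component_change(fr, c("case", rep("control", 5))),
               ">= 2")
})
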
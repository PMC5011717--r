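make_stats <- function(genes, p = NULL, log2fc = NULL, fdr = NULL) {
  n <- length(genes)
  tibble::tibble(gene = genes,
                 log2fc = log2fc %||% rep(1, n),
                 t = rep(1, n),
                 p = p %||% rep(0.5, n),
                 fdr = fdr %||% (p %||% rep(0.5, n)),
                 n_case = 5, n_control = 5)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("differential stats reproduce hand-computed Welch/BH values", {
  vals <- rbind(up = c(5, 6, 7, 1, 2, 3), flat = c(2, 3, 4, 2, 3, 4))
  colnames(vals) <- paste0("s", 1:6)
  x <- tiny_expression(vals, scale = "log2",
                       groups = rep(c("case", "control"), each = 3))
  st <- differential_stats(x)
  expect_equal(st$log2fc[st$gene == "up"], 4)
  expect_equal(st$t[st$gene == "up"], 4.899, tolerance = 1e-3)
  expect_equal(st$log2fc[st$gene == "flat"], 0)
  expect_equal(st$t[st$gene == "flat"], 0)
  # BH step-up on a known p triple
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_error(differential_stats(tiny_expression(
    vals[, 1:3], scale = "log2", groups = c("case", "case", "control"))),
    ">= 2")
})

test_that("informative gene pooling applies top-m and coverage rules", {
  genes <- c("A", "B", "C")
  stats_list <- list(
    d1 = make_stats(c("A", "B", "C"), p = c(0.001, 0.5, 0.6)),
    d2 = make_stats(c("B", "C"), p = c(0.001, 0.6)),
    d3 = make_stats(c("A", "C"), p = c(0.9, 0.001)))
  profiles <- fold_change_profiles(stats_list)
  # top 1 per dataset: A (d1), B (d2), C (d3); coverage > 2/3: A (2/3 fails?),
  # A measured in d1,d3 = 2/3 -> not > 2/3 at frac = 0.5? 2/3 > 0.5 yes.
  got <- select_informative_genes(profiles, stats_list, top_m = 1,
                                  min_coverage_frac = 0.5)
  expect_setequal(got, c("A", "B", "C"))
  # stricter coverage: only genes in all three datasets qualify
  got2 <- select_informative_genes(profiles, stats_list, top_m = 1,
                                   min_coverage_frac = 2 / 3)
  expect_equal(got2, "C")
  expect_error(select_informative_genes(profiles, stats_list["d1"], 1),
               ">= 2")
  # top_m covering everything returns all sufficiently covered genes
  got3 <- select_informative_genes(profiles, stats_list, top_m = 10,
                                   min_coverage_frac = 0.5)
  expect_setequal(got3, genes)
})

test_that("similarity matrix uses pairwise-complete Spearman with unit diagonal", {
  profiles <- cbind(d1 = c(1, 2, 3), d2 = c(3, 2, 1), d3 = c(2, 1, 3))
  rownames(profiles) <- paste0("g", 1:3)
  s <- similarity_matrix(profiles)
  expect_equal(diag(s), setNames(rep(1, 3), colnames(profiles)))
  expect_equal(s["d1", "d2"], -1)
  expect_equal(s["d1", "d3"], 0.5)
  # a pair with < 3 shared genes is missing
  profiles2 <- profiles
  profiles2[1:2, "d3"] <- NA
  s2 <- similarity_matrix(profiles2)
  expect_true(is.na(s2["d1", "d3"]))
})

test_that("complete-linkage clustering on 1 - correlation recovers planted pairs", {
  sim <- matrix(0.05, 4, 4, dimnames = list(paste0("d", 1:4), paste0("d", 1:4)))
  sim["d1", "d2"] <- sim["d2", "d1"] <- 0.95
  sim["d3", "d4"] <- sim["d4", "d3"] <- 0.9
  diag(sim) <- 1
  cl <- cluster_datasets(sim, k = 2)
  expect_equal(cl$labels[["d1"]], cl$labels[["d2"]])
  expect_equal(cl$labels[["d3"]], cl$labels[["d4"]])
  expect_false(cl$labels[["d1"]] == cl$labels[["d3"]])
  sim_na <- sim; sim_na["d1", "d3"] <- NA
  expect_error(cluster_datasets(sim_na, k = 2), "missing")
})

test_that("common-gene counts honour direction and thresholds", {
  stats_list <- list(
    d1 = make_stats(paste0("g", 1:10), fdr = c(rep(0.01, 3), rep(0.9, 7)),
                    log2fc = c(2, 2, -2, rep(0.1, 7))),
    d2 = make_stats(paste0("g", 1:10), fdr = c(rep(0.01, 3), rep(0.9, 7)),
                    log2fc = c(2, -2, -2, rep(0.1, 7))),
    d3 = make_stats(paste0("g", 1:10), fdr = c(0.01, rep(0.9, 9)),
                    log2fc = c(2, rep(0.1, 9))))
  res <- common_genes_fdr(stats_list, n_perm = 10, seed = 1, chosen_n = 3)
  th <- res$thresholds
  # g1 up in all 3; g3 down in d1 and d2 only
  expect_equal(th$observed[th$n == 3], 1L)
  expect_equal(res$up_set, "g1")
  expect_length(res$down_set, 0)
  # o_i is non-increasing in n
  expect_true(all(diff(th$observed) <= 0))
  expect_true(all(diff(th$perm_mean) <= 1e-9))
  # fdr missing where nothing observed
  res4 <- common_genes_fdr(stats_list[1:2], n_perm = 5, seed = 1)
  expect_error(common_genes_fdr(stats_list, n_perm = 0), "n_perm")
})

test_that("permutation null matches the closed-form overlap expectation", {
  stats_list <- list(
    d1 = make_stats(paste0("g", 1:10), fdr = c(rep(0.01, 3), rep(0.9, 7)),
                    log2fc = rep(2, 10)),
    d2 = make_stats(paste0("g", 1:10), fdr = c(rep(0.01, 3), rep(0.9, 7)),
                    log2fc = rep(2, 10)))
  res <- common_genes_fdr(stats_list, n_perm = 1000, seed = 7)
  th <- res$thresholds[res$thresholds$n == 2, ]
  # E[overlap] = 10 * (3/10)^2 = 0.9 for two independent 3-of-10 draws
  expect_lt(abs(th$perm_mean - 0.9), 3 * th$perm_se)
})

test_that("permutation FDR is conservative under a global null", {
  withr::local_seed(77)
  ok <- 0
  for (rep_i in 1:10) {
    stats_list <- lapply(1:2, function(d) {
      fdr <- rep(0.9, 300)
      fdr[sample(300, 60)] <- 0.01   # random 'DE' labels, no real signal
      make_stats(sprintf("g%03d", 1:300), fdr = fdr,
                 log2fc = rnorm(300))
    })
    names(stats_list) <- c("d1", "d2")
    res <- common_genes_fdr(stats_list, n_perm = 200,
                            seed = 1000 + rep_i)
    fdr2 <- res$thresholds$fdr[res$thresholds$n == 2]
    if (is.na(fdr2) || fdr2 >= 0.5) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("shared-shift datasets cluster by fold change and dissolve on residuals", {
  bench <- wb_benchmark(seed = 11, n_genes = 150, n_case = 10, n_control = 20,
                        markers_per_type = 8)
  datasets <- lapply(bench$collection, `[[`, "dataset")
  stats_raw <- lapply(datasets, differential_stats)
  profiles <- fold_change_profiles(stats_raw)
  genes <- select_informative_genes(profiles, stats_raw, top_m = 50)
  sim <- similarity_matrix(profiles, genes)
  shared_ds <- names(datasets)[sub("_d[0-9]+$", "", names(datasets)) %in%
                                 bench$shared_diseases]
  within <- sim[shared_ds, shared_ds][upper.tri(diag(length(shared_ds)))]
  stats_res <- lapply(datasets, function(x) {
    f <- dsa_frequencies(x, bench$markers)
    ctrl <- x$samples$sample_id[x$samples$group == "control"]
    B <- estimate_basis(x$values[, ctrl, drop = FALSE],
                        frequency_matrix(unclass(f)[, ctrl, drop = FALSE]))
    differential_stats(x, values = unclass(compute_residuals(x, f, B)))
  })
  profiles_res <- fold_change_profiles(stats_res)
  sim_res <- similarity_matrix(profiles_res, genes)
  within_res <- sim_res[shared_ds, shared_ds][upper.tri(diag(length(shared_ds)))]
  expect_gt(mean(within), mean(within_res) + 0.3)
})
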
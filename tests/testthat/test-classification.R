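toy_feature_matrix <- function() {
  # 3 features over 8 samples (4 case, 4 control) with |t| ranking f1 > f3 > f2
  z <- rbind(
    f1 = c(10, 10.1, 9.9, 10, 0, 0.1, -0.1, 0),
    f2 = c(0.2, -0.1, 0.1, 0, 0.1, 0, 0.2, -0.1),
    f3 = c(2, 2.2, 1.8, 2.1, 0.1, -0.2, 0.2, 0))
  colnames(z) <- paste0("s", 1:8)
  z
}

test_that("feature ranking follows |Welch t| with lexicographic tie-break", {
  z <- toy_feature_matrix()
  labels <- rep(c(TRUE, FALSE), each = 4)
  expect_equal(select_top_features(z, labels, 2), c("f1", "f3"))
  expect_equal(select_top_features(z, labels, 10), c("f1", "f3", "f2"))
  # exact duplicates tie and resolve by id, stably
  z2 <- rbind(aa = z["f1", ], bb = z["f1", ], cc = z["f2", ])
  colnames(z2) <- colnames(z)
  expect_equal(select_top_features(z2, labels, 2), c("aa", "bb"))
  expect_error(select_top_features(z, rep(TRUE, 8), 1), "both classes")
})

test_that("a separable problem trains to confident training posteriors", {
  withr::local_seed(101)
  n <- 40
  z <- rbind(signal = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
             noise = rnorm(n))
  colnames(z) <- paste0("s", 1:n)
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  br <- train_branch(z, labels, n_top = 2, inner_folds = 5, seed = 1,
                     lambda_rule = "min")
  p <- predict_posterior(br, z)
  expect_true(all(p[labels] > 0.5))
  expect_true(all(p[!labels] < 0.5))
  # same data and seed select the same hyperparameters
  br2 <- train_branch(z, labels, n_top = 2, inner_folds = 5, seed = 1,
                      lambda_rule = "min")
  expect_identical(c(br$alpha, br$lambda), c(br2$alpha, br2$lambda))
})

test_that("uninformative features give posteriors near the weighted prior", {
  withr::local_seed(102)
  z <- matrix(rep(1, 30), 1, dimnames = list("flat", paste0("s", 1:30)))
  labels <- rep(c(TRUE, FALSE), times = c(10, 20))
  br <- train_branch(z, labels, inner_folds = 5, seed = 2)
  p <- predict_posterior(br, z)
  # inverse-prevalence weights centre the intercept near 0.5
  expect_true(all(abs(p - 0.5) < 0.05))
})

test_that("posterior prediction is monotone and strict about missing features", {
  withr::local_seed(103)
  z <- rbind(up = c(rnorm(10, 2), rnorm(10, -2)), other = rnorm(20))
  colnames(z) <- paste0("s", 1:20)
  labels <- rep(c(TRUE, FALSE), each = 10)
  br <- train_branch(z, labels, inner_folds = 5, seed = 3)
  z_new <- z[, 1:2]
  z_more <- z_new
  z_more["up", ] <- z_more["up", ] + 1
  expect_true(all(predict_posterior(br, z_more) >=
                    predict_posterior(br, z_new) - 1e-12))
  expect_error(predict_posterior(br, z_new["other", , drop = FALSE]),
               "missing")
})

test_that("posterior product combines element-wise with absorbing zero", {
  expect_equal(combine_posteriors(c(0.8, 0.5), c(0.5, 0.8)), c(0.4, 0.4))
  expect_equal(combine_posteriors(c(0.3, 0.9), c(1, 1)), c(0.3, 0.9))
  expect_equal(combine_posteriors(c(0, 0.9), c(0.7, 0)), c(0, 0))
  expect_error(combine_posteriors(c(0.5), c(0.5, 0.5)), "length")
  expect_error(combine_posteriors(c(1.2), c(0.5)), "\\[0, 1\\]")
})

test_that("AUC follows the Mann-Whitney formulation with half-credit ties", {
  expect_equal(auc_score(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)), 0.75)
  expect_equal(auc_score(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_score(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_score(1:3, rep(TRUE, 3)), "both classes")
})

test_that("robust gene lists require a strict majority", {
  runs <- c(replicate(6, c("g1", "g2"), simplify = FALSE),
            replicate(4, c("g2", "g3"), simplify = FALSE))
  out <- robust_gene_list(runs)
  expect_equal(out$gene, c("g2", "g1"))  # g2 in 10/10, g1 in 6/10
  expect_false("g3" %in% out$gene)       # 4/10
  # exactly half is excluded
  runs5 <- c(replicate(5, "a", simplify = FALSE),
             replicate(5, "b", simplify = FALSE))
  expect_equal(nrow(robust_gene_list(runs5)), 0)
  expect_error(robust_gene_list(runs[1]), ">= 2")
})

test_that("oracle scoring yields AUC 1 and passes the leakage audit", {
  bench <- wb_benchmark(seed = 3, n_genes = 80, n_case = 6, n_control = 8,
                        markers_per_type = 5, n_de_genes = 4)
  ev <- evaluate_disease_specific(bench$collection, "sepsisB", bench$markers,
                                  features = c("residual", "cell_component",
                                               "combined"),
                                  outer_repeats = 2, seed = 5,
                                  classifier = "oracle")
  expect_equal(unique(ev$rounds$auc), 1)
  expect_true(audit_leakage(ev, bench$collection))
  # every round keeps param-fitting and scored samples disjoint
  roles <- ev$audit |>
    dplyr::group_by(repeat_, held_out, fold, sample_id) |>
    dplyr::summarise(both = all(c("param_fit", "test") %in% role),
                     .groups = "drop")
  expect_false(any(roles$both))
  expect_error(
    evaluate_disease_specific(bench$collection, "unknown_disease",
                              bench$markers),
    ">= 2 datasets")
})

test_that("fitted evaluation reports rounds, tidies and summarises", {
  bench <- wb_benchmark(seed = 4, n_genes = 80, n_case = 6, n_control = 10,
                        markers_per_type = 5, n_de_genes = 4)
  ev <- evaluate_disease_specific(bench$collection, "sepsisA", bench$markers,
                                  features = c("residual", "cell_component",
                                               "combined"),
                                  n_top = 10, inner_folds = 4,
                                  outer_folds = 3, outer_repeats = 1, seed = 6)
  expect_setequal(unique(ev$rounds$config),
                  c("residual", "cell_component", "combined"))
  expect_true(all(ev$rounds$auc >= 0 & ev$rounds$auc <= 1))
  expect_true(audit_leakage(ev, bench$collection))
  expect_s3_class(tidy(ev), "tbl_df")
  g <- glance(ev)
  expect_true(all(c("auc_residual", "auc_combined") %in% names(g)))
  expect_s3_class(autoplot(ev), "ggplot")
})
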
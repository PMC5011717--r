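# Disease-specific classification. One disease is classified against all other
# samples (other diseases' cases and all controls). Features come in three
# spaces — original expression, residual profiles and cell components — each
# control-anchored Z-transformed per dataset. Branches are penalized logistic
# regressions (elastic net, inner-CV tuned); two branches can be combined by
# multiplying posteriors. The evaluation schema guarantees positive test
# samples never share a dataset with positive training samples, and rotates a
# 9/10 parameter-fitting split over the held-out dataset so that Z-parameters
# and basis estimates never touch a scored test sample.

#' Rank features by absolute Welch t
#'
#' Features are ranked by `|t|` (case vs rest) descending; ties (and
#' non-calculable statistics) are broken by feature id lexicographic order.
#'
#' @param z feature-by-sample matrix (already Z-transformed).
#' @param labels logical (or 0/1) vector over samples; `TRUE` = positive.
#' @param n_top number of features to return (capped at the number
#'   available).
#' @return Character vector of feature ids, best first.
#' @export
select_top_features <- function(z, labels, n_top) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present for feature selection", call. = FALSE)
  }
  if (n_top < 1) stop("n_top must be >= 1", call. = FALSE)
  stats <- row_welch_t(z, labels)
  key <- abs(stats$t)
  key[is.na(key)] <- -Inf
  ord <- order(-key, stats$feature)
  stats$feature[ord][seq_len(min(n_top, nrow(z)))]
}

#' Train one elastic-net classifier branch
#'
#' Selects the top `n_top` features by `|Welch t|`, then fits penalized
#' logistic regression over a grid of penalty mixes (`alpha_grid`) and a
#' log-spaced regularization path, choosing the pair maximizing mean
#' inner-CV AUC on seeded stratified folds. Class imbalance is handled by
#' inverse-prevalence sample weights.
#'
#' @param z feature-by-sample matrix (Z-transformed).
#' @param labels logical vector over samples; `TRUE` = positive.
#' @param n_top features entering the model (default: all).
#' @param inner_folds inner cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @param alpha_grid penalty mix grid (0 = ridge, 1 = lasso).
#' @param balance_weights use inverse-prevalence sample weights.
#' @param nlambda length of the regularization path.
#' @param lambda_rule `"1se"` (default): the largest lambda whose inner-CV
#'   AUC is within one Hanley-McNeil standard error of the maximum — the
#'   standard parsimony rule, which also keeps posteriors conservative for
#'   downstream posterior-product combination; `"min"`: the AUC-maximizing
#'   lambda.
#' @return A `wb_branch`: list with the fitted `glmnet` path, chosen `alpha`,
#'   `lambda`, `features`, inner-CV AUC and the nonzero-coefficient feature
#'   ids.
#' @export
train_branch <- function(z, labels, n_top = nrow(z), inner_folds = 10,
                         seed = 1, alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                         balance_weights = TRUE, nlambda = 20,
                         lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("single-class labels", call. = FALSE)
  features <- select_top_features(z, labels, n_top)
  x <- t(z[features, , drop = FALSE])
  if (ncol(x) == 1) {
    # glmnet requires >= 2 columns; pad with a constant-zero pseudo-feature
    x <- cbind(x, `.zero_pad` = 0)
  }
  y <- factor(labels, levels = c(FALSE, TRUE))
  w <- if (balance_weights) {
    ifelse(labels, length(labels) / (2 * n_pos), length(labels) / (2 * n_neg))
  } else rep(1, length(labels))

  k <- min(inner_folds, n_pos, n_neg)
  if (k < 2) stop("cannot stratify inner folds: a class has < 2 samples",
                  call. = FALSE)
  withr::local_seed(seed)
  foldid <- stratified_folds(labels, k)

  if (all(apply(x, 2, var) == 0)) {
    # no usable signal at all: intercept-only model at the (weighted) prior
    prior <- sum(w * labels) / sum(w)
    return(structure(list(model = NULL, alpha = NA_real_, lambda = NA_real_,
                          features = features, cv_auc = 0.5,
                          intercept = stats::qlogis(prior),
                          nonzero = character(0),
                          n_pos = n_pos, n_neg = n_neg),
                     class = "wb_branch"))
  }

  best <- list(cvm = -Inf)
  for (a in alpha_grid) {
    # prevalidated inner-CV AUC: each sample is scored by the model of the
    # fold that excluded it, then one pooled AUC per lambda
    cvfit <- withCallingHandlers(
      glmnet::cv.glmnet(x, y, family = "binomial", weights = w,
                        foldid = foldid, alpha = a,
                        type.measure = "deviance", standardize = FALSE,
                        nlambda = nlambda, lambda.min.ratio = 0.01,
                        keep = TRUE),
      warning = function(w_) {
        # small stratified folds are expected in scaled-down runs
        if (grepl("fewer than 8\\s+observations", conditionMessage(w_))) {
          invokeRestart("muffleWarning")
        }
      })
    preval <- cvfit$fit.preval[, seq_along(cvfit$lambda), drop = FALSE]
    cv_auc <- apply(preval, 2, auc_score, labels = labels)
    # AUC is scale-free, so whole stretches of the path tie; break AUC ties
    # by CV deviance, which is calibration-sensitive
    dev <- cvfit$cvm[seq_along(cv_auc)]
    i_max <- order(-cv_auc, dev)[1]
    i <- if (lambda_rule == "1se") {
      # largest lambda (lambda is decreasing along the path) within one
      # Hanley-McNeil SE of the best AUC
      min(which(cv_auc >= cv_auc[i_max] - auc_se(cv_auc[i_max], n_pos, n_neg)))
    } else i_max
    if (cv_auc[i] > best$cvm + 1e-12) {
      best <- list(cvm = cv_auc[i], alpha = a,
                   lambda = cvfit$lambda[i], fit = cvfit$glmnet.fit)
    }
  }
  coefs <- as.matrix(predict(best$fit, s = best$lambda, type = "coefficients"))
  nonzero <- setdiff(rownames(coefs)[coefs[, 1] != 0],
                     c("(Intercept)", ".zero_pad"))
  structure(list(model = best$fit, alpha = best$alpha, lambda = best$lambda,
                 features = features, cv_auc = best$cvm, nonzero = nonzero,
                 n_pos = n_pos, n_neg = n_neg),
            class = "wb_branch")
}

#' @export
print.wb_branch <- function(x, ...) {
  cat(sprintf("<wb_branch> %d features (alpha %.2f, lambda %.4g, inner-CV AUC %.3f, %d nonzero)\n",
              length(x$features), x$alpha, x$lambda, x$cv_auc,
              length(x$nonzero)))
  invisible(x)
}

#' Posterior probabilities from a fitted branch
#'
#' @param branch a `wb_branch`.
#' @param z_new feature-by-sample matrix containing all branch features.
#' @return Named numeric vector of per-sample probabilities in (0, 1).
#' @export
predict_posterior <- function(branch, z_new) {
  stopifnot(inherits(branch, "wb_branch"))
  missing_feat <- setdiff(branch$features, rownames(z_new))
  if (length(missing_feat)) {
    stop("feature(s) missing from new data: ",
         paste(head(missing_feat, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(branch$model)) {
    p <- rep(stats::plogis(branch$intercept), ncol(z_new))
    return(setNames(p, colnames(z_new)))
  }
  x <- t(z_new[branch$features, , drop = FALSE])
  if (ncol(x) == 1) x <- cbind(x, `.zero_pad` = 0)
  p <- predict(branch$model, newx = x, s = branch$lambda, type = "response")
  setNames(as.numeric(p), colnames(z_new))
}

#' Combine two posterior vectors by element-wise product
#'
#' @param p_a,p_b equal-length probability vectors in `[0, 1]`.
#' @return Element-wise product.
#' @export
combine_posteriors <- function(p_a, p_b) {
  if (length(p_a) != length(p_b)) stop("length mismatch", call. = FALSE)
  if (any(p_a < 0 | p_a > 1 | p_b < 0 | p_b > 1, na.rm = TRUE)) {
    stop("posteriors must lie in [0, 1]", call. = FALSE)
  }
  p_a * p_b
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Ties contribute 1/2 via average ranks.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Robust gene list over repeated classifier fits
#'
#' Genes with a nonzero coefficient in strictly more than half of the runs,
#' sorted by selection frequency (descending) then gene id.
#'
#' @param runs list of `wb_branch` objects, or list of character vectors of
#'   nonzero-coefficient feature ids.
#' @return A tibble with columns `gene`, `n_selected`, `frequency`.
#' @export
robust_gene_list <- function(runs) {
  if (length(runs) < 2) stop("need >= 2 runs", call. = FALSE)
  sel <- lapply(runs, function(r) if (inherits(r, "wb_branch")) r$nonzero else
    as.character(r))
  counts <- table(unlist(sel))
  keep <- counts > length(runs) / 2
  out <- tibble::tibble(gene = names(counts)[keep],
                        n_selected = as.integer(counts[keep]),
                        frequency = as.numeric(counts[keep]) / length(runs))
  out[order(-out$n_selected, out$gene), ]
}

# ---- Evaluation schema ------------------------------------------------------

# Build the three per-dataset feature spaces for one round, given the ids of
# the Z/basis-fitting controls of every dataset. Returns feature-by-sample
# matrices over all samples of all datasets (genes restricted to features
# retained in every dataset).
build_round_features <- function(datasets, freqs, fit_controls, features) {
  per_space <- list()
  if ("original" %in% features) {
    mats <- lapply(names(datasets), function(d) {
      logm <- log2(datasets[[d]]$values + 1)
      zp <- fit_z_params(logm, fit_controls[[d]], source = d)
      apply_z(logm, zp)
    })
    per_space$original <- bind_feature_mats(mats)
  }
  if ("residual" %in% features) {
    mats <- lapply(names(datasets), function(d) {
      xs <- datasets[[d]]$values
      Fd <- freqs[[d]]
      B <- estimate_basis(xs[, fit_controls[[d]], drop = FALSE],
                          frequency_matrix(unclass(Fd)[, fit_controls[[d]], drop = FALSE]))
      R <- unclass(compute_residuals(xs, Fd, B))
      zp <- fit_z_params(R, fit_controls[[d]], source = d)
      apply_z(R, zp)
    })
    per_space$residual <- bind_feature_mats(mats)
  }
  if ("cell_component" %in% features) {
    mats <- lapply(names(datasets), function(d) {
      Fd <- unclass(freqs[[d]])
      zp <- fit_z_params(Fd, fit_controls[[d]], source = d)
      apply_z(Fd, zp)
    })
    per_space$cell_component <- bind_feature_mats(mats)
  }
  per_space
}

bind_feature_mats <- function(mats) {
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) == 0) stop("no shared features across datasets", call. = FALSE)
  do.call(cbind, lapply(mats, function(m) m[shared, , drop = FALSE]))
}

#' Evaluate disease-specific classifiers with independent-dataset validation
#'
#' For each dataset carrying the target disease, that dataset is held out:
#' its case samples are the only positive test samples and the other
#' dataset(s) of the disease supply the positive training samples, so positive
#' train and test samples never share a dataset. The held-out dataset rotates
#' a 10-sub-fold split: in each round 9/10 of its samples serve only to fit
#' the feature-generation parameters (Z mean/SD and the cell-type basis, from
#' its controls) and the remaining 1/10 are scored. All other datasets'
#' samples (other diseases' cases plus every dataset's controls) are split by
#' stratified 10-fold CV between training and test negatives, aligned with
#' the rotation. Per-round AUC is recorded per feature configuration
#' (`original`, `residual`, `cell_component`, and `combined` =
#' residual-posterior x cell-component-posterior); the whole schema is
#' repeated `outer_repeats` times with distinct derived seeds.
#'
#' @param collection named list of annotated linear-scale `wb_expression`
#'   datasets, or of `simulate_dataset()` results.
#' @param disease target disease name (>= 2 datasets must carry it).
#' @param markers [marker_sets()] used for DSA frequency estimation.
#' @param features subset of
#'   `c("original", "residual", "cell_component", "combined")`.
#' @param n_top features per expression-space branch (the cell-component
#'   branch always uses all cell types).
#' @param inner_folds,alpha_grid,balance_weights passed to [train_branch()].
#' @param outer_folds sub-folds of the rotation (and the negative CV).
#' @param outer_repeats independent repetitions of the full schema.
#' @param seed master seed.
#' @param classifier `"glmnet"`, or `"oracle"` (score = true positive
#'   indicator; a plumbing check, no model is fitted).
#' @return A `wb_evaluation`: list with `rounds` (tibble: repeat_, held_out,
#'   fold, config, auc, n_test_pos, n_test_neg), `mean_auc` (tibble),
#'   `audit` (tibble of per-round sample roles), `selected` (per-round
#'   nonzero features of the residual branch) and the call parameters.
#' @export
evaluate_disease_specific <- function(collection, disease, markers,
                                      features = c("original", "residual",
                                                   "cell_component", "combined"),
                                      n_top = 25, inner_folds = 10,
                                      alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                                      balance_weights = TRUE,
                                      outer_folds = 10, outer_repeats = 10,
                                      seed = 1, classifier = c("glmnet", "oracle")) {
  classifier <- match.arg(classifier)
  features <- match.arg(features, several.ok = TRUE)
  datasets <- lapply(collection, function(el) {
    if (inherits(el, "wb_expression")) el else el$dataset
  })
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, function(d) d$samples$dataset_id[1],
                              character(1))
  }
  spaces <- setdiff(features, "combined")
  if ("combined" %in% features) {
    spaces <- union(spaces, c("residual", "cell_component"))
  }

  ann <- dplyr::bind_rows(lapply(datasets, function(d) d$samples))
  pos_datasets <- unique(ann$dataset_id[ann$group == "case" &
                                          !is.na(ann$disease) &
                                          ann$disease == disease])
  if (length(pos_datasets) < 2) {
    stop("disease '", disease, "' needs >= 2 datasets in the collection",
         call. = FALSE)
  }

  freqs <- lapply(datasets, dsa_frequencies, markers = markers)

  rounds <- list(); audit <- list(); selected <- list()
  for (r in seq_len(outer_repeats)) {
    rep_seed <- (seed + 104729L * r) %% .Machine$integer.max
    for (D in pos_datasets) {
      withr::local_seed((rep_seed + match(D, pos_datasets)) %% .Machine$integer.max)
      ann_D <- datasets[[D]]$samples
      fold_D <- stratified_folds(ann_D$group, outer_folds)
      # negative pool: every sample of every other dataset except positive
      # cases of the target disease (those are training positives throughout)
      neg_pool <- ann[ann$dataset_id != D &
                        !(ann$group == "case" & !is.na(ann$disease) &
                            ann$disease == disease), , drop = FALSE]
      fold_neg <- stratified_folds(paste(neg_pool$dataset_id, neg_pool$group),
                                   outer_folds)
      train_pos_ids <- ann$sample_id[ann$dataset_id != D & ann$group == "case" &
                                       !is.na(ann$disease) & ann$disease == disease]

      for (f in seq_len(outer_folds)) {
        test_D_ids <- ann_D$sample_id[fold_D == f]
        param_D_ids <- ann_D$sample_id[fold_D != f]
        test_neg_ids <- neg_pool$sample_id[fold_neg == f]
        train_neg_ids <- neg_pool$sample_id[fold_neg != f]

        fit_controls <- lapply(names(datasets), function(d) {
          a <- datasets[[d]]$samples
          if (d == D) {
            intersect(param_D_ids, a$sample_id[a$group == "control"])
          } else {
            intersect(train_neg_ids, a$sample_id[a$group == "control"])
          }
        })
        names(fit_controls) <- names(datasets)
        if (any(lengths(fit_controls) < 2)) {
          stop("a dataset has < 2 feature-fitting controls in a round",
               call. = FALSE)
        }

        train_ids <- c(train_pos_ids, train_neg_ids)
        test_ids <- c(test_D_ids, test_neg_ids)
        stopifnot(length(intersect(test_ids, train_ids)) == 0)
        is_pos_train <- c(rep(TRUE, length(train_pos_ids)),
                          rep(FALSE, length(train_neg_ids)))
        test_is_case <- ann$group[match(test_ids, ann$sample_id)] == "case" &
          !is.na(ann$disease[match(test_ids, ann$sample_id)]) &
          ann$disease[match(test_ids, ann$sample_id)] == disease
        if (!any(test_is_case) || all(test_is_case)) next  # AUC undefined

        audit[[length(audit) + 1]] <- tibble::tibble(
          repeat_ = r, held_out = D, fold = f,
          sample_id = c(train_ids, test_ids, param_D_ids),
          role = c(rep("train", length(train_ids)),
                   rep("test", length(test_ids)),
                   rep("param_fit", length(param_D_ids))))

        posteriors <- list()
        if (classifier == "oracle") {
          for (sp in spaces) posteriors[[sp]] <- as.numeric(test_is_case)
        } else {
          feat_mats <- build_round_features(datasets, freqs, fit_controls,
                                            spaces)
          for (sp in spaces) {
            z <- feat_mats[[sp]]
            ntop_sp <- if (sp == "cell_component") nrow(z) else n_top
            branch <- train_branch(z[, train_ids, drop = FALSE], is_pos_train,
                                   n_top = ntop_sp, inner_folds = inner_folds,
                                   seed = (rep_seed + 13L * f) %% .Machine$integer.max,
                                   alpha_grid = alpha_grid,
                                   balance_weights = balance_weights)
            posteriors[[sp]] <- predict_posterior(branch,
                                                  z[, test_ids, drop = FALSE])
            if (sp == "residual") {
              selected[[length(selected) + 1]] <- branch$nonzero
            }
          }
        }
        if ("combined" %in% features) {
          posteriors$combined <- combine_posteriors(posteriors$residual,
                                                    posteriors$cell_component)
        }
        for (cfg in features) {
          rounds[[length(rounds) + 1]] <- tibble::tibble(
            repeat_ = r, held_out = D, fold = f, config = cfg,
            auc = auc_score(posteriors[[cfg]], test_is_case),
            n_test_pos = sum(test_is_case),
            n_test_neg = sum(!test_is_case))
        }
      }
    }
  }
  rounds <- dplyr::bind_rows(rounds)
  audit <- dplyr::bind_rows(audit)
  mean_auc <- rounds |>
    dplyr::group_by(.data$config) |>
    dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
                     n_rounds = dplyr::n(), .groups = "drop")
  structure(list(disease = disease, rounds = rounds, mean_auc = mean_auc,
                 audit = audit, selected = selected, n_top = n_top,
                 outer_repeats = outer_repeats, seed = seed),
            class = "wb_evaluation")
}

#' @export
print.wb_evaluation <- function(x, ...) {
  cat(sprintf("<wb_evaluation> disease '%s', %d rounds x %d configs\n",
              x$disease, length(unique(paste(x$rounds$repeat_, x$rounds$held_out,
                                             x$rounds$fold))),
              length(unique(x$rounds$config))))
  print(x$mean_auc)
  invisible(x)
}

#' Audit an evaluation for information leakage
#'
#' Checks that no sample ever holds both the `param_fit` and `test` role in
#' the same round, and that no positive test sample shares a `dataset_id`
#' with a positive training sample.
#'
#' @param evaluation a `wb_evaluation`.
#' @param collection the collection it was computed from.
#' @return `TRUE` invisibly; stops with a description on violation.
#' @export
audit_leakage <- function(evaluation, collection) {
  datasets <- lapply(collection, function(el) {
    if (inherits(el, "wb_expression")) el else el$dataset
  })
  ann <- dplyr::bind_rows(lapply(datasets, function(d) d$samples))
  aud <- dplyr::left_join(evaluation$audit, ann, by = "sample_id")
  overlap <- aud |>
    dplyr::group_by(.data$repeat_, .data$held_out, .data$fold, .data$sample_id) |>
    dplyr::summarise(bad = "param_fit" %in% .data$role & "test" %in% .data$role,
                     .groups = "drop")
  if (any(overlap$bad)) {
    stop("leakage: sample(s) in both param_fit and test roles of one round",
         call. = FALSE)
  }
  pos <- aud[aud$group == "case" & !is.na(aud$disease) &
               aud$disease == evaluation$disease, , drop = FALSE]
  shared <- pos |>
    dplyr::filter(.data$role %in% c("train", "test")) |>
    dplyr::distinct(.data$repeat_, .data$held_out, .data$fold,
                    .data$dataset_id, .data$role) |>
    dplyr::group_by(.data$repeat_, .data$held_out, .data$fold,
                    .data$dataset_id) |>
    dplyr::summarise(bad = dplyr::n_distinct(.data$role) > 1, .groups = "drop")
  if (any(shared$bad)) {
    stop("leakage: positive train and test samples share a dataset",
         call. = FALSE)
  }
  invisible(TRUE)
}
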
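# Synthetic whole-blood cohort simulator. Generates multi-dataset,
# multi-disease expression collections from a known cell-type basis, Dirichlet
# cell frequencies, disease-specific cell-type-restricted fold changes, a
# shared myeloid-up/lymphoid-down frequency shift, multiplicative log-normal
# measurement noise and dataset-level gene-wise batch scaling — the structural
# features the downstream pipeline claims to handle, each controlled by a
# ground-truth object so recovery can be tested.

#' Specify a simulated disease
#'
#' @param name disease name.
#' @param freq_shift named numeric vector of per-cell-type additive shifts
#'   applied to the Dirichlet concentration weights (`alpha_k <-
#'   alpha_k * (1 + shift_k)`, floored at 0.01); cell types not named shift by
#'   0. Positive values enrich the cell type in cases.
#' @param de_effects tibble/data.frame with columns `cell_type`, `gene`,
#'   `fold` (> 0): multiplicative fold applied to the basis entry of `gene` in
#'   `cell_type` for case samples only.
#' @return A `wb_disease_spec` object.
#' @export
disease_spec <- function(name, freq_shift = NULL, de_effects = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (is.null(freq_shift)) freq_shift <- numeric(0)
  if (is.null(de_effects)) {
    de_effects <- tibble::tibble(cell_type = character(),
                                 gene = character(), fold = numeric())
  } else {
    de_effects <- tibble::as_tibble(de_effects)
    stopifnot(all(c("cell_type", "gene", "fold") %in% names(de_effects)))
    if (any(de_effects$fold <= 0)) stop("de_effects fold must be > 0", call. = FALSE)
  }
  structure(list(name = name, freq_shift = freq_shift, de_effects = de_effects),
            class = "wb_disease_spec")
}

#' Simulate a cell-type basis matrix with exclusive marker genes
#'
#' Background entries are log-normal on the linear scale (`meanlog = 3`,
#' `sdlog = 0.5` by default, i.e. typical intensities around 20 with
#' right-skew, as on a linear-scale microarray). Disjoint marker genes are
#' drawn per cell type and their own-type entry is multiplied by
#' `marker_fold`, guaranteeing the marker is the row maximum in its own cell
#' type. With `pure_markers = TRUE`, marker expression outside the own cell
#' type is set to zero (perfectly exclusive markers, as assumed by exact
#' marker-based deconvolution).
#'
#' @param n_genes total number of genes.
#' @param cell_types character vector of cell-type names.
#' @param markers_per_type number of exclusive markers per cell type.
#' @param marker_fold fold applied to the own-type marker entry; must be > 1.
#' @param seed integer seed; same arguments and seed give identical output.
#' @param meanlog,sdlog background log-normal parameters.
#' @param pure_markers zero marker expression outside the own cell type.
#' @return A list with `basis` ([basis_matrix()]) and `markers`
#'   ([marker_sets()]).
#' @export
make_basis <- function(n_genes, cell_types, markers_per_type, marker_fold,
                       seed, meanlog = 3, sdlog = 0.5, pure_markers = FALSE) {
  K <- length(cell_types)
  if (markers_per_type * K > n_genes) {
    stop("markers_per_type * |cell_types| exceeds n_genes", call. = FALSE)
  }
  if (marker_fold <= 1) stop("marker_fold must be > 1", call. = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  withr::local_seed(seed)
  B <- matrix(rlnorm(n_genes * K, meanlog, sdlog), n_genes, K,
              dimnames = list(genes, cell_types))
  marker_idx <- matrix(sample(n_genes, markers_per_type * K), ncol = K)
  markers <- list()
  for (k in seq_len(K)) {
    idx <- marker_idx[, k]
    if (pure_markers) B[idx, -k] <- 0
    B[idx, k] <- B[idx, k] * marker_fold
    # construction guarantee: own-type entry is the row maximum
    other_max <- apply(B[idx, -k, drop = FALSE], 1, max)
    low <- B[idx, k] <= other_max
    if (any(low)) B[idx[low], k] <- marker_fold * pmax(other_max[low], 1e-8)
    markers[[cell_types[k]]] <- genes[sort(idx)]
  }
  list(basis = basis_matrix(B), markers = marker_sets(markers))
}

shift_alpha <- function(alpha, freq_shift) {
  shift <- setNames(rep(0, length(alpha)), names(alpha))
  unknown <- setdiff(names(freq_shift), names(alpha))
  if (length(unknown)) {
    stop("freq_shift names not in cell types: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  shift[names(freq_shift)] <- freq_shift
  pmax(alpha * (1 + shift), 0.01)
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(rgamma(n * K, shape = alpha), nrow = K)
  sweep(g, 2, colSums(g), "/")
}

apply_de_effects <- function(basis, de_effects) {
  B <- unclass(basis)
  for (i in seq_len(nrow(de_effects))) {
    g <- de_effects$gene[i]; ct <- de_effects$cell_type[i]
    if (!g %in% rownames(B) || !ct %in% colnames(B)) {
      stop("de_effect refers to unknown gene or cell type: ", g, "/", ct,
           call. = FALSE)
    }
    B[g, ct] <- B[g, ct] * de_effects$fold[i]
  }
  basis_matrix(B)
}

#' Simulate one case/control dataset from a cell-type basis
#'
#' Per sample, a frequency column is drawn from `Dirichlet(alpha)` (cases:
#' alpha re-weighted by the disease's `freq_shift`); case samples mix through
#' a disease basis with the disease's cell-type-restricted fold changes
#' applied; expression is `basis %*% f` times multiplicative log-normal noise
#' with coefficient of variation `noise_cv` (unit mean), times one
#' dataset-level gene-wise batch factor `exp(N(0, batch_scale_sd^2))` shared by
#' all samples.
#'
#' @param basis healthy [basis_matrix()].
#' @param spec a [disease_spec()] or `NULL` (no case/control difference beyond
#'   sampling noise).
#' @param n_case,n_control group sizes (>= 0).
#' @param dirichlet_alpha named positive concentration vector over the basis'
#'   cell types.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param batch_scale_sd SD of the log batch factor (>= 0).
#' @param seed integer seed.
#' @param dataset_id dataset identifier used in sample annotations.
#' @param frequencies optional fixed cell-type x sample frequency matrix
#'   (columns on the simplex) overriding the Dirichlet draw; useful for
#'   noiseless identity checks.
#' @return A list with `dataset` (linear-scale [expression_dataset()]) and
#'   `truth` (list: `basis`, `disease_basis`, `frequencies` true
#'   [frequency_matrix()], `de_gene_flags` tibble of truly perturbed
#'   (gene, cell_type) pairs, `batch_factor`).
#' @export
simulate_dataset <- function(basis, spec, n_case, n_control, dirichlet_alpha,
                             noise_cv = 0.2, batch_scale_sd = 0, seed = 1,
                             dataset_id = "ds1", frequencies = NULL) {
  stopifnot(inherits(basis, "wb_basis"))
  if (n_case < 0 || n_control < 0) stop("group sizes must be >= 0", call. = FALSE)
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be > 0", call. = FALSE)
  cell_types <- colnames(basis)
  if (is.null(names(dirichlet_alpha))) names(dirichlet_alpha) <- cell_types
  stopifnot(setequal(names(dirichlet_alpha), cell_types))
  dirichlet_alpha <- dirichlet_alpha[cell_types]
  n <- n_case + n_control
  sample_ids <- sprintf("%s_s%03d", dataset_id, seq_len(n))
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))

  withr::local_seed(seed)
  if (is.null(frequencies)) {
    Fm <- matrix(0, length(cell_types), n)
    if (n_control > 0) {
      Fm[, !is_case] <- rdirichlet(n_control, dirichlet_alpha)
    }
    if (n_case > 0) {
      alpha_case <- if (is.null(spec)) dirichlet_alpha else
        shift_alpha(dirichlet_alpha, spec$freq_shift)
      Fm[, is_case] <- rdirichlet(n_case, alpha_case)
    }
  } else {
    Fm <- as.matrix(frequencies)[cell_types, , drop = FALSE]
    if (ncol(Fm) == 1) Fm <- Fm[, rep(1, n), drop = FALSE]
    stopifnot(ncol(Fm) == n)
  }
  dimnames(Fm) <- list(cell_types, sample_ids)

  disease_basis <- if (is.null(spec) || nrow(spec$de_effects) == 0) basis
  else apply_de_effects(basis, spec$de_effects)

  X <- matrix(0, nrow(basis), n, dimnames = list(rownames(basis), sample_ids))
  X[, !is_case] <- unclass(basis) %*% Fm[, !is_case, drop = FALSE]
  if (n_case > 0) {
    X[, is_case] <- unclass(disease_basis) %*% Fm[, is_case, drop = FALSE]
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    X <- X * matrix(rlnorm(length(X), -sdlog^2 / 2, sdlog), nrow(X))
  }
  batch <- rep(1, nrow(basis))
  if (batch_scale_sd > 0) {
    batch <- exp(rnorm(nrow(basis), 0, batch_scale_sd))
    X <- X * batch
  }

  ann <- tibble::tibble(
    sample_id = sample_ids,
    dataset_id = dataset_id,
    group = ifelse(is_case, "case", "control"),
    disease = ifelse(is_case & !is.null(spec), spec$name %||% NA_character_,
                     NA_character_))
  de_flags <- if (is.null(spec)) tibble::tibble(gene = character(),
                                                cell_type = character())
  else spec$de_effects[, c("gene", "cell_type")]

  list(dataset = expression_dataset(X, scale = "linear", annotations = ann),
       truth = list(basis = basis, disease_basis = disease_basis,
                    frequencies = frequency_matrix(Fm, sum_to_one = is.null(frequencies)),
                    de_gene_flags = de_flags, batch_factor = batch))
}

#' Simulate a multi-dataset, multi-disease collection
#'
#' Emulates a meta-analysis collection: several diseases, each observed in
#' two or more independent datasets with their own controls and batch
#' effects, and a frequency shift shared by a declared subset of diseases
#' (the common myeloid-up/lymphoid-down pattern). Shared-subset diseases get
#' `freq_shift = shared_shift + own shift`.
#'
#' @param basis healthy [basis_matrix()].
#' @param specs named list of [disease_spec()]s.
#' @param n_datasets integer (scalar or per-disease) number of datasets per
#'   disease.
#' @param n_case,n_control per-dataset group sizes.
#' @param dirichlet_alpha named baseline concentration vector.
#' @param shared_shift named shift vector added (on the multiplicative weight
#'   scale) to the own shift of diseases in `shared_diseases`.
#' @param shared_diseases character vector naming diseases receiving
#'   `shared_shift` (default: all).
#' @param noise_cv,batch_scale_sd as in [simulate_dataset()].
#' @param alpha_dataset_sd SD of a per-dataset log-normal jitter on the
#'   baseline concentration weights (cohort-to-cohort differences in baseline
#'   blood composition; 0 disables).
#' @param seed integer master seed; each dataset receives a distinct derived
#'   seed.
#' @return A list of per-dataset results as returned by [simulate_dataset()],
#'   named by dataset id (`<disease>_d<i>`).
#' @export
simulate_collection <- function(basis, specs, n_datasets = 2, n_case = 20,
                                n_control = 20, dirichlet_alpha,
                                shared_shift = NULL, shared_diseases = NULL,
                                noise_cv = 0.2, batch_scale_sd = 0.3,
                                alpha_dataset_sd = 0, seed = 1) {
  stopifnot(length(specs) >= 1)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  }
  if (length(n_datasets) == 1) n_datasets <- rep(n_datasets, length(specs))
  if (is.null(shared_diseases)) shared_diseases <- names(specs)
  out <- list()
  idx <- 0
  for (d in seq_along(specs)) {
    spec <- specs[[d]]
    if (!is.null(shared_shift) && spec$name %in% shared_diseases) {
      merged <- shared_shift
      for (ct in names(spec$freq_shift)) {
        merged[ct] <- (merged[ct] %|na|% 0) + spec$freq_shift[ct]
      }
      spec <- disease_spec(spec$name, freq_shift = merged,
                           de_effects = spec$de_effects)
    }
    for (i in seq_len(n_datasets[d])) {
      idx <- idx + 1
      ds_id <- sprintf("%s_d%d", spec$name, i)
      if (ds_id %in% names(out)) stop("duplicate dataset id: ", ds_id, call. = FALSE)
      ds_seed <- (seed * 1000L + idx) %% .Machine$integer.max
      alpha_d <- dirichlet_alpha
      if (alpha_dataset_sd > 0) {
        alpha_d <- withr::with_seed((ds_seed + 7L) %% .Machine$integer.max, {
          dirichlet_alpha * exp(rnorm(length(dirichlet_alpha), 0,
                                      alpha_dataset_sd))
        })
      }
      out[[ds_id]] <- simulate_dataset(
        basis, spec, n_case = n_case, n_control = n_control,
        dirichlet_alpha = alpha_d, noise_cv = noise_cv,
        batch_scale_sd = batch_scale_sd, seed = ds_seed,
        dataset_id = ds_id)
    }
  }
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Default synthetic whole-blood benchmark collection
#'
#' The standard end-to-end test bed of the package: 4 cell types (two myeloid,
#' two lymphoid), three "shared" diseases that all carry a common myeloid-up /
#' lymphoid-down frequency shift plus disease-specific cell-type-restricted
#' differential expression, and two "independent" diseases with their own
#' (non-shared) composition changes — each disease observed in two independent
#' datasets with dataset-level batch scaling. The shared shift makes the three
#' shared diseases look alike in marginal expression while their true
#' disease-specific signal lives in cell-type-restricted expression changes —
#' the confound the residual-profile strategy is designed to break.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param n_case,n_control per-dataset group sizes.
#' @param noise_cv,batch_scale_sd noise controls (see [simulate_dataset()]).
#' @param markers_per_type exclusive marker genes per cell type.
#' @param n_de_genes disease-specific perturbed genes per disease.
#' @param de_fold fold change applied in the target cell type of each disease.
#' @param shared_shift_scale multiplier on the shared myeloid-up/lymphoid-down
#'   shift (0 removes the common composition confound, leaving only
#'   disease-own shifts and cell-type-restricted expression change).
#' @return A list with `collection` (see [simulate_collection()]), `basis`,
#'   `markers`, `cell_types`, `dirichlet_alpha`, `shared_diseases` and
#'   `de_truth` (tibble of disease/gene/cell_type).
#' @export
wb_benchmark <- function(seed = 1, n_genes = 300, n_case = 15, n_control = 40,
                         noise_cv = 0.2, batch_scale_sd = 0.3,
                         markers_per_type = 20, n_de_genes = 20,
                         de_fold = 2, shared_shift_scale = 1) {
  cell_types <- c("neutrophil", "monocyte", "tcell", "bcell")
  dirichlet_alpha <- c(neutrophil = 22, monocyte = 4, tcell = 12, bcell = 2)
  made <- make_basis(n_genes, cell_types, markers_per_type = markers_per_type,
                     marker_fold = 50, seed = seed, sdlog = 1.2)
  marker_genes <- unlist(made$markers, use.names = FALSE)
  free_genes <- setdiff(rownames(made$basis), marker_genes)
  if (length(free_genes) < 5 * n_de_genes) {
    stop("n_genes too small: need at least markers + 5 * n_de_genes free genes",
         call. = FALSE)
  }
  shared_shift <- shared_shift_scale * c(neutrophil = 0.4, monocyte = 0.4,
                                         tcell = -0.3, bcell = -0.3)
  shared <- c("sepsisA", "sepsisB", "sepsisC")
  indep <- c("quietA", "quietB")
  target_ct <- c(sepsisA = "tcell", sepsisB = "monocyte",
                 sepsisC = "tcell", quietA = "tcell", quietB = "monocyte")
  # each disease also carries its own mild composition signature on top of
  # the shared shift (cohorts of one disease resemble each other in their
  # cell-component profile), secondary to the common myeloid/lymphoid pattern
  own_shift <- list(
    sepsisA = c(monocyte = 0.5, neutrophil = -0.15),
    sepsisB = c(bcell = -0.4, tcell = 0.12),
    sepsisC = c(monocyte = -0.3, neutrophil = 0.12, bcell = 0.35),
    quietA = c(tcell = 0.3, neutrophil = -0.2),
    quietB = c(monocyte = 0.35, bcell = -0.25))
  specs <- list()
  de_truth <- list()
  withr::local_seed(seed + 17)
  pool <- sample(free_genes)
  offset <- 0
  for (d in c(shared, indep)) {
    genes_d <- pool[offset + seq_len(n_de_genes)]
    offset <- offset + n_de_genes
    de <- tibble::tibble(cell_type = target_ct[[d]], gene = genes_d,
                         fold = de_fold)
    specs[[d]] <- disease_spec(d, freq_shift = own_shift[[d]], de_effects = de)
    de_truth[[d]] <- tibble::tibble(disease = d, gene = genes_d,
                                    cell_type = target_ct[[d]])
  }
  collection <- simulate_collection(
    made$basis, specs, n_datasets = 2, n_case = n_case, n_control = n_control,
    dirichlet_alpha = dirichlet_alpha, shared_shift = shared_shift,
    shared_diseases = shared, noise_cv = noise_cv,
    batch_scale_sd = batch_scale_sd, alpha_dataset_sd = 0.12, seed = seed)
  list(collection = collection, basis = made$basis, markers = made$markers,
       cell_types = cell_types, dirichlet_alpha = dirichlet_alpha,
       shared_diseases = shared, de_truth = dplyr::bind_rows(de_truth))
}
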
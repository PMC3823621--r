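#' Planted effect-size presets
#'
#' The default planted effects mirror the magnitudes a 3-condition
#' polarization experiment reports: a very large M1-responsive gene
#' induction (425-fold, IL-6-like), a large M2a-responsive gene induction
#' (38.85-fold, CHI3L3-like), a strong M1-responsive miRNA induction
#' (9.69-fold, miR-155-like) and a modest M2a-responsive miRNA induction
#' (2.66-fold, miR-145-like). Feature ids carry a `LIKE`/`like` suffix to
#' mark them as synthetic stand-ins.
#'
#' @return A named list with tibbles `genes` and `mirnas`
#'   (`feature_id`, `condition`, `linear_fold`).
#' @export
planted_presets <- function() {
  list(
    genes = tibble::tibble(
      preset = c("il6_like", "chi3l3_like"),
      feature_id = c("IL6LIKE", "CHI3L3LIKE"),
      condition = c("M1", "M2a"),
      linear_fold = c(425, 38.85)
    ),
    mirnas = tibble::tibble(
      preset = c("mir155_like", "mir145_like"),
      feature_id = c("miR-155like", "miR-145like"),
      condition = c("M1", "M2a"),
      linear_fold = c(9.69, 2.66)
    )
  )
}

#' Simulate a paired miRNA/mRNA polarization dataset with planted truth
#'
#' Generates log2 expression for a 3-condition (M0 resting, M1, M2a)
#' design with `n_replicates` per condition. Each miRNA's log2 value is
#' baseline + condition effect + Gaussian noise; each gene's log2 value is
#' baseline + condition effect + the sum over incoming regulatory edges of
#' `beta` times the regulating miRNA's condition-level deviation from its
#' baseline, + Gaussian noise. Repressive edges (negative beta) therefore
#' produce inverse miRNA:gene correlation across conditions, activating
#' edges positive correlation. Two noisy prediction databases contain each true edge with
#' probability `db_sensitivity` plus `db_noise` decoy predictions per
#' regulator, and an annotation collection holds one "network" set per
#' regulator (its true targets) plus size-matched decoy sets.
#'
#' @param seed Integer seed (required; the dataset is a pure function of
#'   the arguments).
#' @param n_genes,n_mirnas Feature counts (minimum 50 genes, 10 miRNAs).
#' @param n_replicates Replicates per condition (minimum 2; the study
#'   design uses 3).
#' @param noise_sd Gaussian noise standard deviation, log2 units
#'   (default 0.2; 0 gives the zero-noise limit).
#' @param gene_presets,mirna_presets Planted condition effects; tibbles
#'   with columns `feature_id`, `condition`, `linear_fold`
#'   (defaults from [planted_presets()]). Preset features carry pure
#'   condition effects and never receive incoming edges, so the planted
#'   fold is the realized fold.
#' @param n_repressive,n_activating Edges per regulator miRNA.
#' @param beta_repressive,beta_activating Edge slopes on log2 scale
#'   (repressive slope must be negative).
#' @param db_sensitivity Probability a true edge enters each database.
#' @param db_noise Decoy predictions per regulator per database.
#' @param n_decoy_sets Decoy annotation sets (size-matched to true sets).
#' @return A list: `mrna`, `mirna` ([expression_matrix()]s), `samples`
#'   (sample sheet), `db_a`, `db_b` (target databases), `annotations`
#'   (gene-set collection), `truth` (`polarmir_truth`).
#' @export
simulate_microglia <- function(seed,
                               n_genes = 300,
                               n_mirnas = 60,
                               n_replicates = 3,
                               noise_sd = 0.2,
                               gene_presets = planted_presets()$genes,
                               mirna_presets = planted_presets()$mirnas,
                               n_repressive = 6,
                               n_activating = 3,
                               beta_repressive = -1.5,
                               beta_activating = 1.5,
                               db_sensitivity = 0.9,
                               db_noise = 5,
                               n_decoy_sets = 4) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("An explicit integer `seed` is required.", call. = FALSE)
  }
  if (n_genes < 50 || n_mirnas < 10 || n_replicates < 2) {
    stop("Minimal design: >=50 genes, >=10 miRNAs, >=2 replicates.",
         call. = FALSE)
  }
  stopifnot(noise_sd >= 0, db_sensitivity >= 0, db_sensitivity <= 1,
            db_noise >= 0, beta_repressive <= 0, beta_activating >= 0,
            all(gene_presets$linear_fold > 0),
            all(mirna_presets$linear_fold > 0))
  conditions <- c("M0", "M1", "M2a")
  stopifnot(all(gene_presets$condition %in% conditions),
            all(mirna_presets$condition %in% conditions))

  withr::with_seed(as.integer(seed), {
    samples <- tidyr::expand_grid(condition = conditions,
                                  replicate = seq_len(n_replicates))
    samples$sample_id <- paste0(samples$condition, "_", samples$replicate)
    samples <- samples[c("sample_id", "condition", "replicate")]
    n_samp <- nrow(samples)

    reference_mirna <- "miR-709like"
    n_filler_mi <- n_mirnas - nrow(mirna_presets) - 1L
    mirna_ids <- normalize_mirna(c(mirna_presets$feature_id, reference_mirna,
                                   sprintf("miR-n%03d", seq_len(n_filler_mi))))
    n_filler_g <- n_genes - nrow(gene_presets)
    gene_ids <- normalize_symbol(c(gene_presets$feature_id,
                                   sprintf("GENE%04d", seq_len(n_filler_g))))
    filler_genes <- setdiff(gene_ids,
                            normalize_symbol(as.character(gene_presets$feature_id)))

    # baselines: planted miRNAs high so the expression-fraction rule keeps
    # them; the reference is fixed at the top of the baseline range
    mi_base <- stats::setNames(stats::runif(n_mirnas, 4, 12), mirna_ids)
    mi_base[normalize_mirna(mirna_presets$feature_id)] <-
      seq(13.5, 13.1, length.out = nrow(mirna_presets))
    mi_base[normalize_mirna(reference_mirna)] <- 14
    g_base <- stats::setNames(stats::runif(n_genes, 4, 12), gene_ids)

    # condition effects (log2)
    mi_eff <- matrix(0, n_mirnas, length(conditions),
                     dimnames = list(mirna_ids, conditions))
    for (i in seq_len(nrow(mirna_presets))) {
      mi_eff[normalize_mirna(mirna_presets$feature_id[i]),
             mirna_presets$condition[i]] <- log2(mirna_presets$linear_fold[i])
    }
    g_eff <- matrix(0, n_genes, length(conditions),
                    dimnames = list(gene_ids, conditions))
    for (i in seq_len(nrow(gene_presets))) {
      g_eff[normalize_symbol(gene_presets$feature_id[i]),
            gene_presets$condition[i]] <- log2(gene_presets$linear_fold[i])
    }

    # regulatory edges: each planted miRNA regulates disjoint filler genes
    regulators <- normalize_mirna(mirna_presets$feature_id)
    per_reg <- n_repressive + n_activating
    if (length(regulators) * per_reg > length(filler_genes)) {
      stop("Not enough filler genes for the requested edges.", call. = FALSE)
    }
    target_pool <- sample(filler_genes,
                          length(regulators) * per_reg)
    edges <- dplyr::bind_rows(lapply(seq_along(regulators), function(i) {
      tg <- target_pool[((i - 1) * per_reg + 1):(i * per_reg)]
      tibble::tibble(
        mirna_id = regulators[i],
        gene_id = tg,
        beta = c(rep(beta_repressive, n_repressive),
                 rep(beta_activating, n_activating)),
        sign = c(rep("repressive", n_repressive),
                 rep("activating", n_activating))
      )
    }))

    cond_of <- samples$condition
    # miRNA matrix: baseline + condition effect + noise
    mi_vals <- mi_base + mi_eff[, cond_of, drop = FALSE] +
      matrix(stats::rnorm(n_mirnas * n_samp, 0, noise_sd), n_mirnas, n_samp)
    colnames(mi_vals) <- samples$sample_id

    # gene matrix: baseline + condition effect + edge terms + noise
    g_vals <- g_base + g_eff[, cond_of, drop = FALSE] +
      matrix(stats::rnorm(n_genes * n_samp, 0, noise_sd), n_genes, n_samp)
    colnames(g_vals) <- samples$sample_id
    for (i in seq_len(nrow(edges))) {
      dev <- mi_eff[edges$mirna_id[i], cond_of]
      g_vals[edges$gene_id[i], ] <- g_vals[edges$gene_id[i], ] +
        edges$beta[i] * dev
    }

    make_db <- function(source_name) {
      sets <- lapply(regulators, function(mi) {
        true_tg <- edges$gene_id[edges$mirna_id == mi]
        kept <- true_tg[stats::runif(length(true_tg)) < db_sensitivity]
        non_tg <- setdiff(gene_ids, true_tg)
        decoys <- if (db_noise > 0) sample(non_tg, min(db_noise, length(non_tg)))
                  else character(0)
        sort(unique(c(kept, decoys)))
      })
      names(sets) <- regulators
      sets <- sets[lengths(sets) > 0]
      gene_sets(sets, role = "targets", source_name = source_name)
    }
    db_a <- make_db("synthetic_db_a")
    db_b <- make_db("synthetic_db_b")

    true_sets <- lapply(regulators, function(mi) {
      sort(edges$gene_id[edges$mirna_id == mi])
    })
    names(true_sets) <- paste0("NETWORK_", gsub("[^A-Za-z0-9]", "", regulators))
    set_sizes <- lengths(true_sets)
    non_target <- setdiff(gene_ids, edges$gene_id)
    decoy_sets <- lapply(seq_len(n_decoy_sets), function(i) {
      sz <- set_sizes[((i - 1) %% length(set_sizes)) + 1]
      sort(sample(non_target, sz))
    })
    names(decoy_sets) <- sprintf("DECOYNET_%02d", seq_len(n_decoy_sets))
    annotations <- gene_sets(c(true_sets, decoy_sets), role = "annotation",
                             source_name = "synthetic_networks")

    dataset_id <- sprintf("sim-%d-%dgx%dm-%dr", as.integer(seed),
                          n_genes, n_mirnas, n_replicates)
    mrna <- expression_matrix(
      tibble::tibble(feature_id = gene_ids,
                     !!!tibble::as_tibble(g_vals)), "mRNA")
    mirna <- expression_matrix(
      tibble::tibble(feature_id = mirna_ids,
                     !!!tibble::as_tibble(mi_vals)), "miRNA")
    attr(mrna, "dataset_id") <- dataset_id
    attr(mirna, "dataset_id") <- dataset_id

    truth <- structure(list(
      planted_mirna_effects = mirna_presets |>
        dplyr::mutate(feature_id = normalize_mirna(.data$feature_id)),
      planted_gene_effects = gene_presets |>
        dplyr::mutate(feature_id = normalize_symbol(.data$feature_id)),
      regulatory_edges = edges,
      reference_mirna = normalize_mirna(reference_mirna),
      db_sensitivity = db_sensitivity,
      db_noise = db_noise,
      noise_sd = noise_sd,
      conditions = conditions,
      n_replicates = n_replicates,
      dataset_id = dataset_id
    ), class = "polarmir_truth")

    list(mrna = mrna, mirna = mirna, samples = samples,
         db_a = db_a, db_b = db_b, annotations = annotations, truth = truth)
  })
}

#' @export
print.polarmir_truth <- function(x, ...) {
  cat("<polarmir planted truth> ", x$dataset_id, "\n",
      "  planted gene effects: ", nrow(x$planted_gene_effects),
      "; planted miRNA effects: ", nrow(x$planted_mirna_effects),
      "; regulatory edges: ", nrow(x$regulatory_edges), "\n", sep = "")
  invisible(x)
}

#' Score pipeline output against the planted truth
#'
#' Computes precision and recall of regulatory-edge recovery from one or
#' more interactome tables, and (when DE tables are supplied) the bias of
#' the recovered fold change for every planted effect. Inputs generated
#' from a different dataset than `truth` (detected via the embedded
#' dataset id) are an error.
#'
#' @param truth A `polarmir_truth` object.
#' @param interactomes A `polarmir_interactome` tibble or list of them.
#' @param de_mrna,de_mirna Optional `polarmir_de` tables whose contrast's
#'   treated condition matches a planted effect's condition.
#' @param dataset_id Optional dataset id of the analyzed data; checked
#'   against `truth$dataset_id` when available.
#' @return A list with tibbles `edge_recovery` (`n_true`, `n_recovered`,
#'   `n_correct`, `precision`, `recall`) and `fold_recovery`
#'   (`feature_id`, `kind`, `condition`, `planted_fold`, `estimated_fold`,
#'   `relative_error`).
#' @export
truth_report <- function(truth, interactomes, de_mrna = NULL, de_mirna = NULL,
                         dataset_id = NULL) {
  stopifnot(inherits(truth, "polarmir_truth"))
  check_id <- function(id) {
    if (!is.null(id) && !identical(id, truth$dataset_id)) {
      stop("Dataset id mismatch: truth is '", truth$dataset_id,
           "' but output came from '", id, "'.", call. = FALSE)
    }
  }
  check_id(dataset_id)
  check_id(attr(de_mrna, "dataset_id"))
  check_id(attr(de_mirna, "dataset_id"))
  if (is.data.frame(interactomes)) interactomes <- list(interactomes)
  recovered <- dplyr::bind_rows(lapply(interactomes, function(x) {
    tibble::as_tibble(x)[c("mirna_id", "gene_symbol")]
  }))
  true_edges <- truth$regulatory_edges
  key <- function(a, b) paste(a, b, sep = "::")
  tp <- sum(key(recovered$mirna_id, recovered$gene_symbol) %in%
              key(true_edges$mirna_id, true_edges$gene_id))
  edge_recovery <- tibble::tibble(
    n_true = nrow(true_edges),
    n_recovered = nrow(recovered),
    n_correct = tp,
    precision = if (nrow(recovered) > 0) tp / nrow(recovered) else NA_real_,
    recall = if (nrow(true_edges) > 0) tp / nrow(true_edges) else NA_real_
  )
  fold_rows <- list()
  score_folds <- function(presets, de, kind) {
    if (is.null(de)) return(NULL)
    hits <- presets[presets$condition == attr(de, "treated"), , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    est <- de$linear_fold[match(hits$feature_id, de$feature_id)]
    tibble::tibble(
      feature_id = hits$feature_id, kind = kind,
      condition = hits$condition, planted_fold = hits$linear_fold,
      estimated_fold = est,
      relative_error = (abs(est) - hits$linear_fold) / hits$linear_fold
    )
  }
  fold_recovery <- dplyr::bind_rows(
    score_folds(truth$planted_gene_effects, de_mrna, "mRNA"),
    score_folds(truth$planted_mirna_effects, de_mirna, "miRNA")
  )
  list(edge_recovery = edge_recovery, fold_recovery = fold_recovery)
}
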
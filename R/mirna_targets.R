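#' Correlate one miRNA profile with every gene
#'
#' Computes the Pearson correlation between a miRNA's log2 expression
#' profile and every gene's profile, across the pooled samples of the two
#' contrast conditions (the screen is contrast-specific, so only the
#' samples that define the contrast enter the correlation; pass all
#' conditions to correlate over the full design instead). Genes with zero
#' variance across the used samples get `r = 0` and a `degenerate` flag
#' rather than an undefined correlation.
#'
#' @param mirna_em miRNA [expression_matrix()].
#' @param mrna_em mRNA [expression_matrix()] measured on the same samples.
#' @param sheet A [sample_sheet()].
#' @param mirna_id The miRNA to correlate (normalized with
#'   [normalize_mirna()]).
#' @param conditions Character vector of condition labels whose samples are
#'   pooled for the correlation (typically the contrast's two conditions).
#' @return Tibble of class `polarmir_cor`: `gene_id`, `r`, `n_samples`,
#'   `degenerate`; attribute `mirna_id`.
#' @export
correlate_mirna_genes <- function(mirna_em, mrna_em, sheet, mirna_id,
                                  conditions) {
  mirna_id <- normalize_mirna(mirna_id)
  sheet <- sample_sheet(sheet)
  use <- sheet$sample_id[sheet$condition %in% conditions]
  miss_mi <- setdiff(use, names(mirna_em)[-1])
  miss_mr <- setdiff(use, names(mrna_em)[-1])
  if (length(miss_mi) > 0L || length(miss_mr) > 0L) {
    stop("Sample(s) missing from a matrix: ",
         paste(unique(c(miss_mi, miss_mr)), collapse = ", "), call. = FALSE)
  }
  if (length(use) < 3L) {
    stop("Fewer than 3 usable samples for conditions ",
         paste(conditions, collapse = ", "), ".", call. = FALSE)
  }
  mi <- expr_values(mirna_em)
  if (!mirna_id %in% rownames(mi)) {
    stop("miRNA '", mirna_id, "' absent from the miRNA matrix.", call. = FALSE)
  }
  x <- mi[mirna_id, use]
  genes <- expr_values(mrna_em)[, use, drop = FALSE]
  gene_sd <- apply(genes, 1L, stats::sd)
  degenerate <- gene_sd == 0 | stats::sd(x) == 0
  r <- rep(0, nrow(genes))
  if (stats::sd(x) > 0 && any(!degenerate)) {
    r[!degenerate] <- as.vector(stats::cor(t(genes[!degenerate, , drop = FALSE]), x))
  }
  out <- tibble::tibble(
    gene_id = rownames(genes),
    r = r,
    n_samples = length(use),
    degenerate = degenerate
  )
  structure(out, class = c("polarmir_cor", class(tibble::tibble())),
            mirna_id = mirna_id)
}

#' Filter candidate target genes by correlation and DE significance
#'
#' Keeps genes with `|r| > r_threshold` and DE `p_value < p_threshold`
#' (both strict), the screen applied before database intersection.
#'
#' @param correlations A `polarmir_cor` table from
#'   [correlate_mirna_genes()].
#' @param de A `polarmir_de` table for the same contrast.
#' @param r_threshold Absolute correlation threshold (default 0.5).
#' @param p_threshold DE significance threshold (default 1e-4).
#' @return Sorted character vector of surviving gene symbols.
#' @export
filter_candidates <- function(correlations, de, r_threshold = 0.5,
                              p_threshold = 1e-4) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(correlations),
    tibble::as_tibble(de)[c("feature_id", "p_value")],
    by = c(gene_id = "feature_id")
  )
  keep <- abs(joined$r) > r_threshold & joined$p_value < p_threshold
  sort(joined$gene_id[keep])
}

#' Triple intersection of candidates with two prediction databases
#'
#' The Venn criterion for a putative target: a gene must survive the
#' correlation/DE screen and be predicted by both databases for the miRNA.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param db_a,db_b `polarmir_genesets` target databases.
#' @param mirna_id miRNA whose predictions to use; if absent from a
#'   database, a warning is issued and that database contributes the empty
#'   set.
#' @return Sorted character vector: `candidates` ∩ `db_a[mirna]` ∩
#'   `db_b[mirna]`.
#' @export
intersect_targets <- function(candidates, db_a, db_b, mirna_id) {
  mirna_id <- normalize_mirna(mirna_id)
  fetch <- function(db) {
    if (!mirna_id %in% names(db)) {
      warning("miRNA '", mirna_id, "' absent from database '",
              attr(db, "source_name"), "'; treating as empty prediction set.",
              call. = FALSE)
      return(character(0))
    }
    db[[mirna_id]]
  }
  sort(intersect(intersect(normalize_symbol(candidates), fetch(db_a)),
                 fetch(db_b)))
}

#' Build a miRNA:mRNA interactome table
#'
#' One row per candidate gene, carrying its correlation with the miRNA
#' (`correlation_factor`), its DE log2 fold change, and its DE p-value
#' (`power`). Direction is `inversely_correlated` iff the correlation is
#' negative. Rows are sorted with the positively correlated class first,
#' then within each class by descending absolute log2 fold change, ties
#' broken alphabetically by gene symbol.
#'
#' @param candidates Character vector of gene symbols (each must appear in
#'   both tables).
#' @param correlations A `polarmir_cor` table.
#' @param de A `polarmir_de` table.
#' @param descriptions Optional named character vector of gene descriptions.
#' @return Tibble of class `polarmir_interactome`: `mirna_id`,
#'   `gene_symbol`, `description`, `correlation_factor`,
#'   `log2_fold_change`, `power`, `direction`.
#' @export
build_interactome <- function(candidates, correlations, de,
                              descriptions = NULL) {
  candidates <- normalize_symbol(candidates)
  if (length(candidates) == 0L) {
    return(new_interactome(tibble::tibble(
      mirna_id = character(0), gene_symbol = character(0),
      description = character(0), correlation_factor = numeric(0),
      log2_fold_change = numeric(0), power = numeric(0),
      direction = character(0)
    )))
  }
  cors <- tibble::as_tibble(correlations)
  det <- tibble::as_tibble(de)
  miss_c <- setdiff(candidates, cors$gene_id)
  miss_d <- setdiff(candidates, det$feature_id)
  if (length(miss_c) > 0L || length(miss_d) > 0L) {
    stop("Candidate(s) missing from correlation or DE table: ",
         paste(unique(c(miss_c, miss_d)), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    mirna_id = attr(correlations, "mirna_id") %||% NA_character_,
    gene_symbol = candidates,
    description = if (is.null(descriptions)) NA_character_ else
      unname(descriptions[candidates]),
    correlation_factor = cors$r[match(candidates, cors$gene_id)],
    log2_fold_change = det$log2_fold_change[match(candidates, det$feature_id)],
    power = det$p_value[match(candidates, det$feature_id)]
  )
  out$direction <- dplyr::if_else(out$correlation_factor < 0,
                                  "inversely_correlated",
                                  "positively_correlated")
  new_interactome(sort_interactome(out))
}

new_interactome <- function(x) {
  structure(x, class = c("polarmir_interactome", class(tibble::tibble())))
}

sort_interactome <- function(x) {
  dplyr::arrange(x,
                 factor(.data$direction,
                        levels = c("positively_correlated",
                                   "inversely_correlated")),
                 dplyr::desc(abs(.data$log2_fold_change)),
                 .data$gene_symbol)
}

#' Read an interactome table from TSV
#'
#' Reads a table with columns `mirna_id`, `gene_symbol`, `description`,
#' `correlation_factor`, `log2_fold_change`, `power` (a `direction` column,
#' if absent, is derived from the sign of the correlation) and applies the
#' canonical ordering. The packaged `table2_mir155.tsv` fixture loads
#' through this reader.
#'
#' @param path Path to a TSV file.
#' @return A `polarmir_interactome` tibble.
#' @export
read_interactome <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    description = readr::col_character(),
    correlation_factor = readr::col_double(),
    log2_fold_change = readr::col_double(),
    power = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  x$mirna_id <- normalize_mirna(x$mirna_id)
  x$gene_symbol <- normalize_symbol(x$gene_symbol)
  if (!"direction" %in% names(x)) {
    x$direction <- dplyr::if_else(x$correlation_factor < 0,
                                  "inversely_correlated",
                                  "positively_correlated")
  }
  new_interactome(tibble::as_tibble(x))
}

#' Write an interactome table to TSV
#'
#' @param interactome A `polarmir_interactome` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(interactome, path) {
  readr::write_tsv(tibble::as_tibble(interactome), path, progress = FALSE)
  invisible(path)
}

#' Count interactome records by correlation direction
#'
#' @param interactome A `polarmir_interactome` tibble.
#' @return One-row tibble: `n_positive`, `n_negative` (they sum to the
#'   table size).
#' @export
classify_directions <- function(interactome) {
  tibble::tibble(
    n_positive = sum(interactome$direction == "positively_correlated"),
    n_negative = sum(interactome$direction == "inversely_correlated")
  )
}

#' Overlap statistics between candidates and prediction databases
#'
#' Sizes and fractions (relative to the candidate set) of the pairwise
#' overlaps with each database's predictions and of the triple
#' intersection.
#'
#' @param candidates Character vector of screened candidate gene symbols.
#' @param db_a_set,db_b_set Character vectors of predicted target symbols
#'   for the miRNA, one per database.
#' @return One-row tibble: `n_correlated_de`, `n_db_a`, `n_db_b`,
#'   `n_overlap_a`, `n_overlap_b`, `n_triple`, `frac_overlap_a`,
#'   `frac_overlap_b`, `frac_triple`, `degenerate`. Fractions are `NA` and
#'   `degenerate` is `TRUE` when the candidate set is empty.
#' @export
overlap_fractions <- function(candidates, db_a_set, db_b_set) {
  candidates <- unique(normalize_symbol(as.character(candidates)))
  db_a_set <- unique(normalize_symbol(as.character(db_a_set)))
  db_b_set <- unique(normalize_symbol(as.character(db_b_set)))
  n <- length(candidates)
  ov_a <- intersect(candidates, db_a_set)
  ov_b <- intersect(candidates, db_b_set)
  tri <- intersect(ov_a, db_b_set)
  degenerate <- n == 0L
  if (degenerate) {
    warning("Empty candidate set: overlap fractions undefined.", call. = FALSE)
  }
  tibble::tibble(
    n_correlated_de = n,
    n_db_a = length(db_a_set),
    n_db_b = length(db_b_set),
    n_overlap_a = length(ov_a),
    n_overlap_b = length(ov_b),
    n_triple = length(tri),
    frac_overlap_a = if (degenerate) NA_real_ else length(ov_a) / n,
    frac_overlap_b = if (degenerate) NA_real_ else length(ov_b) / n,
    frac_triple = if (degenerate) NA_real_ else length(tri) / n,
    degenerate = degenerate
  )
}
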
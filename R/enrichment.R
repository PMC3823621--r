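#' Right-tailed hypergeometric over-representation probability
#'
#' Probability of observing at least `k` members of an annotation set of
#' size `K` in a query of size `n` drawn without replacement from a
#' universe of size `N`.
#'
#' @param k Observed overlap count.
#' @param K Annotation-set size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return P(X >= k) under Hypergeometric(N, K, n).
#' @export
hypergeometric_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (K > N || n > N) {
    stop("Set and query sizes cannot exceed the universe size.", call. = FALSE)
  }
  if (k > K || k > n) {
    stop("Overlap k cannot exceed the set size or the query size.",
         call. = FALSE)
  }
  if (k < 0) stop("Counts must be non-negative.", call. = FALSE)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Over-representation of a gene set collection in a query
#'
#' Tests each annotation set for enrichment in the query with a
#' right-tailed hypergeometric test, after restricting both the query and
#' every set to the universe (query genes outside the universe are dropped
#' with a warning). Benjamini-Hochberg q-values are computed across the
#' collection.
#'
#' @param query Character vector of gene symbols (e.g. an interactome's
#'   genes).
#' @param collection A `polarmir_genesets` annotation collection.
#' @param universe Character vector of all measurable gene symbols
#'   (typically every gene on the expression matrix).
#' @param mirna_id Optional miRNA label carried into the output (used when
#'   pooling per-miRNA results).
#' @return Tibble of class `polarmir_enrichment`: `mirna_id`, `set_name`,
#'   `k_overlap`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `q_value`, `neg_log10_p`. Empty (with a warning) when the query is
#'   empty.
#' @export
enrich <- function(query, collection, universe, mirna_id = NA_character_) {
  universe <- unique(normalize_symbol(as.character(universe)))
  if (length(universe) == 0L) stop("Empty universe.", call. = FALSE)
  query <- unique(normalize_symbol(as.character(query)))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped.",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  empty <- tibble::tibble(
    mirna_id = character(0), set_name = character(0),
    k_overlap = integer(0), set_size = integer(0), query_size = integer(0),
    universe_size = integer(0), p_value = numeric(0), q_value = numeric(0),
    neg_log10_p = numeric(0)
  )
  if (length(query) == 0L) {
    warning("Empty query: no enrichment computed.", call. = FALSE)
    return(new_enrichment(empty))
  }
  rows <- purrr::map(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    k <- length(intersect(query, s))
    p <- hypergeometric_p(k, length(s), length(query), length(universe))
    tibble::tibble(mirna_id = mirna_id, set_name = nm,
                   k_overlap = k, set_size = length(s),
                   query_size = length(query),
                   universe_size = length(universe), p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out$neg_log10_p <- -log10(out$p_value)
  new_enrichment(out)
}

new_enrichment <- function(x, alpha = NULL) {
  structure(x, class = c("polarmir_enrichment", class(tibble::tibble())),
            significance_line = if (is.null(alpha)) NULL else -log10(alpha))
}

#' Pool per-miRNA enrichment tables and rank by -log10(p)
#'
#' Concatenates enrichment tables from several miRNAs, sorts by descending
#' `neg_log10_p`, and keeps the top rows. Duplicate set names from
#' different miRNAs remain separate rows, so each bar in the ranked list
#' carries its originating miRNA. The significance line `-log10(alpha)`
#' (1.30 for alpha = 0.05) is attached as the `significance_line`
#' attribute.
#'
#' @param per_mirna A list of `polarmir_enrichment` tables (or a single
#'   table).
#' @param alpha Significance level marking the ranking's threshold line.
#' @param top_n Number of top rows to keep.
#' @return A ranked `polarmir_enrichment` tibble with attribute
#'   `significance_line`.
#' @export
pool_and_rank <- function(per_mirna, alpha = 0.05, top_n = 15) {
  if (is.data.frame(per_mirna)) per_mirna <- list(per_mirna)
  pooled <- dplyr::bind_rows(lapply(per_mirna, tibble::as_tibble))
  pooled <- dplyr::arrange(pooled, dplyr::desc(.data$neg_log10_p),
                           .data$set_name, .data$mirna_id)
  pooled <- utils::head(pooled, top_n)
  new_enrichment(pooled, alpha = alpha)
}
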
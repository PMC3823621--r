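# Small deterministic fixtures built in code.

toy_matrix <- function(values, feature_ids, sample_ids,
                       feature_kind = "mRNA") {
  m <- matrix(values, nrow = length(feature_ids), byrow = TRUE,
              dimnames = list(NULL, sample_ids))
  df <- tibble::tibble(feature_id = feature_ids,
                       !!!tibble::as_tibble(m))
  expression_matrix(df, feature_kind)
}

toy_sheet <- function(conditions = c("M0", "M1"), n_replicates = 3) {
  tibble::tibble(
    sample_id = paste0(rep(conditions, each = n_replicates), "_",
                       rep(seq_len(n_replicates), length(conditions))),
    condition = rep(conditions, each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(conditions))
  )
}

# independent brute-force BH step-up, straight from the definition
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    # q_i = min over j >= rank(i) of n * p_(j) / j
    ranked <- p[o]
    q[o[i]] <- min(pmin(1, n * ranked[i:n] / (i:n)))
  }
  q
}

# exhaustive hypergeometric tail: enumerate every n-subset of the universe
brute_force_hyper_tail <- function(k, K, n, N) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% inset))
  mean(hits >= k)
}

table2_path <- function() polarmir_example("table2_mir155.tsv")
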
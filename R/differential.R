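#' Two-group differential expression on a log2 matrix
#'
#' For every feature, compares `treated` against `control` samples with a
#' two-sided two-sample Student t-test (pooled variance by default, the
#' convention of the array analysis this package mirrors; Welch via
#' `var_equal = FALSE`). Fold changes are differences of group means on the
#' log2 scale; the signed linear fold is `2^|log2FC|` with the sign of the
#' log2 fold change (a log2FC of 0 maps to fold 1). Benjamini-Hochberg
#' q-values are computed over all tested features.
#'
#' Features with zero variance in both groups are flagged: their t statistic
#' is 0 and p-value 1 when the means agree, and the p-value degenerates to 0
#' when the means differ (the zero-noise limit).
#'
#' @param em An [expression_matrix()] (log2 scale).
#' @param sheet A [sample_sheet()] covering the matrix samples.
#' @param treated,control Condition labels to contrast (treated minus control).
#' @param var_equal Pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @return A tibble of class `polarmir_de`, one row per feature:
#'   `feature_id`, `mean_treated`, `mean_control`, `log2_fold_change`,
#'   `linear_fold`, `t_statistic`, `p_value`, `q_value`, `zero_variance`.
#' @export
run_contrast <- function(em, sheet, treated, control, var_equal = TRUE) {
  sheet <- join_samples(em, sheet)
  if (identical(treated, control)) {
    stop("`treated` and `control` must be different conditions.", call. = FALSE)
  }
  for (cond in c(treated, control)) {
    n <- sum(sheet$condition == cond)
    if (n == 0L) stop("Condition '", cond, "' absent from sample sheet.", call. = FALSE)
    if (n < 2L) stop("Condition '", cond, "' has fewer than 2 replicates.", call. = FALSE)
  }
  vals <- expr_values(em)
  xt <- vals[, sheet$sample_id[sheet$condition == treated], drop = FALSE]
  xc <- vals[, sheet$sample_id[sheet$condition == control], drop = FALSE]
  n1 <- ncol(xt); n2 <- ncol(xc)
  m1 <- rowMeans(xt); m2 <- rowMeans(xc)
  v1 <- apply(xt, 1L, stats::var); v2 <- apply(xc, 1L, stats::var)
  d <- m1 - m2
  if (var_equal) {
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- d / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  degen <- se == 0
  tstat[degen & d == 0] <- 0
  p[degen & d == 0] <- 1
  tstat[degen & d != 0] <- sign(d[degen & d != 0]) * Inf
  p[degen & d != 0] <- 0
  out <- tibble::tibble(
    feature_id = rownames(vals),
    mean_treated = unname(m1),
    mean_control = unname(m2),
    log2_fold_change = unname(d),
    linear_fold = unname(signed_fold(d)),
    t_statistic = unname(tstat),
    p_value = unname(p),
    q_value = unname(bh_adjust(p)),
    zero_variance = unname(v1 == 0 & v2 == 0)
  )
  out <- structure(out, class = c("polarmir_de", class(tibble::tibble())),
                   treated = treated, control = control,
                   feature_kind = attr(em, "feature_kind"))
  attr(out, "dataset_id") <- attr(em, "dataset_id")
  out
}

# signed linear fold: 2^|lfc| with the sign of lfc; lfc 0 -> 1
signed_fold <- function(lfc) {
  ifelse(lfc >= 0, 2^lfc, -(2^(-lfc)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving BH q-values over a vector of p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric.", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("All p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Count significant features up and down at a p-value threshold
#'
#' Reproduces the up/down counting convention of two-group array reports:
#' features with `p_value < p_threshold` are split by the sign of the log2
#' fold change, and the percentages are of the significant count. A
#' significant feature with log2FC exactly 0 belongs to neither class.
#'
#' @param records A `polarmir_de` table from [run_contrast()].
#' @param p_threshold Significance threshold (strict `<`).
#' @return One-row tibble: `n_tested`, `n_significant`, `n_up`, `n_down`,
#'   `pct_up`, `pct_down` (percentages are `NA` when nothing is significant).
#' @export
summarize_contrast <- function(records, p_threshold) {
  stopifnot(is.data.frame(records), p_threshold > 0, p_threshold <= 1)
  sig <- records[records$p_value < p_threshold, , drop = FALSE]
  n_up <- sum(sig$log2_fold_change > 0)
  n_down <- sum(sig$log2_fold_change < 0)
  n_sig <- nrow(sig)
  tibble::tibble(
    n_tested = nrow(records),
    n_significant = n_sig,
    n_up = n_up,
    n_down = n_down,
    pct_up = if (n_sig > 0) 100 * n_up / n_sig else NA_real_,
    pct_down = if (n_sig > 0) 100 * n_down / n_sig else NA_real_
  )
}

#' Shortlist miRNAs by significance and expression relative to a reference
#'
#' Keeps miRNAs that are differentially expressed (`p_value < p_threshold`)
#' and whose mean expression exceeds `min_fraction` of the reference
#' miRNA's mean — the "greater than 50% of the top expressor" rule used to
#' focus the interactome screen on abundantly expressed miRNAs. Expression
#' is compared on the linear scale: the mean over all samples of
#' `2^log2` values. Both inequalities are strict; the reference itself is
#' retained when significant (its fraction is 1).
#'
#' @param records A `polarmir_de` table for the miRNA matrix.
#' @param em The miRNA [expression_matrix()] the records came from.
#' @param reference_mirna Feature id of the reference (highest-expressing)
#'   miRNA; normalized with [normalize_mirna()].
#' @param min_fraction Minimum fraction of the reference mean (default 0.5).
#' @param p_threshold DE significance threshold (default 0.05).
#' @return Tibble: `mirna_id`, `direction` (`"up"`/`"down"` by log2FC sign),
#'   `log2_fold_change`, `p_value`, `mean_linear`, `fraction_of_reference`.
#' @export
select_mirnas <- function(records, em, reference_mirna,
                          min_fraction = 0.5, p_threshold = 0.05) {
  stopifnot(inherits(em, "polarmir_expr"))
  reference_mirna <- normalize_mirna(reference_mirna)
  vals <- expr_values(em)
  if (!reference_mirna %in% rownames(vals)) {
    stop("Reference miRNA '", reference_mirna, "' not found in the matrix.",
         call. = FALSE)
  }
  mean_linear <- rowMeans(2^vals)
  ref_mean <- mean_linear[[reference_mirna]]
  out <- tibble::tibble(
    mirna_id = records$feature_id,
    direction = dplyr::if_else(records$log2_fold_change >= 0, "up", "down"),
    log2_fold_change = records$log2_fold_change,
    p_value = records$p_value,
    mean_linear = mean_linear[records$feature_id],
    fraction_of_reference = mean_linear[records$feature_id] / ref_mean
  )
  dplyr::filter(out,
                .data$p_value < p_threshold,
                .data$fraction_of_reference > min_fraction) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2_fold_change)))
}

#' Convert between relative-quantification ddCT values and linear fold
#'
#' RT-PCR relative quantification reports fold change as `2^(-ddCT)`.
#'
#' @param ddct Numeric vector of ddCT values (cycle-threshold units).
#' @return `ddct_to_fold()`: linear fold; `fold_to_ddct()`: ddCT.
#' @export
ddct_to_fold <- function(ddct) {
  stopifnot(is.numeric(ddct), all(is.finite(ddct)))
  2^(-ddct)
}

#' @rdname ddct_to_fold
#' @param fold Positive numeric vector of linear folds.
#' @export
fold_to_ddct <- function(fold) {
  stopifnot(is.numeric(fold), all(is.finite(fold)), all(fold > 0))
  -log2(fold)
}

#' Squared Pearson correlation between two measurement methods
#'
#' Cross-method concordance of paired measurements (e.g. array fold changes
#' against RT-PCR ddCT-derived folds), reported as the square of the
#' Pearson correlation coefficient.
#'
#' @param values_a,values_b Equal-length numeric vectors (length >= 3) with
#'   nonzero variance.
#' @return Scalar r-squared in \[0, 1\].
#' @export
method_concordance <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("Input vectors must have equal length.", call. = FALSE)
  }
  if (length(values_a) < 3L) {
    stop("Need at least 3 paired values.", call. = FALSE)
  }
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    stop("Both vectors must have nonzero variance.", call. = FALSE)
  }
  stats::cor(values_a, values_b)^2
}
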
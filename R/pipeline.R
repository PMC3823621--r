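#' Default analysis thresholds
#'
#' The thresholds the integrated screen applies at each stage: gene DE
#' p < 1e-4, miRNA DE p < 0.05, |r| > 0.5 for the correlation screen,
#' q < 1e-7 for the heatmap gene selection, alpha = 0.05 for the
#' enrichment significance line, and the 50%-of-reference expression rule
#' for the miRNA shortlist.
#'
#' @return Named list of threshold defaults.
#' @export
default_thresholds <- function() {
  list(mrna_p = 1e-4, mirna_p = 0.05, r_threshold = 0.5,
       heatmap_q = 1e-7, alpha = 0.05, ref_fraction = 0.5, top_n = 15)
}

#' Run the integrated miRNA-mRNA analysis pipeline
#'
#' Orchestrates, per contrast (treated condition versus the resting
#' control): differential expression on both matrices, the miRNA
#' shortlist, per-miRNA Pearson correlation screening, overlap statistics
#' against the two prediction databases, triple intersection, interactome
#' construction with direction classification, and pooled hypergeometric
#' enrichment ranking. All thresholds used and the count surviving each
#' filter are logged.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Recognized fields: `mrna`, `mirna`, `samples`, `db_a`,
#'   `db_b`, `annotations` (in-memory objects, e.g. from
#'   [simulate_microglia()]) or the corresponding `*_path` entries;
#'   `reference_mirna` (required); `contrasts` (list of
#'   `list(treated=, control=)`; default: every non-control condition vs
#'   `control_condition`); `control_condition` (default `"M0"`);
#'   `thresholds` (overrides of [default_thresholds()]); `out_dir`
#'   (optional; write all tables, the log, and a JSON summary there).
#' @return A `polarmir_pipeline` object: list with `contrasts` (per
#'   contrast: DE tables, summaries, shortlist, per-miRNA results, pooled
#'   enrichment), `summary`, `config`, `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  for (nm in c("mrna_p", "mirna_p", "r_threshold", "heatmap_q", "alpha",
               "ref_fraction")) {
    v <- th[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("Threshold `", nm, "` must lie in (0, 1).", call. = FALSE)
    }
  }
  get_input <- function(nm, reader, ...) {
    if (!is.null(config[[nm]])) return(config[[nm]])
    p <- config[[paste0(nm, "_path")]]
    if (is.null(p)) stop("Config must supply `", nm, "` or `", nm, "_path`.",
                         call. = FALSE)
    reader(p, ...)
  }
  mrna <- get_input("mrna", read_expression_matrix, feature_kind = "mRNA")
  mirna <- get_input("mirna", read_expression_matrix, feature_kind = "miRNA")
  sheet <- sample_sheet(get_input("samples", read_sample_sheet))
  db_a <- get_input("db_a", read_gmt, role = "targets")
  db_b <- get_input("db_b", read_gmt, role = "targets")
  annotations <- get_input("annotations", read_gmt, role = "annotation")
  if (is.null(config$reference_mirna)) {
    stop("Config must name `reference_mirna`.", call. = FALSE)
  }
  join_samples(mrna, sheet)
  join_samples(mirna, sheet)

  control <- config$control_condition %||% "M0"
  conditions <- unique(sheet$condition)
  contrasts <- config$contrasts %||%
    lapply(setdiff(conditions, control),
           function(trt) list(treated = trt, control = control))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  note("thresholds: ", paste(names(th), unlist(th), sep = "=", collapse = ", "))

  universe <- mrna$feature_id
  results <- list()
  for (ct in contrasts) {
    treated <- ct$treated; ctl <- ct$control %||% control
    if (identical(treated, ctl)) {
      stop("Contrast has treated == control ('", treated, "').", call. = FALSE)
    }
    if (!all(c(treated, ctl) %in% conditions)) {
      stop("Contrast references unknown condition(s): ",
           paste(setdiff(c(treated, ctl), conditions), collapse = ", "),
           call. = FALSE)
    }
    label <- paste0(treated, "_vs_", ctl)
    note("[", label, "] differential expression")
    de_mrna <- run_contrast(mrna, sheet, treated, ctl)
    de_mirna <- run_contrast(mirna, sheet, treated, ctl)
    sum_mrna <- summarize_contrast(de_mrna, th$mrna_p)
    sum_mirna <- summarize_contrast(de_mirna, th$mirna_p)
    heatmap_genes <- de_mrna$feature_id[de_mrna$q_value < th$heatmap_q]
    note("[", label, "] genes p<", th$mrna_p, ": ", sum_mrna$n_significant,
         "/", sum_mrna$n_tested, " (up ", sum_mrna$n_up, ", down ",
         sum_mrna$n_down, "); heatmap q<", th$heatmap_q, ": ",
         length(heatmap_genes))
    note("[", label, "] miRNAs p<", th$mirna_p, ": ",
         sum_mirna$n_significant, "/", sum_mirna$n_tested)
    shortlist <- select_mirnas(de_mirna, mirna, config$reference_mirna,
                               min_fraction = th$ref_fraction,
                               p_threshold = th$mirna_p)
    note("[", label, "] shortlisted miRNAs (>",
         100 * th$ref_fraction, "% of ", config$reference_mirna, "): ",
         nrow(shortlist))
    per_mirna <- list()
    enr_tables <- list()
    for (mi in shortlist$mirna_id) {
      cors <- correlate_mirna_genes(mirna, mrna, sheet, mi, c(treated, ctl))
      candidates <- filter_candidates(cors, de_mrna,
                                      r_threshold = th$r_threshold,
                                      p_threshold = th$mrna_p)
      set_a <- if (mi %in% names(db_a)) db_a[[mi]] else character(0)
      set_b <- if (mi %in% names(db_b)) db_b[[mi]] else character(0)
      overlap <- if (length(candidates) > 0) {
        overlap_fractions(candidates, set_a, set_b)
      } else NULL
      targets <- sort(intersect(intersect(candidates, set_a), set_b))
      interactome <- build_interactome(targets, cors, de_mrna)
      directions <- classify_directions(interactome)
      note("[", label, "] ", mi, ": correlated+DE ", length(candidates),
           " -> db_a ", length(set_a), " / db_b ", length(set_b),
           " -> triple ", length(targets), " (pos ",
           directions$n_positive, ", neg ", directions$n_negative, ")")
      if (nrow(interactome) > 0) {
        enr_tables[[mi]] <- enrich(interactome$gene_symbol, annotations,
                                   universe, mirna_id = mi)
      }
      per_mirna[[mi]] <- list(correlations = cors, candidates = candidates,
                              overlap = overlap, interactome = interactome,
                              directions = directions)
    }
    pooled <- if (length(enr_tables) > 0) {
      pool_and_rank(enr_tables, alpha = th$alpha, top_n = th$top_n)
    } else NULL
    results[[label]] <- list(
      treated = treated, control = ctl,
      de_mrna = de_mrna, de_mirna = de_mirna,
      summary_mrna = sum_mrna, summary_mirna = sum_mirna,
      heatmap_genes = heatmap_genes, shortlist = shortlist,
      per_mirna = per_mirna, enrichment = pooled
    )
  }

  summary <- lapply(results, function(res) {
    list(
      treated = res$treated, control = res$control,
      mrna = as.list(res$summary_mrna),
      mirna = as.list(res$summary_mirna),
      n_heatmap_genes = length(res$heatmap_genes),
      n_shortlisted_mirnas = nrow(res$shortlist),
      interactomes = lapply(res$per_mirna, function(pm) {
        list(n_candidates = length(pm$candidates),
             n_interactome = nrow(pm$interactome),
             n_positive = pm$directions$n_positive,
             n_negative = pm$directions$n_negative)
      })
    )
  })

  out <- structure(list(contrasts = results, summary = summary,
                        config = c(config["reference_mirna"],
                                   list(thresholds = th, control = control)),
                        log = log_lines,
                        dataset_id = attr(mrna, "dataset_id")),
                   class = "polarmir_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  out
}

#' @export
print.polarmir_pipeline <- function(x, ...) {
  cat("<polarmir pipeline> ", length(x$contrasts), " contrast(s): ",
      paste(names(x$contrasts), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Writes per-contrast DE tables, shortlists, per-miRNA interactomes,
#' pooled enrichment tables (all TSV), the stage log, and a JSON summary
#' of every count.
#'
#' @param pipeline A `polarmir_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (label in names(pipeline$contrasts)) {
    res <- pipeline$contrasts[[label]]
    readr::write_tsv(tibble::as_tibble(res$de_mrna),
                     file.path(out_dir, paste0("de_mrna_", label, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(res$de_mirna),
                     file.path(out_dir, paste0("de_mirna_", label, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(res$shortlist,
                     file.path(out_dir, paste0("mirna_shortlist_", label, ".tsv")),
                     progress = FALSE)
    for (mi in names(res$per_mirna)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", mi)
      write_interactome(res$per_mirna[[mi]]$interactome,
                        file.path(out_dir,
                                  paste0("interactome_", label, "_", safe, ".tsv")))
    }
    if (!is.null(res$enrichment)) {
      readr::write_tsv(tibble::as_tibble(res$enrichment),
                       file.path(out_dir, paste0("enrichment_", label, ".tsv")),
                       progress = FALSE)
    }
  }
  jsonlite::write_json(pipeline$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_lines(pipeline$log, file.path(out_dir, "pipeline_log.txt"))
  invisible(out_dir)
}

#' Tidy the interactomes of a pipeline run
#'
#' @param x A `polarmir_pipeline` object.
#' @param ... Unused.
#' @return Tibble of all interactome records across contrasts and miRNAs,
#'   with a `contrast` column.
#' @method tidy polarmir_pipeline
#' @export
tidy.polarmir_pipeline <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$contrasts), function(label) {
    res <- x$contrasts[[label]]
    dplyr::bind_rows(lapply(res$per_mirna, function(pm) {
      tibble::as_tibble(pm$interactome)
    })) |>
      dplyr::mutate(contrast = label, .before = 1)
  }))
}

#' One-row-per-contrast summary of a pipeline run
#'
#' @param x A `polarmir_pipeline` object.
#' @param ... Unused.
#' @return Tibble with one row per contrast: DE counts for both feature
#'   kinds, shortlist size, and interactome direction totals.
#' @method glance polarmir_pipeline
#' @export
glance.polarmir_pipeline <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$contrasts), function(label) {
    res <- x$contrasts[[label]]
    dirs <- dplyr::bind_rows(lapply(res$per_mirna, `[[`, "directions"))
    tibble::tibble(
      contrast = label,
      treated = res$treated,
      control = res$control,
      n_genes_tested = res$summary_mrna$n_tested,
      n_genes_significant = res$summary_mrna$n_significant,
      n_genes_up = res$summary_mrna$n_up,
      n_genes_down = res$summary_mrna$n_down,
      n_mirnas_significant = res$summary_mirna$n_significant,
      n_mirnas_shortlisted = nrow(res$shortlist),
      n_interactome = sum(vapply(res$per_mirna,
                                 function(pm) nrow(pm$interactome), 0L)),
      n_positive = sum(dirs$n_positive %||% 0L),
      n_negative = sum(dirs$n_negative %||% 0L)
    )
  }))
}
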
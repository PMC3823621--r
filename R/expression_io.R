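#' Normalize gene symbols to a canonical form
#'
#' Gene symbols arrive in mixed case conventions (array annotations often use
#' title case, prediction databases upper case). Set operations across sources
#' are only well-defined after mapping every symbol to a single canonical
#' form: trimmed and upper-cased.
#'
#' @param x Character vector of raw gene symbols.
#' @return Character vector of canonical (upper-case, trimmed) symbols.
#' @examples
#' normalize_symbol(c("Socs1 ", "xiap"))
#' @export
normalize_symbol <- function(x) {
  if (!is.character(x)) {
    stop("`x` must be a character vector of gene symbols.", call. = FALSE)
  }
  out <- toupper(trimws(x))
  bad <- !nzchar(out) | is.na(out)
  if (any(bad)) {
    stop("Empty or whitespace-only gene symbol at position ",
         paste(which(bad), collapse = ", "), ".", call. = FALSE)
  }
  out
}

#' Normalize miRNA identifiers to a canonical form
#'
#' miRNA ids come with or without a species prefix (`mmu-miR-155` vs
#' `miR-155`) and with inconsistent casing of the `miR` stem. The canonical
#' form drops the species prefix, lower-cases the id, and restores the
#' conventional `miR` casing. Star-form ids (`miR-191*`) keep their `*` and
#' remain distinct from their mates, as the arrays report them separately.
#'
#' @param x Character vector of raw miRNA identifiers.
#' @return Character vector of canonical miRNA ids.
#' @examples
#' normalize_mirna(c("mmu-miR-155", "MIR-191*", "let-7a"))
#' @export
normalize_mirna <- function(x) {
  if (!is.character(x)) {
    stop("`x` must be a character vector of miRNA ids.", call. = FALSE)
  }
  out <- trimws(x)
  bad <- !nzchar(out) | is.na(out)
  if (any(bad)) {
    stop("Empty or whitespace-only miRNA id at position ",
         paste(which(bad), collapse = ", "), ".", call. = FALSE)
  }
  out <- tolower(out)
  # species prefixes such as "mmu-", "hsa-" precede the mir/let stem
  out <- sub("^[a-z]{3}-(?=(mir|let))", "", out, perl = TRUE)
  out <- sub("^mir", "miR", out)
  out
}

#' Validated feature-by-sample expression container
#'
#' An expression matrix is stored as a tibble whose first column,
#' `feature_id`, holds canonical feature identifiers and whose remaining
#' columns hold one sample each, on log2 scale. The feature kind
#' (`"mRNA"` or `"miRNA"`) travels as an attribute and controls which
#' normalizer is applied to the ids.
#'
#' @param x A data frame with a `feature_id` first column and one numeric
#'   column per sample (log2 expression).
#' @param feature_kind Either `"mRNA"` or `"miRNA"`.
#' @return A tibble of class `polarmir_expr` with attribute `feature_kind`.
#' @export
expression_matrix <- function(x, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L || names(x)[1] != "feature_id") {
    stop("Expression data must have a `feature_id` first column and at least one sample column.",
         call. = FALSE)
  }
  ids <- if (feature_kind == "mRNA") normalize_symbol(x$feature_id) else normalize_mirna(x$feature_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("Duplicate feature id(s) after normalization: ",
         paste(utils::head(dup, 5L), collapse = ", "), ".", call. = FALSE)
  }
  samp <- names(x)[-1]
  if (anyDuplicated(samp)) {
    stop("Duplicate sample id(s): ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "), ".", call. = FALSE)
  }
  vals <- x[-1]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      stop("Sample column `", samp[j], "` is not numeric.", call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop("Non-finite value in sample `", samp[j], "`, row ",
           which(!is.finite(v))[1], ".", call. = FALSE)
    }
  }
  x$feature_id <- ids
  structure(x,
            class = c("polarmir_expr", class(tibble::tibble()))) |>
    `attr<-`("feature_kind", feature_kind)
}

#' @export
print.polarmir_expr <- function(x, ...) {
  cat("<polarmir expression matrix> ", attr(x, "feature_kind"), ", ",
      nrow(x), " features x ", ncol(x) - 1L, " samples\n", sep = "")
  NextMethod()
}

#' Extract the numeric value grid of an expression matrix
#'
#' @param em An [expression_matrix()].
#' @return Numeric matrix (features x samples) with feature ids as rownames.
#' @export
expr_values <- function(em) {
  stopifnot(inherits(em, "polarmir_expr"))
  m <- as.matrix(em[-1])
  rownames(m) <- em$feature_id
  m
}

#' Read a log2 expression matrix from TSV
#'
#' Expects tab-separated text with one header row: first column the feature
#' id, remaining columns one sample each. Values are parsed as numbers; a
#' non-numeric cell is a hard error reporting its row and column.
#'
#' @param path Path to a TSV file.
#' @param feature_kind `"mRNA"` or `"miRNA"`; selects the id normalizer.
#' @return A validated [expression_matrix()].
#' @export
read_expression_matrix <- function(path, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) {
    stop("Expression file must have a feature-id column and at least one sample column: ",
         path, call. = FALSE)
  }
  names(raw)[1] <- "feature_id"
  for (j in 2:ncol(raw)) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(num) & !is.na(raw[[j]]))
    if (length(bad) > 0L) {
      stop("Non-numeric value '", raw[[j]][bad[1]], "' at row ", bad[1],
           ", column '", names(raw)[j], "' of ", path, call. = FALSE)
    }
    if (anyNA(num)) {
      stop("Missing value at row ", which(is.na(num))[1], ", column '",
           names(raw)[j], "' of ", path, call. = FALSE)
    }
    raw[[j]] <- num
  }
  expression_matrix(raw, feature_kind)
}

#' Write an expression matrix to TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "polarmir_expr"))
  readr::write_tsv(tibble::as_tibble(em), path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Requires exactly the columns `sample_id`, `condition`, `replicate`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id` (unique), `condition` and
#'   `replicate` (positive integer).
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  sample_sheet(x)
}

#' Validate a sample sheet
#'
#' @param x Data frame with columns `sample_id`, `condition`, `replicate`.
#' @return A validated tibble.
#' @export
sample_sheet <- function(x) {
  x <- tibble::as_tibble(x)
  wanted <- c("sample_id", "condition", "replicate")
  extra <- setdiff(names(x), wanted)
  if (length(extra) > 0L) {
    stop("Unknown sample-sheet column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(wanted, names(x))
  if (length(missing) > 0L) {
    stop("Sample sheet is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) {
    stop("Duplicate sample_id(s): ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$replicate)) || any(x$replicate < 1)) {
    stop("`replicate` must be a positive integer.", call. = FALSE)
  }
  x
}

#' Check that a matrix and a sample sheet describe the same samples
#'
#' Every sample column of the matrix must appear exactly once in the sheet.
#'
#' @param em An [expression_matrix()].
#' @param sheet A [sample_sheet()].
#' @return The sheet restricted to the matrix samples, in matrix column order.
#' @export
join_samples <- function(em, sheet) {
  stopifnot(inherits(em, "polarmir_expr"))
  sheet <- sample_sheet(sheet)
  samp <- names(em)[-1]
  missing <- setdiff(samp, sheet$sample_id)
  if (length(missing) > 0L) {
    stop("Sample(s) in matrix but not in sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sheet[match(samp, sheet$sample_id), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then one member per field. Members are symbol-normalized and
#' deduplicated; for `role = "targets"` the set names are miRNA ids and are
#' normalized with [normalize_mirna()].
#'
#' @param path Path to a GMT file.
#' @param role `"targets"` for a miRNA prediction database, `"annotation"`
#'   for a gene-set annotation collection.
#' @param source_name Name for the collection; defaults to the file name.
#' @return A named list of character vectors of class `polarmir_genesets`,
#'   with attributes `role` and `source_name`.
#' @export
read_gmt <- function(path, role = c("targets", "annotation"),
                     source_name = basename(path)) {
  role <- match.arg(role)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(trimws(fields))]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " of ", path,
           " has fewer than 3 fields (name, description, >=1 member).",
           call. = FALSE)
    }
    nms[i] <- if (role == "targets") normalize_mirna(fields[1]) else trimws(fields[1])
    sets[[i]] <- sort(unique(normalize_symbol(fields[-(1:2)])))
  }
  if (anyDuplicated(nms)) {
    stop("Duplicate set name(s) in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nms
  gene_sets(sets, role = role, source_name = source_name)
}

#' Construct a validated gene-set collection
#'
#' @param sets Named list of character vectors (members are normalized and
#'   deduplicated).
#' @param role `"targets"` or `"annotation"`.
#' @param source_name Collection name.
#' @return A `polarmir_genesets` object.
#' @export
gene_sets <- function(sets, role = c("targets", "annotation"),
                      source_name = "genesets") {
  role <- match.arg(role)
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) sort(unique(normalize_symbol(s))))
  if (role == "targets") names(sets) <- normalize_mirna(names(sets))
  structure(sets, class = "polarmir_genesets",
            role = role, source_name = source_name)
}

#' @export
print.polarmir_genesets <- function(x, ...) {
  cat("<polarmir gene sets> ", attr(x, "source_name"), " (",
      attr(x, "role"), "), ", length(x), " sets\n", sep = "")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `polarmir_genesets` object or named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "source_name") %||% "na"
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a vector of available file names.
#' @export
polarmir_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "polarmir")))
  }
  p <- system.file("extdata", file, package = "polarmir")
  if (!nzchar(p)) stop("No packaged file called '", file, "'.", call. = FALSE)
  p
}
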
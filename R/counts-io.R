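#' Read a two-column HTSeq count file
#'
#' HTSeq writes one feature per line as `identifier<TAB>count`, followed by
#' summary rows whose identifiers start with `"__"` (`__no_feature`,
#' `__ambiguous`, ...). Summary rows are not annotated features and are
#' dropped from the returned table; their values are kept in the
#' `"summary_rows"` attribute so library-level bookkeeping is not lost.
#'
#' @param path Path to an HTSeq count file.
#'
#' @return A tibble with columns `gene_id` (character) and `count`
#'   (non-negative integer), one row per annotated feature, in file order.
#'   Attribute `"summary_rows"` holds the excluded `__*` rows as a named
#'   integer vector.
#' @export
#'
#' @examples
#' f <- tempfile()
#' writeLines(c("geneA\t5", "geneB\t0", "__no_feature\t100"), f)
#' read_htseq_counts(f)
read_htseq_counts <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("HTSeq count file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0L) {
    out <- tibble(gene_id = character(), count = integer())
    attr(out, "summary_rows") <- integer()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    abort(paste0("malformed HTSeq line ", bad[1L],
                 " (expected 'identifier<TAB>integer'): ", lines[bad[1L]]))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  count_chr <- vapply(parts, `[[`, character(1), 2L)
  ok <- grepl("^-?[0-9]+$", count_chr)
  if (any(!ok)) {
    i <- which(!ok)[1L]
    abort(paste0("malformed HTSeq line ", i,
                 " (count is not an integer): ", lines[i]))
  }
  counts <- as.integer(count_chr)
  if (any(counts < 0L)) {
    i <- which(counts < 0L)[1L]
    abort(paste0("negative count on line ", i, ": ", lines[i]))
  }
  summary_row <- startsWith(ids, "__")
  out <- tibble(gene_id = ids[!summary_row], count = counts[!summary_row])
  attr(out, "summary_rows") <- setNames(counts[summary_row], ids[summary_row])
  out
}

#' Assemble a time-ordered count matrix from per-sample count tables
#'
#' Combines one count table per sample (as returned by
#' [read_htseq_counts()]) into the genes-by-samples count tibble that the
#' rest of the pipeline consumes. Columns are ordered by sampling time and
#' genes lexicographically, so the result does not depend on the order in
#' which samples are supplied.
#'
#' @param per_sample Named list of tibbles with columns `gene_id`, `count`;
#'   names are sample ids. All tables must share an identical gene universe.
#' @param samples Sample sheet: tibble with columns `sample_id`,
#'   `time_minutes`, one row per entry of `per_sample`.
#'
#' @return A list with elements `counts` (tibble: `gene_id` plus one numeric
#'   column per sample, columns in increasing time order) and `samples` (the
#'   sample sheet sorted by time).
#' @export
assemble_count_matrix <- function(per_sample, samples) {
  if (length(per_sample) < 2L) {
    abort("at least 2 samples are required")
  }
  if (is.null(names(per_sample)) || any(names(per_sample) == "")) {
    abort("`per_sample` must be a named list (names are sample ids)")
  }
  samples <- validate_sample_sheet(samples)
  if (!setequal(names(per_sample), samples$sample_id)) {
    abort("sample ids in `per_sample` and `samples` do not match")
  }
  if (anyDuplicated(samples$time_minutes)) {
    abort("duplicate time_minutes in sample sheet")
  }
  universe <- sort(per_sample[[1L]]$gene_id)
  for (nm in names(per_sample)) {
    ids <- per_sample[[nm]]$gene_id
    if (anyDuplicated(ids)) {
      abort(paste0("duplicate gene ids in sample ", nm))
    }
    if (!setequal(ids, universe)) {
      diff <- c(setdiff(ids, universe), setdiff(universe, ids))
      abort(paste0("gene universes differ (sample ", nm, "); ",
                   "symmetric difference: ",
                   paste(sort(unique(diff)), collapse = ", ")))
    }
  }
  samples <- arrange(samples, .data$time_minutes)
  counts <- tibble(gene_id = universe)
  for (nm in samples$sample_id) {
    tab <- per_sample[[nm]]
    counts[[nm]] <- tab$count[match(universe, tab$gene_id)]
  }
  validate_count_matrix(counts, samples)
  list(counts = counts, samples = samples)
}

#' Write / read a count matrix as TSV with a sample-sheet sidecar
#'
#' The matrix TSV has `gene_id` as its first column and one column per
#' sample; sample times travel in a sidecar TSV (`sample_id`,
#' `time_minutes`) because the matrix header cannot carry them. Writing then
#' reading is the identity on the counts up to numeric formatting (readr
#' emits shortest round-trip representations, so doubles survive exactly).
#'
#' @param counts Count tibble (`gene_id` + one numeric column per sample).
#' @param samples Sample sheet tibble (`sample_id`, `time_minutes`).
#' @param path Path of the matrix TSV.
#' @param sample_path Path of the sample-sheet TSV; default `path` with a
#'   `.samples.tsv` suffix.
#'
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   returns a list with `counts` and `samples` as in
#'   [assemble_count_matrix()].
#' @export
write_matrix_tsv <- function(counts, samples, path,
                             sample_path = paste0(path, ".samples.tsv")) {
  validate_count_matrix(counts, samples)
  readr::write_tsv(counts, path)
  readr::write_tsv(samples, sample_path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, sample_path = paste0(path, ".samples.tsv")) {
  counts <- suppressWarnings(readr::read_tsv(path, show_col_types = FALSE))
  if (nrow(readr::problems(counts)) > 0L) {
    abort(paste0("malformed matrix TSV (ragged or mistyped rows): ", path))
  }
  if (names(counts)[1L] != "gene_id") {
    abort("matrix TSV must have 'gene_id' as its first column")
  }
  samples <- readr::read_tsv(sample_path, show_col_types = FALSE)
  samples <- validate_sample_sheet(samples)
  validate_count_matrix(counts, samples)
  list(counts = counts, samples = samples)
}

# ---- validation helpers ----------------------------------------------------

validate_sample_sheet <- function(samples) {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "time_minutes") %in% names(samples))) {
    abort("sample sheet needs columns sample_id, time_minutes")
  }
  samples <- as_tibble(samples)
  if (any(!nzchar(samples$sample_id)) || anyDuplicated(samples$sample_id)) {
    abort("sample ids must be nonempty and unique")
  }
  if (any(!is.finite(samples$time_minutes)) || any(samples$time_minutes < 0)) {
    abort("time_minutes must be finite and nonnegative")
  }
  samples
}

validate_count_matrix <- function(counts, samples) {
  if (!is.data.frame(counts) || names(counts)[1L] != "gene_id") {
    abort("count matrix must be a data frame with first column gene_id")
  }
  if (anyDuplicated(counts$gene_id)) {
    abort("duplicate gene_ids in count matrix")
  }
  value_cols <- setdiff(names(counts), "gene_id")
  if (!identical(value_cols, samples$sample_id[order(samples$time_minutes)])) {
    if (!setequal(value_cols, samples$sample_id)) {
      abort("count matrix columns and sample sheet do not match")
    }
    abort("count matrix columns must be ordered by increasing time_minutes")
  }
  vals <- as.matrix(counts[value_cols])
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    abort("count values must be nonnegative finite numbers")
  }
  invisible(TRUE)
}

# genes x samples numeric matrix (rownames = gene ids) from a count tibble
count_values <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  m
}
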
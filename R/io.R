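# File readers and the report writer. Wide TSV/CSV, genes as rows, samples
# as columns; delimiter inferred from the extension unless given.

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Read a wide gene x sample table as character cells, then convert with
# cell-level error reporting (row/column coordinates on failure).
read_wide_numeric <- function(path, sep, what = "value",
                              allow_missing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (ncol(raw) < 2) stop("expected a gene id column plus sample columns")
  gene_ids <- trimws(raw[[1]])
  sample_ids <- trimws(colnames(raw)[-1])
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells <- trimws(cells)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  blank <- cells == "" | toupper(cells) %in% c("NA", "NAN")
  bad <- which(is.na(num) & !blank, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric %s '%s' at gene '%s', sample '%s'",
                 what, cells[bad[1, 1], bad[1, 2]],
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  }
  if (!allow_missing && any(blank))
    stop(sprintf("missing %s at gene '%s'", what,
                 gene_ids[which(rowSums(blank) > 0)[1]]))
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Read an expression matrix from a wide TSV/CSV file
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#' Row and column order are preserved as in the file. Duplicate identifiers,
#' non-numeric cells (reported with their coordinates) and negative values
#' are hard errors.
#'
#' @param path Path to the file.
#' @param sep Field delimiter; inferred from the extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  sep <- infer_sep(path, sep)
  num <- read_wide_numeric(path, sep, what = "FPKM", allow_missing = FALSE)
  expression_matrix(num)
}

#' Read a Cq table and its sample metadata
#'
#' The Cq file is wide (genes as rows, samples as columns); empty cells are
#' read as missing, never as zero. The metadata file must provide columns
#' `sample_id`, `group` and `condition` covering every Cq sample; a sample
#' absent from the metadata is a hard error naming it. Genes with fewer than
#' 3 present values are kept but flagged with a warning.
#'
#' @param cq_path Path to the wide Cq file.
#' @param metadata_path Path to the metadata file.
#' @param sep Field delimiter; inferred from each file's extension when
#'   `NULL`.
#' @return A [cq_table()].
#' @export
read_cq_table <- function(cq_path, metadata_path, sep = NULL) {
  num <- read_wide_numeric(cq_path, infer_sep(cq_path, sep), what = "Cq",
                           allow_missing = TRUE)
  if (!file.exists(metadata_path))
    stop("file not found: ", metadata_path)
  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = infer_sep(metadata_path, sep),
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"")
  cq_table(num, meta)
}

#' Write a pipeline result to a TSV report
#'
#' Serializes any pipeline result (stability results, consensus rankings,
#' screening tables, quantification tables, plain data frames) as a TSV with
#' a deterministic column order and floats at 6 significant digits, so that
#' re-reading reproduces the values to that precision. An empty result
#' yields a header-only file.
#'
#' @param results A pipeline result object or data frame.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_report <- function(results, path) {
  df <- as.data.frame(results)
  num_cols <- vapply(df, is.numeric, logical(1))
  df[num_cols] <- lapply(df[num_cols], signif, digits = 6)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write report to '", path, "': ", conditionMessage(ok))
  invisible(df)
}
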
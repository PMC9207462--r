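#' Analysis configuration
#'
#' Bundles the tunable thresholds and numeric conventions used throughout the
#' pipeline. All fields have defaults matching the screening criteria of the
#' workflow (mean FPKM above 50, maximum fold change below 1.5, coefficient
#' of variation below 0.1) and the standard qPCR conventions (amplification
#' base 2, log base 2, sample standard deviation).
#'
#' @param mv_min Minimum mean FPKM a gene must exceed to pass screening
#'   (strict inequality). Default 50.
#' @param mfc_max Maximum fold change (max/min FPKM) a gene must stay below
#'   (strict). Default 1.5.
#' @param cv_max Coefficient of variation (SD/mean) a gene must stay below
#'   (strict). Default 0.1.
#' @param efficiency_default Amplification base E used when converting Cq to
#'   relative quantities; 2.0 corresponds to 100% PCR efficiency. Must lie in
#'   (1, 3].
#' @param log_base Base for the log transform of relative quantities
#'   (geNorm/NormFinder work on log-scale data). Default 2.
#' @param sd_mode Either `"sample"` (n-1 denominator, the default) or
#'   `"population"` (n denominator); applied everywhere a standard deviation
#'   is computed.
#' @param tie_method Rank tie handling; only `"fractional"` (mean rank) is
#'   supported.
#' @param rng_seed Optional integer seed recorded for reproducibility.
#'
#' @return An object of class `analysis_config`.
#' @examples
#' cfg <- analysis_config(mv_min = 50, mfc_max = 1.5, cv_max = 0.1)
#' @export
analysis_config <- function(mv_min = 50, mfc_max = 1.5, cv_max = 0.1,
                            efficiency_default = 2.0, log_base = 2,
                            sd_mode = c("sample", "population"),
                            tie_method = "fractional", rng_seed = NULL) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(is.numeric(mv_min), is.numeric(mfc_max), is.numeric(cv_max))
  if (mv_min <= 0 || mfc_max <= 0 || cv_max <= 0)
    stop("screening thresholds must be strictly positive")
  if (!(efficiency_default > 1 && efficiency_default <= 3))
    stop("efficiency_default must lie in (1, 3]")
  if (!identical(tie_method, "fractional"))
    stop("only tie_method = 'fractional' is supported")
  structure(
    list(mv_min = mv_min, mfc_max = mfc_max, cv_max = cv_max,
         efficiency_default = efficiency_default, log_base = log_base,
         sd_mode = sd_mode, tie_method = tie_method, rng_seed = rng_seed),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a flat YAML file
#'
#' Every field is optional; omitted fields take the defaults of
#' [analysis_config()].
#'
#' @param path Path to a flat key/value YAML file.
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    # flat key: value fallback parser
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(lines, ":", fixed = TRUE)
    vals <- lapply(kv, function(p) {
      v <- trimws(paste(p[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    names(vals) <- trimws(vapply(kv, `[[`, "", 1))
    vals
  }
  known <- names(formals(analysis_config))
  vals <- vals[intersect(names(vals), known)]
  do.call(analysis_config, vals)
}

#' Construct a validated expression matrix
#'
#' A genes-by-samples matrix of non-negative FPKM values with unique row and
#' column identifiers, the substrate of candidate screening.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids Optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return A numeric matrix of class `expression_matrix` with gene row names
#'   and sample column names.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2), c("g1", "g2", "g3"), c("s1", "s2"))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- trimws(as.character(gene_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", quoted_list(dup_g))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", quoted_list(dup_s))
  if (ncol(values) < 2) stop("an expression matrix needs at least 2 samples")
  if (anyNA(values)) stop("expression values must not be missing")
  if (any(values < 0)) stop("expression (FPKM) values must be non-negative")
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Construct a validated Cq table
#'
#' A genes-by-samples matrix of quantification-cycle values joined with
#' per-sample metadata. Missing Cq values ("no amplification") are `NA`,
#' never zero, and are excluded pairwise by downstream computations.
#'
#' @param cq Numeric matrix of Cq values (PCR cycles), genes in rows,
#'   samples in columns; entries may be `NA`.
#' @param metadata Data frame with one row per sample and columns
#'   `sample_id`, `group`, `condition` (levels "control"/"experiment"),
#'   optionally `tissue`, `cultivar`, `replicate`.
#' @return A list of class `cq_table` with elements `cq` (matrix) and
#'   `metadata` (data frame, one row per Cq column, in column order). Genes
#'   with fewer than 3 present values are flagged in
#'   `attr(, "flagged_genes")` with a warning.
#' @export
cq_table <- function(cq, metadata) {
  cq <- as.matrix(cq)
  storage.mode(cq) <- "double"
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop("cq matrix must carry gene row names and sample column names")
  rownames(cq) <- trimws(rownames(cq))
  colnames(cq) <- trimws(colnames(cq))
  if (anyDuplicated(rownames(cq)))
    stop("duplicate gene identifiers: ",
         quoted_list(unique(rownames(cq)[duplicated(rownames(cq))])))
  if (anyDuplicated(colnames(cq)))
    stop("duplicate sample identifiers: ",
         quoted_list(unique(colnames(cq)[duplicated(colnames(cq))])))
  if (any(!is.na(cq) & !is.finite(cq)))
    stop("present Cq values must be finite")
  present <- is.finite(cq)
  if (any(cq[present] <= 0))
    stop("present Cq values must be finite and > 0")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "condition")
  miss_cols <- setdiff(req, names(metadata))
  if (length(miss_cols))
    stop("metadata lacks required column(s): ", quoted_list(miss_cols))
  metadata$sample_id <- trimws(as.character(metadata$sample_id))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata: ",
         quoted_list(unique(metadata$sample_id[duplicated(metadata$sample_id)])))
  missing_meta <- setdiff(colnames(cq), metadata$sample_id)
  if (length(missing_meta))
    stop("sample(s) missing from metadata: ", quoted_list(missing_meta))
  metadata <- metadata[match(colnames(cq), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  flagged <- rownames(cq)[rowSums(present) < 3]
  if (length(flagged))
    warning("gene(s) with fewer than 3 present Cq values: ",
            quoted_list(flagged))
  structure(list(cq = cq, metadata = metadata),
            class = "cq_table", flagged_genes = flagged)
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> %d genes x %d samples, %d missing Cq\n",
              nrow(x$cq), ncol(x$cq), sum(!is.finite(x$cq))))
  cat("groups: ", paste(unique(x$metadata$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}
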
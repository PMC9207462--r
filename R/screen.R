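#' Per-gene screening statistics from an expression matrix
#'
#' Computes, for every gene, the mean FPKM (MV), standard deviation (SD),
#' maximum fold change (MFC = max/min) and coefficient of variation
#' (CV = SD/MV) across samples, and whether the gene passes the screening
#' thresholds: MV strictly greater than `mv_min`, MFC strictly less than
#' `mfc_max` and CV strictly less than `cv_max`. A gene whose minimum FPKM
#' is zero has an undefined MFC and cannot pass; a gene whose mean is zero
#' has an undefined CV and cannot pass.
#'
#' Every column is treated as one sample; replicate averaging, if wanted,
#' is a pre-step the caller performs before building the matrix.
#'
#' @param matrix An [expression_matrix()].
#' @param config An [analysis_config()]; supplies the thresholds and the SD
#'   convention.
#' @return A data frame of class `screen_stats` with columns `gene`, `mv`,
#'   `sd`, `mfc`, `cv`, `passes`, one row per gene in matrix order.
#' @examples
#' m <- expression_matrix(rbind(stable = c(100, 102, 98, 100),
#'                              wobbly = c(50, 100, 75, 80)),
#'                        sample_ids = paste0("s", 1:4))
#' screen_stats(m, analysis_config())
#' @export
screen_stats <- function(matrix, config = analysis_config()) {
  if (!inherits(matrix, "expression_matrix")) matrix <- expression_matrix(matrix)
  if (ncol(matrix) < 2)
    stop("screening needs at least 2 samples (SD undefined otherwise)")
  vals <- unclass(matrix)
  mv <- rowMeans(vals)
  sdv <- apply(vals, 1, sd_by_mode, mode = config$sd_mode)
  mn <- apply(vals, 1, min)
  mx <- apply(vals, 1, max)
  mfc <- ifelse(mn > 0, mx / mn, NA_real_)
  cv <- ifelse(mv > 0, sdv / mv, NA_real_)
  passes <- !is.na(mfc) & !is.na(cv) &
    mv > config$mv_min & mfc < config$mfc_max & cv < config$cv_max
  out <- data.frame(gene = rownames(vals), mv = mv, sd = sdv,
                    mfc = mfc, cv = cv, passes = passes,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("screen_stats", class(out))
  out
}

#' Select candidate reference genes from screening statistics
#'
#' Filters to genes that pass all thresholds, orders them from the least to
#' the highest SD (most to least stable) with lexicographic gene-id
#' tie-break, and optionally truncates to the top `top_n`. The published
#' workflow follows this ranked list with a manual, annotation-based
#' curation step; `top_n` is the programmatic stand-in for that external
#' curation.
#'
#' @param stats A `screen_stats` data frame from [screen_stats()].
#' @param config Unused placeholder for interface symmetry; thresholds are
#'   already baked into `stats$passes`.
#' @param top_n Optional cap on the number of returned genes.
#' @return Character vector of gene ids, ascending SD; possibly empty.
#' @export
select_candidates <- function(stats, config = analysis_config(), top_n = NULL) {
  if (!nrow(stats)) stop("empty screening table")
  keep <- stats[stats$passes, , drop = FALSE]
  keep <- keep[order(keep$sd, keep$gene), , drop = FALSE]
  ids <- keep$gene
  if (!is.null(top_n)) {
    stopifnot(top_n >= 1)
    ids <- utils::head(ids, top_n)
  }
  ids
}
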
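#' BestKeeper descriptive stability
#'
#' Ranks candidates by the spread of their raw Cq values and reports the
#' classic BestKeeper descriptors. The BestKeeper index is the per-sample
#' geometric mean of the Cq of all input genes (the correlated gene is
#' included, no leave-one-out), computed on complete-case samples (samples
#' where every gene is present). Per-gene descriptors (mean, geometric
#' mean, min, max, SD, CV% = 100 * SD / mean) use each gene's own present
#' values; the Pearson correlation against the index uses the complete-case
#' samples.
#'
#' The stability value is the SD of Cq (ascending = more stable). Setting
#' `use_mad = TRUE` switches the stability value to the mean absolute
#' deviation around the arithmetic mean, a variant found in some
#' descriptions of the method; the choice is logged.
#'
#' @param cq A [cq_table()].
#' @param config An [analysis_config()].
#' @param use_mad Use mean absolute deviation instead of SD as the
#'   stability value (default `FALSE`).
#' @return A `stability_result` (method `"bestkeeper"`, values in cycles);
#'   `extras$descriptors` is the per-gene table and `extras$index` the
#'   per-sample BestKeeper index.
#' @export
bestkeeper <- function(cq, config = analysis_config(), use_mad = FALSE) {
  stopifnot(inherits(cq, "cq_table"))
  x <- cq$cq
  genes <- rownames(x)
  if (length(genes) < 2) stop("BestKeeper needs at least 2 genes")
  complete <- colSums(!is.finite(x)) == 0
  if (sum(complete) < 3)
    stop("BestKeeper needs at least 3 complete-case samples (have ",
         sum(complete), ")")
  idx <- apply(x[, complete, drop = FALSE], 2, geomean)
  per_gene <- lapply(genes, function(g) {
    v <- x[g, ]
    v <- v[is.finite(v)]
    s <- sd_by_mode(v, config$sd_mode)
    mad_v <- mean(abs(v - mean(v)))
    r <- suppressWarnings(
      stats::cor(x[g, complete], idx, method = "pearson"))
    data.frame(gene = g, n = length(v), mean = mean(v), geo_mean = geomean(v),
               min = min(v), max = max(v), sd = s, mad = mad_v,
               cv_pct = 100 * s / mean(v), r_index = r,
               stringsAsFactors = FALSE)
  })
  desc <- do.call(rbind, per_gene)
  refstab_log("BestKeeper stability value: ",
              if (use_mad) "mean absolute deviation" else "sample SD of Cq")
  stab <- setNames(if (use_mad) desc$mad else desc$sd, genes)
  stability_result("bestkeeper", stab,
                   extras = list(descriptors = desc, index = idx,
                                 stat = if (use_mad) "mad" else "sd"))
}
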
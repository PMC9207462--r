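#' Comparative delta-Ct stability
#'
#' For every gene pair (i, j) the standard deviation across samples of the
#' Cq difference Cq_i - Cq_j is computed; the stability value of gene i is
#' the mean of these pairwise SDs over all j != i. A gene that keeps a
#' constant offset to every other gene gets stability 0. Pairs are computed
#' on the samples where both genes are present; a pair with fewer than 3
#' common samples is skipped with a warning and excluded from the mean.
#'
#' @param cq A [cq_table()].
#' @param config An [analysis_config()]; supplies the SD convention.
#' @return A `stability_result` (method `"delta_ct"`, values in cycles);
#'   `extras$pairwise_sd` holds the full gene x gene SD matrix.
#' @export
delta_ct_stability <- function(cq, config = analysis_config()) {
  stopifnot(inherits(cq, "cq_table"))
  x <- cq$cq
  genes <- rownames(x)
  G <- length(genes)
  if (G < 2) stop("delta-Ct stability needs at least 2 genes")
  sd_mat <- matrix(NA_real_, G, G, dimnames = list(genes, genes))
  skipped <- character(0)
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      both <- is.finite(x[i, ]) & is.finite(x[j, ])
      if (sum(both) < 3) {
        skipped <- c(skipped, paste0(genes[i], "/", genes[j]))
        next
      }
      s <- sd_by_mode(x[i, both] - x[j, both], config$sd_mode)
      sd_mat[i, j] <- sd_mat[j, i] <- s
    }
  }
  if (length(skipped))
    warning("pair(s) skipped (< 3 common samples): ", quoted_list(skipped))
  stab <- vapply(seq_len(G), function(i) {
    vals <- sd_mat[i, -i]
    if (all(is.na(vals)))
      stop("gene '", genes[i], "' has no usable pair")
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  names(stab) <- genes
  stability_result("delta_ct", stab, extras = list(pairwise_sd = sd_mat))
}
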
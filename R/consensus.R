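#' RefFinder-style consensus ranking
#'
#' Combines the rankings of two to four stability methods into a
#' comprehensive ranking: each gene's consensus score is the geometric mean
#' of its per-method ranks (the methods' "weights"), and the final order is
#' ascending in that geometric mean. Fractional ranks coming from ties
#' (e.g. geNorm's 1.5/1.5 pair) enter the geometric mean as-is. Final ties
#' get fractional ranks; row order breaks remaining ties by gene id.
#'
#' @param results A list of 2-4 `stability_result` objects covering the
#'   same gene set (order-insensitive).
#' @return A data frame of class `consensus_ranking`, one row per gene,
#'   ordered by the final rank, with one `rank_<method>` column per input
#'   method plus `geomean` and `final_rank`.
#' @examples
#' ## a gene ranked 1, 2, 4 and 8 by the four methods has consensus score
#' ## (1*2*4*8)^(1/4) = 2.8284
#' @export
reffinder_consensus <- function(results) {
  if (inherits(results, "stability_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "stability_result")))
  m <- length(results)
  if (m < 2 || m > 4)
    stop("consensus needs between 2 and 4 method results (got ", m, ")")
  gene_sets <- lapply(results, function(r) sort(names(r$stability)))
  for (i in seq_len(m - 1)) {
    a <- gene_sets[[i]]; b <- gene_sets[[i + 1]]
    diff <- union(setdiff(a, b), setdiff(b, a))
    if (length(diff))
      stop("method results cover different gene sets; symmetric difference: ",
           quoted_list(sort(diff)))
  }
  genes <- sort(names(results[[1]]$stability))
  methods <- vapply(results, `[[`, "", "method")
  if (anyDuplicated(methods))
    methods <- make.unique(methods, sep = "_")
  ranks <- vapply(results, function(r) r$rank[genes], numeric(length(genes)))
  ranks <- matrix(ranks, nrow = length(genes),
                  dimnames = list(genes, paste0("rank_", methods)))
  gm <- apply(ranks, 1, geomean)
  final <- rank(gm, ties.method = "average")
  out <- data.frame(gene = genes, ranks, geomean = gm,
                    final_rank = final, row.names = NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(out$geomean, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "methods") <- methods
  class(out) <- c("consensus_ranking", class(out))
  out
}
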
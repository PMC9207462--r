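#' geNorm M-value stability with stepwise exclusion
#'
#' For genes j and k the pairwise variation V_jk is the standard deviation
#' across samples of log2(q_j / q_k); the M-value of gene j is the mean of
#' V_jk over all k != j. The least stable gene (highest M) is removed and
#' all M-values recomputed, repeatedly, until two genes remain; these final
#' two cannot be ordered by the algorithm and are tied at rank 1.5.
#'
#' The stability value reported for each gene is its M at the step it was
#' removed (the two survivors keep their M from the last elimination
#' round, i.e. the three-gene step). Because M is built from
#' log-ratios, multiplying one gene's quantities by a constant — or adding
#' a per-sample constant to all Cq values — leaves every M unchanged.
#'
#' Ties in the removal choice (equal maximum M) are broken by removing the
#' lexicographically last gene id, which makes the procedure deterministic.
#'
#' @param q An `rq_matrix` from [cq_to_relative_quantity()], a [cq_table()]
#'   (converted with the config default efficiency), or a bare genes x
#'   samples matrix of relative quantities.
#' @param config An [analysis_config()]; supplies the log base and SD
#'   convention.
#' @param pairwise_variation Also compute V(n/n+1), the SD of the log-ratio
#'   of normalization factors built from the n and n+1 most stable genes
#'   (default `TRUE`). The conventional V < 0.15 guideline for "enough
#'   references" is reported, never decided on.
#' @return A `stability_result` (method `"genorm"`, values are M);
#'   `extras$removal_order` (first removed = least stable),
#'   `extras$m_steps` (M of each gene at its removal step) and
#'   `extras$pairwise_variation` (data frame with columns `n` and `v` for
#'   V(n/n+1)) when requested.
#' @export
genorm <- function(q, config = analysis_config(), pairwise_variation = TRUE) {
  rq <- as_rq(q, config)
  y <- log(rq$q, base = config$log_base)
  genes <- rownames(y)
  G <- length(genes)
  if (G < 3) stop("geNorm needs at least 3 genes")
  pair_v <- function(a, b) {
    both <- is.finite(y[a, ]) & is.finite(y[b, ])
    if (sum(both) < 3)
      stop("gene pair '", a, "'/'", b, "' has fewer than 3 common samples")
    sd_by_mode(y[a, both] - y[b, both], config$sd_mode)
  }
  m_values <- function(active) {
    V <- outer(active, active, Vectorize(function(a, b)
      if (a == b) NA_real_ else pair_v(a, b)))
    rowMeans(V, na.rm = TRUE)
  }
  active <- genes
  removal_order <- character(0)
  m_at_removal <- setNames(numeric(G), genes)
  while (length(active) > 2) {
    M <- setNames(m_values(active), active)
    worst_m <- max(M)
    tied <- active[M == worst_m]
    drop_gene <- sort(tied)[length(tied)]
    m_at_removal[drop_gene] <- worst_m
    removal_order <- c(removal_order, drop_gene)
    active <- setdiff(active, drop_gene)
    # survivors keep the M of the last elimination round
    m_at_removal[active] <- M[active]
  }
  # ranking: survivors tied at 1.5, then reverse removal order
  rank_v <- setNames(numeric(G), genes)
  rank_v[active] <- 1.5
  rank_v[rev(removal_order)] <- seq(3, length.out = length(removal_order))
  extras <- list(removal_order = removal_order,
                 m_steps = m_at_removal)
  if (pairwise_variation && G >= 3) {
    stable_order <- c(sort(active), rev(removal_order))
    v_tab <- do.call(rbind, lapply(2:(G - 1), function(n) {
      top_n <- stable_order[seq_len(n)]
      top_n1 <- stable_order[seq_len(n + 1)]
      ok <- colSums(!is.finite(rq$q[top_n1, , drop = FALSE])) == 0
      nf_n <- apply(rq$q[top_n, ok, drop = FALSE], 2, geomean)
      nf_n1 <- apply(rq$q[top_n1, ok, drop = FALSE], 2, geomean)
      data.frame(n = n,
                 v = sd_by_mode(log(nf_n / nf_n1, base = config$log_base),
                                config$sd_mode))
    }))
    extras$pairwise_variation <- v_tab
  }
  stability_result("genorm", m_at_removal[genes], rank_v[genes],
                   extras = extras)
}
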
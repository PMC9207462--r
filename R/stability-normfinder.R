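#' NormFinder variance-decomposition stability
#'
#' Models the log2 relative quantities y(g, s) as gene effect + sample
#' effect + gene-by-group interaction + residual and scores each gene by an
#' estimate of how much it deviates between groups and fluctuates within
#' them.
#'
#' With two or more groups the stability of gene g is
#' \deqn{\rho_g = \frac{1}{I}\sum_i \left(|\tilde d_{g,i}| +
#'   \sqrt{\hat\sigma^2_{g,i}/n_i}\right)}
#' where d_{g,i} is the intergroup deviation (the group-i mean of gene g,
#' double-centred on gene and group means), sigma^2_{g,i} the intragroup
#' error variance and d-tilde the variance-shrunken deviation
#' d * gamma^2 / (gamma^2 + sigma^2/n) with
#' gamma^2 = max(0, Var_g(d_{g,i}) - mean_g(sigma^2_{g,i}/n_i)) estimated
#' per group; when gamma^2 = 0 the shrunken deviations collapse to zero.
#' With a single group (or no group labels) the stability is simply
#' sqrt(sigma^2_g), the intragroup SD after removing gene and per-sample
#' means.
#'
#' The intragroup variance uses the two-way residuals within each group,
#' debiased for the gene-specific case as
#' sigma^2_{g,i} = max(0, (v_{g,i} - vbar_i/(k-1)) * k/(k-2)) with v the raw
#' residual variance and k the number of genes; this is why at least 3
#' genes are required. Only complete cases within each group (samples with
#' every gene present) are used.
#'
#' @param q An `rq_matrix`, [cq_table()] or bare quantity matrix (see
#'   [genorm()] for the accepted forms).
#' @param groups Per-sample group labels (recycled from the Cq metadata
#'   `group` column when `q` carries metadata and `groups` is `NULL`).
#'   Pass `NA` or a single-level vector for the ungrouped analysis.
#' @param config An [analysis_config()].
#' @return A `stability_result` (method `"normfinder"`); `extras$d` and
#'   `extras$sigma2` are the per-gene-per-group intergroup deviations and
#'   intragroup variances (with >= 2 groups), `extras$groups` the labels
#'   used.
#' @export
normfinder <- function(q, groups = NULL, config = analysis_config()) {
  rq <- as_rq(q, config)
  y <- log(rq$q, base = config$log_base)
  genes <- rownames(y)
  G <- length(genes)
  if (G < 3) stop("NormFinder needs at least 3 genes")
  if (is.null(groups) && !is.null(rq$metadata)) groups <- rq$metadata$group
  if (is.null(groups) || all(is.na(groups)))
    groups <- rep("all", ncol(y))
  groups <- as.character(groups)
  if (length(groups) != ncol(y))
    stop("need one group label per sample")
  lev <- unique(groups)

  # per-group complete-case variance components
  grp_stats <- lapply(lev, function(gr) {
    cols <- which(groups == gr)
    ok <- cols[colSums(!is.finite(y[, cols, drop = FALSE])) == 0]
    if (length(ok) < 2)
      stop("group '", gr, "' has fewer than 2 complete samples")
    z <- y[, ok, drop = FALSE]
    n <- ncol(z)
    gene_mean <- rowMeans(z)
    samp_mean <- colMeans(z)
    resid <- z - outer(gene_mean, rep(1, n)) -
      outer(rep(1, G), samp_mean) + mean(z)
    v <- rowSums(resid^2) / (n - 1)
    sigma2 <- pmax(0, (v - mean(v) / (G - 1)) * G / (G - 2))
    list(group = gr, n = n, gene_mean = gene_mean, sigma2 = sigma2)
  })
  names(grp_stats) <- lev

  if (length(lev) < 2) {
    stab <- sqrt(grp_stats[[1]]$sigma2)
    names(stab) <- genes
    return(stability_result("normfinder", stab,
                            extras = list(groups = groups,
                                          sigma2 = grp_stats[[1]]$sigma2)))
  }

  gm <- vapply(grp_stats, `[[`, numeric(G), "gene_mean")   # genes x groups
  n_i <- vapply(grp_stats, `[[`, numeric(1), "n")
  sig2 <- vapply(grp_stats, `[[`, numeric(G), "sigma2")    # genes x groups
  # intergroup deviation: double-centre the gene-by-group means
  d <- gm - rowMeans(gm)
  d <- sweep(d, 2, colMeans(d))
  # per-group shrinkage toward zero
  se2 <- sweep(sig2, 2, n_i, "/")                           # sigma^2 / n
  d_shrunk <- d
  for (j in seq_along(lev)) {
    gamma2 <- max(0, sum(d[, j]^2) / (G - 1) - mean(se2[, j]))
    d_shrunk[, j] <- if (gamma2 > 0)
      d[, j] * gamma2 / (gamma2 + se2[, j]) else 0
  }
  stab <- rowMeans(abs(d_shrunk) + sqrt(se2))
  names(stab) <- genes
  dimnames(d) <- dimnames(sig2) <- list(genes, lev)
  stability_result("normfinder", stab,
                   extras = list(groups = groups, d = d, d_shrunk = d_shrunk,
                                 sigma2 = sig2, n = n_i))
}
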
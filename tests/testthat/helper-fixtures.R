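# Fixture builders and independent brute-force oracles used across tests.

# Minimal cq_table from a genes x samples matrix.
make_cq <- function(mat, group = NULL, condition = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  n <- ncol(mat)
  if (is.null(group)) group <- rep("grp1", n)
  if (is.null(condition))
    condition <- ifelse(group == group[1], "control", "experiment")
  cq_table(mat, data.frame(sample_id = colnames(mat), group = group,
                           condition = condition, stringsAsFactors = FALSE))
}

# Sample SD written out longhand, independent of stats::sd.
long_sd <- function(x) {
  x <- x[is.finite(x)]
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Brute-force geNorm: recompute every pairwise V and every M from scratch
# at each exclusion step, with the documented tie rule (drop the
# lexicographically last gene among those sharing the maximum M).
oracle_genorm <- function(q) {
  y <- log2(q)
  m_of <- function(g, active) {
    others <- setdiff(active, g)
    mean(vapply(others, function(k) long_sd(y[g, ] - y[k, ]), numeric(1)))
  }
  active <- sort(rownames(q))
  removed <- character(0)
  m_rec <- setNames(numeric(nrow(q)), rownames(q))
  while (length(active) > 2) {
    M <- vapply(active, m_of, numeric(1), active = active)
    worst <- max(M)
    tied <- sort(names(M)[M == worst])
    drop <- tied[length(tied)]
    m_rec[drop] <- worst
    removed <- c(removed, drop)
    active <- setdiff(active, drop)
    m_rec[active] <- M[active]  # survivors keep last-round M
  }
  rank_v <- setNames(numeric(nrow(q)), rownames(q))
  rank_v[active] <- 1.5
  rank_v[rev(removed)] <- seq(3, length.out = length(removed))
  list(m = m_rec[rownames(q)], rank = rank_v[rownames(q)],
       removal_order = removed)
}

# Brute-force delta-Ct stabilities via explicit double loop.
oracle_delta_ct <- function(mat) {
  genes <- rownames(mat)
  vapply(genes, function(i) {
    mean(vapply(setdiff(genes, i), function(j) {
      long_sd(mat[i, ] - mat[j, ])
    }, numeric(1)))
  }, numeric(1))
}
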
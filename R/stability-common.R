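#' Convert Cq values to relative quantities
#'
#' Applies the standard preprocessing for geNorm/NormFinder: per gene g,
#' q(g, s) = E_g ^ (min_s Cq(g, s) - Cq(g, s)), so the most abundant sample
#' of each gene gets q = 1 and every other sample a value in (0, 1].
#' Missing Cq values propagate as missing.
#'
#' @param cq A [cq_table()].
#' @param efficiency Amplification base E per gene: a scalar (default 2.0,
#'   i.e. 100% efficiency) or a named vector covering every gene. Must be
#'   > 1.
#' @return An object of class `rq_matrix`: list with `q` (genes x samples
#'   matrix of relative quantities), `efficiency` (named per-gene vector)
#'   and `metadata` carried over from the Cq table.
#' @examples
#' ## a gene measured at Cq 20, 21, 22 halves in abundance each cycle:
#' ## q = 1, 0.5, 0.25
#' @export
cq_to_relative_quantity <- function(cq, efficiency = 2.0) {
  stopifnot(inherits(cq, "cq_table"))
  genes <- rownames(cq$cq)
  if (length(efficiency) == 1L && is.null(names(efficiency))) {
    eff <- setNames(rep(as.numeric(efficiency), length(genes)), genes)
  } else {
    miss <- setdiff(genes, names(efficiency))
    if (length(miss))
      stop("no efficiency supplied for gene(s): ", quoted_list(miss))
    eff <- as.numeric(efficiency[genes])
    names(eff) <- genes
  }
  if (any(eff <= 1)) stop("amplification efficiency (base) must be > 1")
  npresent <- rowSums(is.finite(cq$cq))
  if (any(npresent < 2))
    stop("each gene needs at least 2 present Cq values; offending gene(s): ",
         quoted_list(genes[npresent < 2]))
  q <- cq$cq
  for (g in genes) {
    row <- cq$cq[g, ]
    q[g, ] <- eff[g]^(min(row, na.rm = TRUE) - row)
  }
  structure(list(q = q, efficiency = eff, metadata = cq$metadata),
            class = "rq_matrix")
}

# Coerce input for geNorm/NormFinder: accept an rq_matrix, a cq_table
# (transformed with the config default efficiency), or a bare q matrix.
as_rq <- function(x, config = analysis_config()) {
  if (inherits(x, "rq_matrix")) return(x)
  if (inherits(x, "cq_table"))
    return(cq_to_relative_quantity(x, config$efficiency_default))
  if (is.matrix(x))
    return(structure(list(q = x, efficiency = NULL, metadata = NULL),
                     class = "rq_matrix"))
  stop("expected an rq_matrix, cq_table or matrix")
}

#' Fractional ranks of stability values
#'
#' Ascending fractional (mean) ranking: rank 1 is the most stable (smallest)
#' value and tied values share the mean of the ranks they span.
#'
#' @param values Named numeric vector of stability values; must be finite.
#' @return Named numeric vector of fractional ranks.
#' @examples
#' assign_ranks(c(a = 0.2, b = 0.5, c = 0.2))  # a = 1.5, b = 3, c = 1.5
#' @export
assign_ranks <- function(values) {
  if (!length(values)) stop("no values to rank")
  if (any(!is.finite(values)))
    stop("cannot rank non-finite stability value(s)",
         if (!is.null(names(values)))
           paste0(": ", quoted_list(names(values)[!is.finite(values)])))
  rank(values, ties.method = "average")
}

# Constructor shared by the four methods.
stability_result <- function(method, stability, rank = assign_ranks(stability),
                             extras = list()) {
  stopifnot(length(stability) == length(rank))
  structure(list(method = method, stability = stability, rank = rank,
                 extras = extras),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result: %s> %d genes (lower value = more stable)\n",
              x$method, length(x$stability)))
  df <- as.data.frame(x)
  print(df[order(df$rank), ], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.stability_result <- function(x, ...) {
  data.frame(gene = names(x$stability),
             value = unname(x$stability),
             rank = unname(x$rank),
             stringsAsFactors = FALSE)
}
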
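#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Ordinary least squares of Cq on log10(template concentration). The
#' amplification efficiency is derived from the slope as
#' E = (10^(-1/slope) - 1) * 100%; a slope of -3.3219 (= -1/log10(2))
#' corresponds to perfect doubling, E = 100%. A non-negative slope signals
#' primer failure: the fit is returned but the efficiency is undefined,
#' with a warning.
#'
#' @param points Data frame (or list) with columns/elements `concentration`
#'   (relative template amounts, strictly positive, e.g. a 10-fold dilution
#'   series) and `cq`.
#' @return An object of class `standard_curve`: list with `points`,
#'   `slope` (cycles per log10 concentration), `intercept`, `r_squared`
#'   and `efficiency_percent` (`NA` when the slope is non-negative).
#' @examples
#' conc <- 10^(0:-4)
#' fit <- fit_standard_curve(data.frame(concentration = conc,
#'                                      cq = 30 - 3.3219 * log10(conc)))
#' fit$efficiency_percent  # ~100%
#' @export
fit_standard_curve <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("concentration", "cq") %in% names(points)))
    stop("need columns 'concentration' and 'cq'")
  points <- points[, c("concentration", "cq")]
  if (nrow(points) < 3) stop("a standard curve needs at least 3 points")
  if (any(points$concentration <= 0))
    stop("concentrations must be strictly positive")
  if (length(unique(points$concentration)) < 2)
    stop("concentrations must not all be equal")
  fit <- stats::lm(cq ~ log10(concentration), data = points)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (slope < 0) {
    eff <- (10^(-1 / slope) - 1) * 100
  } else {
    warning("non-negative slope (", format(slope),
            "): amplification efficiency undefined (primer failure?)")
    eff <- NA_real_
  }
  structure(list(points = points, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency_percent = eff),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve> %d points, slope = %.4f, ",
                     "R^2 = %.4f, E = %s%%\n"),
              nrow(x$points), x$slope, x$r_squared,
              if (is.na(x$efficiency_percent)) "NA"
              else sprintf("%.1f", x$efficiency_percent)))
  invisible(x)
}

# Per-sample delta-Cq for one target/reference pair, with the control-mean
# subtraction. Returns the per-sample table restricted to samples where
# both genes are present.
single_ddcq <- function(cq, target, reference, control) {
  x <- cq$cq
  meta <- cq$metadata
  for (g in c(target, reference))
    if (!g %in% rownames(x)) stop("gene '", g, "' not in Cq table")
  both <- is.finite(x[target, ]) & is.finite(x[reference, ])
  dcq <- x[target, ] - x[reference, ]
  is_ctrl <- meta$condition == control
  usable_ctrl <- both & is_ctrl
  if (!any(usable_ctrl))
    stop("no usable control sample (condition '", control,
         "') with both '", target, "' and '", reference, "' present")
  ddcq <- dcq - mean(dcq[usable_ctrl])
  data.frame(sample_id = colnames(x), group = meta$group,
             condition = meta$condition, dcq = dcq, ddcq = ddcq,
             stringsAsFactors = FALSE)[both, , drop = FALSE]
}

finish_quant <- function(tab, target, references, control, base) {
  tab$rq <- base^(-tab$ddcq)
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(split(tab, tab$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d), mean_rq = mean(d$rq),
               sd_rq = if (nrow(d) > 1) stats::sd(d$rq) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(tab, class = c("quantification_result", class(tab)),
            target = target, references = references, control = control,
            base = base, summary = summ)
}

#' Relative expression by 2^-ddCq with a single reference gene
#'
#' Per sample s: dCq_s = Cq_target,s - Cq_ref,s; ddCq_s = dCq_s minus the
#' mean dCq over control samples; RQ_s = base^-ddCq_s. By construction the
#' control group's mean ddCq is 0. The default base 2 assumes perfect
#' doubling; pass `base = 1 + E` for an efficiency-corrected variant.
#'
#' @param cq A [cq_table()].
#' @param target,reference Gene ids.
#' @param control The `condition` level that defines the calibrator
#'   samples (default `"control"`); their mean dCq is the baseline.
#' @param base Quantification base (default 2).
#' @return A data frame of class `quantification_result` with columns
#'   `sample_id`, `group`, `condition`, `dcq`, `ddcq`, `rq` (samples with
#'   either gene missing are dropped); `attr(, "summary")` holds per-group
#'   mean and SD of RQ.
#' @export
relative_expression_single <- function(cq, target, reference,
                                       control = "control", base = 2) {
  stopifnot(inherits(cq, "cq_table"))
  tab <- single_ddcq(cq, target, reference, control)
  finish_quant(tab, target, reference, control, base)
}

#' Relative expression by 2^-ddCq with two reference genes
#'
#' The double-reference ddCq is the arithmetic mean of the two
#' single-reference ddCq values:
#' ddCq = (ddCq_ref1 + ddCq_ref2) / 2, and RQ = base^-ddCq — algebraically
#' the geometric mean of the two single-reference RQ series. When the two
#' references have identical Cq profiles this collapses exactly to the
#' single-reference result.
#'
#' @inheritParams relative_expression_single
#' @param ref1,ref2 The two (distinct) reference gene ids.
#' @return A `quantification_result` as in
#'   [relative_expression_single()], restricted to samples where the
#'   target and both references are present.
#' @export
relative_expression_double <- function(cq, target, ref1, ref2,
                                       control = "control", base = 2) {
  stopifnot(inherits(cq, "cq_table"))
  if (identical(ref1, ref2))
    stop("the two reference genes must differ")
  t1 <- single_ddcq(cq, target, ref1, control)
  t2 <- single_ddcq(cq, target, ref2, control)
  common <- intersect(t1$sample_id, t2$sample_id)
  t1 <- t1[match(common, t1$sample_id), , drop = FALSE]
  t2 <- t2[match(common, t2$sample_id), , drop = FALSE]
  tab <- t1
  tab$dcq <- (t1$dcq + t2$dcq) / 2
  tab$ddcq <- (t1$ddcq + t2$ddcq) / 2
  finish_quant(tab, target, c(ref1, ref2), control, base)
}

#' @export
print.quantification_result <- function(x, ...) {
  cat(sprintf("<quantification_result> target '%s' vs reference(s) %s\n",
              attr(x, "target"), quoted_list(attr(x, "references"))))
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' Pairwise Pearson concordance between normalization series
#'
#' Computes the pairwise Pearson correlation matrix between aligned numeric
#' series — raw Cq vectors of candidate references, or log2 RQ series of a
#' target quantified under different normalizations. The caller chooses the
#' scale; correlations are computed on the values as supplied, pairwise
#' complete. A zero-variance series yields undefined correlations for its
#' pairs, reported as missing with a warning.
#'
#' @param series A list of equal-length numeric vectors, or a matrix/data
#'   frame with one series per column.
#' @param labels Optional series labels (defaults to names/colnames).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
normalization_concordance <- function(series, labels = NULL) {
  if (is.list(series) && !is.data.frame(series)) {
    lens <- lengths(series)
    if (length(unique(lens)) != 1)
      stop("all series must have the same length")
    series <- do.call(cbind, series)
  }
  series <- as.matrix(series)
  if (nrow(series) < 3) stop("series must have length >= 3")
  if (ncol(series) < 2) stop("need at least 2 series")
  if (!is.null(labels)) colnames(series) <- labels
  if (is.null(colnames(series)))
    colnames(series) <- paste0("series", seq_len(ncol(series)))
  cc <- suppressWarnings(
    stats::cor(series, method = "pearson", use = "pairwise.complete.obs"))
  diag(cc) <- 1
  if (anyNA(cc))
    warning("zero-variance series: some correlations undefined (NA)")
  cc
}
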
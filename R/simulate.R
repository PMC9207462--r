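# Synthetic-data generators with recorded ground truth. All randomness is
# Gaussian on the Cq scale (multiplicative on abundance), the standard qPCR
# error structure, and every generator is deterministic given its seed
# (R's default Mersenne-Twister stream).

#' Simulate an RNA-seq FPKM matrix with known screening truth
#'
#' Emulates a multi-tissue FPKM profile: stable genes have a single
#' baseline above the screening threshold with small multiplicative noise
#' (CV < 0.05), variable genes carry per-tissue multipliers that force a
#' maximum fold change of at least 2. Optional edge-case genes exercise the
#' screening rules: constant genes (zero noise) and genes switched off
#' (FPKM 0) in one tissue. Samples are split evenly over `n_tissues`
#' tissues.
#'
#' The returned truth records the generator parameters and, computed by an
#' independent brute-force pass over the generated values, which genes
#' satisfy the screening thresholds.
#'
#' @param n_stable,n_variable Number of stable / tissue-variable genes.
#' @param n_samples Number of samples (default 12, i.e. 4 tissues x 3
#'   replicates).
#' @param config An [analysis_config()]; its thresholds define the recorded
#'   truth.
#' @param seed Integer seed.
#' @param n_constant Extra stable genes with exactly zero noise.
#' @param n_zero Extra genes with FPKM 0 in one tissue (undefined MFC).
#' @param n_tissues Number of tissue blocks (default 4).
#' @return List with `matrix` (an [expression_matrix()]) and `truth` (list:
#'   per-gene `type`, `mu`, `cv`, the tissue assignment, and
#'   `expected_pass`, the brute-force pass set).
#' @export
simulate_expression_matrix <- function(n_stable, n_variable,
                                       n_samples = 12,
                                       config = analysis_config(),
                                       seed = 1, n_constant = 0, n_zero = 0,
                                       n_tissues = 4) {
  stopifnot(n_stable >= 0, n_variable >= 0, n_samples >= 2)
  set.seed(seed)
  tissue <- rep_len(paste0("tissue", seq_len(n_tissues)), n_samples)
  genes <- c(if (n_stable) paste0("stable", seq_len(n_stable)),
             if (n_variable) paste0("variable", seq_len(n_variable)),
             if (n_constant) paste0("constant", seq_len(n_constant)),
             if (n_zero) paste0("zeromin", seq_len(n_zero)))
  type <- rep(c("stable", "variable", "constant", "zeromin"),
              c(n_stable, n_variable, n_constant, n_zero))
  G <- length(genes)
  if (!G) stop("nothing to simulate")
  mu <- numeric(G); cv <- numeric(G)
  vals <- matrix(0, G, n_samples, dimnames = list(genes, paste0("s", seq_len(n_samples))))
  for (g in seq_len(G)) {
    if (type[g] == "stable") {
      mu[g] <- runif(1, 60, 400); cv[g] <- runif(1, 0.005, 0.045)
      base <- rep(mu[g], n_samples)
    } else if (type[g] == "variable") {
      mu[g] <- runif(1, 20, 300); cv[g] <- 0.04
      m <- runif(n_tissues, 0.9, 1.1)
      m[sample.int(n_tissues, 1)] <- max(m) * runif(1, 2.5, 4)
      base <- mu[g] * m[match(tissue, unique(tissue))]
    } else if (type[g] == "constant") {
      mu[g] <- runif(1, 60, 400); cv[g] <- 0
      base <- rep(mu[g], n_samples)
    } else { # zeromin: off in one tissue
      mu[g] <- runif(1, 60, 200); cv[g] <- 0.03
      off <- paste0("tissue", sample.int(n_tissues, 1))
      base <- ifelse(tissue == off, 0, mu[g])
    }
    noise <- if (cv[g] > 0) rnorm(n_samples, 0, cv[g]) else rep(0, n_samples)
    vals[g, ] <- pmax(0, base * (1 + noise))
  }
  # brute-force screening truth, independent of screen_stats()
  expected_pass <- genes[vapply(seq_len(G), function(g) {
    v <- vals[g, ]
    m <- mean(v)
    s <- if (config$sd_mode == "sample") stats::sd(v)
         else sqrt(mean((v - m)^2))
    if (min(v) <= 0 || m <= 0) return(FALSE)
    m > config$mv_min && max(v) / min(v) < config$mfc_max &&
      s / m < config$cv_max
  }, logical(1))]
  list(matrix = expression_matrix(vals),
       truth = list(gene = genes, type = type, mu = mu, cv = cv,
                    tissue = tissue, expected_pass = expected_pass,
                    seed = seed))
}

#' Simulate a multi-group Cq experiment with known noise structure
#'
#' Generates Cq(g, s) = a_g + t(g, grp(s)) + delta_s + e(g, s) with
#' per-gene baselines a_g (uniform 18-30 cycles), per-gene per-group shifts
#' t, a shared per-sample loading effect delta_s ~ N(0, sigma_load) and
#' per-gene noise e(g, s) ~ N(0, sigma_g). The loading effect is drawn
#' after the residuals, so runs that share a seed and differ only in
#' `sigma_load` share the identical residual stream — which is what makes
#' the loading-invariance properties of delta-Ct and geNorm directly
#' testable.
#'
#' Default dimensions mirror a realistic reference-gene study: 32 genes and
#' 6 treatment groups of 9 samples each (3 tissues x 3 replicates), 54
#' samples in all.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Integer vector of samples per group; names become the
#'   group labels (defaults `grp1`, `grp2`, ...). The first group is
#'   labelled condition "control", the rest "experiment".
#' @param sigma Per-gene noise SDs (cycles); recycled; default drawn
#'   uniformly from [0.05, 0.6].
#' @param shifts Genes x groups matrix of group shifts t (cycles); default
#'   all zero.
#' @param sigma_load SD of the per-sample loading effect (cycles), default
#'   0.
#' @param seed Integer seed.
#' @return List with `cq` (a [cq_table()]) and `truth` (list: `baseline`,
#'   `sigma`, `shifts`, `sigma_load`, `delta`, `seed`).
#' @export
simulate_cq_experiment <- function(n_genes = 32,
                                   group_sizes = rep(9, 6),
                                   sigma = NULL, shifts = NULL,
                                   sigma_load = 0, seed = 1) {
  stopifnot(n_genes >= 1, all(group_sizes >= 1))
  set.seed(seed)
  n_groups <- length(group_sizes)
  grp_names <- names(group_sizes)
  if (is.null(grp_names)) grp_names <- paste0("grp", seq_len(n_groups))
  S <- sum(group_sizes)
  genes <- sprintf("gene%02d", seq_len(n_genes))
  group <- rep(grp_names, group_sizes)
  a <- runif(n_genes, 18, 30)
  if (is.null(sigma)) sigma <- runif(n_genes, 0.05, 0.6)
  sigma <- rep_len(sigma, n_genes)
  if (is.null(shifts)) shifts <- matrix(0, n_genes, n_groups)
  shifts <- as.matrix(shifts)
  if (!all(dim(shifts) == c(n_genes, n_groups)))
    stop("shifts must be a genes x groups matrix")
  e <- matrix(rnorm(n_genes * S), n_genes, S) * sigma
  delta <- rnorm(S) * sigma_load
  cqv <- a + shifts[, match(group, grp_names), drop = FALSE] +
    matrix(delta, n_genes, S, byrow = TRUE) + e
  dimnames(cqv) <- list(genes, sprintf("s%02d", seq_len(S)))
  meta <- data.frame(
    sample_id = colnames(cqv),
    group = group,
    condition = ifelse(group == grp_names[1], "control", "experiment"),
    tissue = rep_len(paste0("tissue", 1:3), S),
    replicate = unlist(lapply(group_sizes, seq_len)),
    stringsAsFactors = FALSE)
  list(cq = cq_table(cqv, meta),
       truth = list(baseline = setNames(a, genes),
                    sigma = setNames(sigma, genes),
                    shifts = shifts, sigma_load = sigma_load,
                    delta = delta, seed = seed))
}

#' Simulate a 10-fold dilution standard-curve series
#'
#' Concentrations 10^0, 10^-1, ..., 10^-(n-1); Cq = intercept -
#' log10(c) / log10(1 + e_true) + noise. With zero noise the fitted
#' efficiency recovers `e_true` exactly.
#'
#' @param e_true True amplification efficiency as a fraction (1.0 = 100%);
#'   must be > 0.
#' @param intercept Cq of the undiluted template (cycles).
#' @param n_points Number of dilution points.
#' @param noise_sd SD of Cq noise (cycles).
#' @param seed Integer seed.
#' @return Data frame with columns `concentration` and `cq`;
#'   `attr(, "truth")` records `e_true`, `intercept` and the implied slope.
#' @export
simulate_dilution_series <- function(e_true = 1.0, intercept = 30,
                                     n_points = 5, noise_sd = 0, seed = 1) {
  if (e_true <= 0) stop("e_true must be > 0")
  stopifnot(n_points >= 1)
  set.seed(seed)
  conc <- 10^(-(seq_len(n_points) - 1))
  slope <- -1 / log10(1 + e_true)
  cq <- intercept + slope * log10(conc) + rnorm(n_points, 0, noise_sd)
  out <- data.frame(concentration = conc, cq = cq)
  attr(out, "truth") <- list(e_true = e_true, intercept = intercept,
                             slope = slope, noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a target-gene experiment with known fold changes
#'
#' Builds a Cq table holding stable reference genes plus target genes whose
#' Cq in each experimental group is shifted by -1 cycle per log2 unit of
#' true fold change relative to the control group, so quantification
#' should recover RQ = 2^fold within noise. A control group is always
#' generated; the experimental groups are the columns of `log2_fc`.
#'
#' @param log2_fc Targets x groups matrix of true log2 fold changes
#'   (rownames = target ids, colnames = group labels; a vector is treated
#'   as one target across groups).
#' @param n_references Number of stable reference genes to include
#'   (ids `ref1`, `ref2`, ...).
#' @param n_replicates Biological replicates per group.
#' @param noise_sd Per-well Cq noise SD (cycles) applied to every gene.
#' @param sigma_load SD of a shared per-sample loading effect (cycles).
#' @param seed Integer seed.
#' @return List with `cq` (a [cq_table()]; control group has condition
#'   "control") and `truth` (list: `log2_fc`, `references`, `noise_sd`,
#'   `sigma_load`, `seed`).
#' @export
simulate_target_experiment <- function(log2_fc, n_references = 2,
                                       n_replicates = 3, noise_sd = 0.1,
                                       sigma_load = 0, seed = 1) {
  if (is.null(dim(log2_fc))) {
    log2_fc <- matrix(log2_fc, nrow = 1,
                      dimnames = list("target1",
                                      paste0("grp", seq_along(log2_fc))))
  }
  log2_fc <- as.matrix(log2_fc)
  if (is.null(rownames(log2_fc)))
    rownames(log2_fc) <- paste0("target", seq_len(nrow(log2_fc)))
  if (is.null(colnames(log2_fc)))
    colnames(log2_fc) <- paste0("grp", seq_len(ncol(log2_fc)))
  stopifnot(n_references >= 1, n_replicates >= 1)
  set.seed(seed)
  targets <- rownames(log2_fc)
  refs <- paste0("ref", seq_len(n_references))
  groups <- c("control", colnames(log2_fc))
  S <- length(groups) * n_replicates
  group <- rep(groups, each = n_replicates)
  a_ref <- runif(n_references, 18, 26)
  a_tgt <- runif(length(targets), 22, 30)
  shift <- cbind(control = 0, -log2_fc)   # targets x groups, cycles
  cqv <- rbind(
    matrix(a_ref, n_references, S),
    matrix(a_tgt, length(targets), S) +
      shift[, match(group, colnames(shift)), drop = FALSE])
  cqv <- cqv + matrix(rnorm(nrow(cqv) * S, 0, noise_sd), nrow(cqv), S)
  delta <- rnorm(S) * sigma_load
  cqv <- cqv + matrix(delta, nrow(cqv), S, byrow = TRUE)
  dimnames(cqv) <- list(c(refs, targets), sprintf("s%02d", seq_len(S)))
  meta <- data.frame(
    sample_id = colnames(cqv), group = group,
    condition = ifelse(group == "control", "control", "experiment"),
    replicate = rep(seq_len(n_replicates), length(groups)),
    stringsAsFactors = FALSE)
  list(cq = cq_table(cqv, meta),
       truth = list(log2_fc = log2_fc, references = refs,
                    noise_sd = noise_sd, sigma_load = sigma_load,
                    seed = seed))
}
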
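---
title: "Reference gene selection and stability analysis with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference gene selection and stability analysis with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR quantifies a target transcript relative to one or more *reference*
(housekeeping) genes that are assumed to be stably expressed across the
tissues, treatments and genotypes under study. A poorly chosen reference
injects its own biology into every normalized measurement. `refstab`
implements the complete workflow for choosing and validating references:

1. **Screening** candidates from RNA-seq FPKM profiles.
2. **Stability ranking** of an RT-qPCR candidate panel with four
   independent algorithms (comparative delta-Ct, BestKeeper, geNorm,
   NormFinder).
3. **Consensus** ranking by the geometric mean of the four methods' ranks.
4. **Validation**: primer efficiency from dilution standard curves,
   target quantification by $2^{-\Delta\Delta C_q}$ with one or two
   references, and concordance analysis between normalizations.

A synthetic-data module generates every input with recorded ground truth,
so each stage is testable end to end.

## Screening from RNA-seq

For each gene the screen computes the mean FPKM (MV), the standard
deviation (SD), the maximum fold change $\mathrm{MFC} = \max/\min$ and
the coefficient of variation $\mathrm{CV} = \mathrm{SD}/\mathrm{MV}$
across samples. A candidate passes when, strictly,

$$\mathrm{MV} > 50, \qquad \mathrm{MFC} < 1.5, \qquad \mathrm{CV} < 0.1,$$

and passing genes are ranked from the least to the highest SD. The
thresholds are the `analysis_config()` defaults and can be changed there.
Two rules keep degenerate genes out: a gene whose minimum FPKM is zero
has an undefined MFC and cannot pass, and a gene with zero mean has an
undefined CV. Every column is treated as one sample; if technical
replicates should be averaged first, that collapse is a deliberate
pre-step for the caller, because averaging before or after changes MFC
and CV and the right choice depends on the design. In practice the
SD-ranked pass list is followed by curation against functional
annotations; `top_n` in `select_candidates()` is the programmatic
stand-in for that manual step.

```{r screen-demo}
sim <- simulate_expression_matrix(n_stable = 6, n_variable = 3, seed = 42)
head(screen_stats(sim$matrix))
select_candidates(screen_stats(sim$matrix))
```

## From Cq to relative quantities

geNorm and NormFinder operate on relative quantities rather than cycles:

$$q_{gs} = E_g^{\,\min_s C_{q,gs} - C_{q,gs}},$$

so each gene's most abundant sample has $q = 1$. The amplification base
defaults to $E = 2$ (100% efficiency), matching the common practice of
quantifying with $2^{-\Delta\Delta C_q}$ even when measured primer
efficiencies deviate from 100%; per-gene bases are supported but off by
default. Missing Cq values ("no amplification") stay missing — they are
never imputed and never coded as zero, and every computation deletes them
pairwise, failing loudly when it drops below its minimum sample count.

## The four stability algorithms

**Comparative delta-Ct.** For genes $i \ne j$,
$\mathrm{SD}_s(C_{q,is} - C_{q,js})$ is computed over the samples where
both are present (at least 3, otherwise the pair is skipped with a
warning); the stability of gene $i$ is the mean of these pairwise SDs.
Units are cycles. Because only differences enter, a per-sample loading
shift common to all genes cancels exactly.

**BestKeeper.** Descriptive statistics of the raw Cq per gene (arithmetic
and geometric mean, min, max, SD, CV% $= 100\cdot\mathrm{SD}/\mathrm{mean}$)
plus the Pearson correlation of each gene against the *BestKeeper index*,
the per-sample geometric mean of all candidate genes' Cq computed on
complete-case samples (the gene being correlated is included — no
leave-one-out). The stability value used for ranking is the SD of Cq;
a mean-absolute-deviation variant is available behind `use_mad = TRUE`
and the choice is logged. Ranking uses SD, not CV%.

**geNorm.** Pairwise variation $V_{jk} = \mathrm{SD}_s\!\left(\log_2
q_{js}/q_{ks}\right)$ and M-value $M_j = \operatorname{mean}_{k \ne j}
V_{jk}$. The gene with the highest M is removed and all M recomputed,
until two genes remain; these survivors cannot be ordered by the
algorithm and are tied at rank 1.5, keeping the M they had at the last
elimination round. The reported pairwise variation $V(n/n{+}1)$ is the SD
of the log-ratio of normalization factors (geometric means of $q$) built
from the $n$ and $n+1$ most stable genes; the conventional $V < 0.15$
guideline is reported, never decided on. Removal ties (equal maximum M)
are broken by removing the lexicographically last gene id, which makes
the procedure deterministic.

**NormFinder.** The log quantities $y_{gs} = \log_2 q_{gs}$ are modelled
as gene effect + sample effect + gene-by-group interaction + residual.
Within each group $i$ ($n_i$ complete-case samples, $k$ genes) the
two-way residual variance of gene $g$ is

$$v_{gi} = \frac{1}{n_i - 1}\sum_s \left(y_{gs} - \bar y_{g\cdot}
  - \bar y_{\cdot s} + \bar y_{\cdot\cdot}\right)^2,$$

whose expectation is $(1 - 2/k)\,\sigma^2_{gi} + \bar\sigma^2_i/k$
because the subtracted per-sample mean contains every gene's noise. The
debiased estimator used here,

$$\hat\sigma^2_{gi} = \max\!\left(0,\;\Bigl(v_{gi} -
  \frac{\bar v_i}{k-1}\Bigr)\frac{k}{k-2}\right),$$

is exactly unbiased for gene-specific error variances (substituting the
expectations above shows the contamination term cancels); it needs
$k \ge 3$ genes. With two or more groups the intergroup deviation
$d_{gi}$ (the gene-by-group mean, double-centred on gene and group
means) is shrunk toward zero,
$\tilde d_{gi} = d_{gi}\,\gamma_i^2 / (\gamma_i^2 + \hat\sigma^2_{gi}/n_i)$
with $\gamma_i^2 = \max\bigl(0, \operatorname{Var}_g(d_{gi}) -
\operatorname{mean}_g(\hat\sigma^2_{gi}/n_i)\bigr)$ estimated per group
(when $\gamma^2_i = 0$ all $\tilde d$ collapse to zero), and the
stability is

$$\rho_g = \frac{1}{I}\sum_i \left(|\tilde d_{gi}| +
  \sqrt{\hat\sigma^2_{gi}/n_i}\right).$$

With a single group the stability is simply $\sqrt{\hat\sigma^2_g}$.
Grouping defaults to the metadata `group` column (treatment); any other
factor can be passed explicitly.

```{r stability-demo}
exp1 <- simulate_cq_experiment(n_genes = 6, group_sizes = c(12, 12),
                               sigma = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.9),
                               seed = 7)
res <- list(delta_ct_stability(exp1$cq), bestkeeper(exp1$cq),
            genorm(exp1$cq), normfinder(exp1$cq))
reffinder_consensus(res)
```

## Consensus ranking

Each method contributes its fractional ranking (ascending stability
value, mean ranks for ties; geNorm's final pair enters as 1.5/1.5). The
consensus score of a gene is the geometric mean of its ranks over the
$m$ supplied methods, $\left(\prod_m r_{gm}\right)^{1/m}$, and the final
order is ascending in that score. The "weights" aggregated here are the
ranks themselves, not the stability magnitudes — rank aggregation keeps
methods with different units (cycles, M-values, $\rho$) commensurable.
Unanimity is preserved (a gene ranked 1 everywhere ranks 1 overall), and
improving a gene's rank in one method can never worsen its consensus
score.

## Efficiency and quantification

A standard curve is an ordinary least-squares fit of Cq on
$\log_{10}$(template amount) over a dilution series (at least 3 points);
the efficiency is $E = \bigl(10^{-1/\text{slope}} - 1\bigr)\times 100\%$,
so a slope of $-3.32$ means perfect doubling. A non-negative slope
signals primer failure and yields an undefined efficiency with a
warning.

Relative expression uses the $2^{-\Delta\Delta C_q}$ scheme:
$\Delta C_{q,s} = C_{q,\text{target},s} - C_{q,\text{ref},s}$, baselined
against the *mean* $\Delta C_q$ of the control-condition replicates (not
a single calibrator sample), and $\mathrm{RQ}_s = 2^{-\Delta\Delta C_{q,s}}$.
With two references the combined value is the arithmetic mean of the two
single-reference $\Delta\Delta C_q$ — algebraically, the RQ is the
geometric mean of the two single-reference RQ series. The base is 2 by
default for fidelity to standard practice; an efficiency-corrected base
$1 + E$ can be passed.

`normalization_concordance()` computes pairwise Pearson correlations
between aligned series on whatever scale the caller supplies: raw Cq
vectors when comparing candidate references across samples, or log2 RQ
series when comparing normalizations of the same target. Both uses are
exposed because either scale can be defended; the choice is the
caller's, made explicit by the input.

```{r quant-demo}
fc <- matrix(c(2, -1), 1, 2, dimnames = list("PR1", c("day7", "day14")))
tg <- simulate_target_experiment(fc, noise_sd = 0.05, seed = 11)
q1 <- relative_expression_single(tg$cq, "PR1", "ref1")
attr(q1, "summary")
q2 <- relative_expression_double(tg$cq, "PR1", "ref1", "ref2")
attr(q2, "summary")
```

## What the simulators emulate — and what they do not

All generators put Gaussian noise on the Cq scale (equivalently,
multiplicative log-normal noise on abundance), which matches the
dominant error structure of qPCR; heavier-tailed contamination,
plate/batch structure and amplification inhibition are *not* modelled.

* `simulate_expression_matrix()` emulates a multi-tissue FPKM profile:
  stable genes with baseline above the MV threshold and CV below 0.05,
  tissue-variable genes whose per-tissue multipliers force MFC ≥ 2, plus
  optional constant and switched-off edge-case genes. Defaults (12
  samples = 4 tissues × 3 replicates) mirror a typical RNA-seq screening
  design.
* `simulate_cq_experiment()` draws
  $C_{q,gs} = a_g + t_{g,\mathrm{grp}(s)} + \delta_s + e_{gs}$ with
  baselines uniform in 18–30 cycles, optional group shifts $t$, a shared
  loading effect $\delta_s \sim N(0, \sigma_\text{load})$ and per-gene
  noise $e_{gs} \sim N(0, \sigma_g)$. When no noise profile is supplied,
  $\sigma_g$ is drawn uniformly from 0.05–0.6 cycles, a realistic range
  from tight technical replication to visible treatment responsiveness.
  The default design is 32 genes and 6 treatment groups × 9 samples
  (3 tissues × 3 replicates), 54 samples. The loading effect is drawn
  *after* the residuals so that runs differing only in
  $\sigma_\text{load}$ share the identical residual stream — this makes
  the loading-invariance of delta-Ct, geNorm and RQ directly testable.
* `simulate_dilution_series()` inverts the standard-curve model exactly
  at zero noise, so generator and fitter are mutual inverses.
* `simulate_target_experiment()` shifts target Cq by −1 cycle per log2
  unit of true fold change against a control group, so quantification
  should recover $\mathrm{RQ} = 2^{\text{fold}}$ within noise.

Because the generators share the pipeline's own model family, passing
recovery tests demonstrates internal consistency and correct
implementation of the defining formulas — not robustness to the
non-Gaussian artefacts of real instruments.

## Numerical choices

* **SD convention.** Sample SD ($n-1$) everywhere by default
  (`sd_mode = "population"` switches all of them at once); published
  descriptions of these tools rarely state their convention, so it is a
  single explicit knob rather than a hidden mixture.
* **Ties.** All rankings are fractional (mean rank). geNorm's final pair
  is tied at 1.5 by construction. Deterministic tie-breaks: geNorm
  removal drops the lexicographically last gene; candidate selection and
  consensus output order break value ties by gene id.
* **Missing data.** Pairwise deletion with hard minimums: 3 common
  samples per delta-Ct/geNorm pair, 3 complete-case samples for the
  BestKeeper index, 2 complete samples per NormFinder group. Falling
  below a minimum raises an error or a named warning, never a silent
  degradation.
* **Degenerate inputs.** Zero-minimum FPKM → MFC undefined, gene cannot
  pass screening. Non-negative standard-curve slope → efficiency
  undefined with warning. Zero-variance series in concordance →
  undefined correlations reported as missing with warning.
  $\gamma^2 = 0$ in NormFinder → intergroup deviations shrunk to zero.
* **Serialization.** Reports are TSV with 6 significant digits and a
  deterministic column order, so write-then-read reproduces results to
  that precision.

## Known limitations

* NormFinder removes a per-sample mean taken over *all* genes, so one
  very noisy candidate contaminates every gene's residual variance; with
  small panels and moderate sample counts the method cannot reliably
  separate the two most stable genes, even though it identifies the
  least stable ones well. The consensus inherits some of this blur, and
  geNorm contributes no strict ordering of its final pair at all — in
  small simulations the consensus therefore identifies the most stable
  *pair* far more reliably than the single best gene.
* The BestKeeper index correlation is descriptive; ranking uses the SD
  only, as the correlation depends on panel composition.
* Test and example problem sizes in this package (typically 3–6 genes ×
  4–24 samples, and 100-replicate simulation sweeps) were chosen to make
  every property checkable by brute force; the algorithms themselves
  scale comfortably to panels of dozens of candidates.
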
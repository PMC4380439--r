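---
title: "Reference-gene validation with refstab: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene validation with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR quantifies transcripts relative to endogenous reference
("housekeeping") genes, but no gene is perfectly stable across tissues or
conditions. Good practice is therefore to screen a panel of candidate
reference genes in each experimental system, rank them by expression
stability, and normalize against the geometric mean of the most stable
subset. Several ranking algorithms coexist — geNorm, NormFinder,
BestKeeper and the comparative delta-Ct method — and popular web tools
aggregate them from raw quantification-cycle (Cq) input. A raw-Cq pipeline
silently assumes every assay doubles its product each cycle; real assays
do not, and `refstab` exists to make the consequences of that assumption
measurable: it runs all four algorithms from one Cq table in both
efficiency-corrected and uncorrected (E = 2) modes and quantifies how the
rankings move.

## From Cq to relative quantities

For gene $i$ with amplification base $E_i$ (per-cycle amplification
factor; $E_i = 2$ is "100% efficiency", and efficiency in percent is
$(E_i-1)\times 100$), the relative quantity of sample $j$ uses the
lowest-Cq sample of that gene as reference:

$$RQ_{ij} = E_i^{\,\min_j Cq_{ij} - Cq_{ij}} \in (0, 1].$$

Stability computations operate on $\log_2 RQ$. Two consequences shape the
whole package:

* with $E_i = 2$, $\log_2 RQ_{ij} = \min Cq_i - Cq_{ij}$ exactly, so
  every SD-based statistic computed from E = 2 quantities equals the one
  computed directly from raw Cq — the mechanism behind the agreement
  between original packages run at 100% efficiency and raw-Cq web tools;
* the exponent's overall sign is irrelevant to every ranking (standard
  deviations and variances are sign-invariant), so the typographically
  ambiguous direction of the transform cannot affect results. This is
  asserted as a property test on random matrices.

The direction yielding $RQ \le 1$ was chosen so the minimum-Cq (highest
abundance) sample is the reference.

## The four stability algorithms

**geNorm.** $M_i$ is the mean over partner genes $k$ of
$\mathrm{SD}_j(\log_2 RQ_{ij} - \log_2 RQ_{kj})$ (n−1 denominator
throughout, matching spreadsheet STDEV). The gene with the highest $M$ is
removed and $M$ recomputed until two genes remain; these two are mutually
indistinguishable by a pairwise criterion and share the printed tie rank
"1/2". Exact ties during exclusion remove the gene later in input order
(deterministic, documented). Each gene reports its $M$ at removal; the
full per-step trajectory is also returned. Normalization factors $NF_n$
(per-sample geometric means of the $n$ most stable genes, tie pair first,
then reverse exclusion order) give the pairwise variation
$V_{n,n+1} = \mathrm{SD}_j \log_2 (NF_n / NF_{n+1})$; the smallest $n$
with $V < 0.15$ is reported as the optimal panel size. The 0.15 cutoff is
a rule of thumb, surfaced as a parameter and flagged as such in reports;
when no $V$ passes, the optimal size is undefined and the report advises
visual inspection of the trend.

**NormFinder.** A two-way additive model on the log scale,
$x_{ij} = \alpha_i + \beta_j + \varepsilon_{ij}$ with
$\mathrm{Var}\,\varepsilon_{ij} = \sigma_i^2$. Per-gene residual
variances $s_i^2$ from the two-way fit are de-biased for the contamination
each gene's residuals inherit from the panel:
$\hat\sigma_i^2 = (s_i^2 - \textstyle\sum_{i'} s_{i'}^2 / (G(G-1)))
\cdot G/(G-2)$. This moment estimator is exactly unbiased under the model
(we verified the algebra before implementation and verify it by
simulation in the suite); the reported stability is
$\rho_i = \sqrt{\max(\hat\sigma_i^2, 0)}$. The truncation at zero is
needed for $\rho$ but makes the truncated estimator biased upward for
genes with tiny $\sigma$; the untruncated estimate is therefore exposed
as `sigma2_raw`, and the Monte-Carlo recovery test targets it. In grouped
mode, group deviations $\hat d_{ig}$ (size-weighted-centred group means
of sample-centred expression) are shrunk by the common intergroup
variance, $\tilde d_{ig} = \hat d_{ig}\,\hat\gamma^2 / (\hat\gamma^2 +
\hat\sigma^2_{ig}/n_g)$, and
$\rho_i = K^{-1} \sum_g (|\tilde d_{ig}| + \hat\sigma_{ig}/\sqrt{n_g})$.
Absolute stability values are implementation-specific across the various
NormFinder ports; rankings are the contract here, not values.

One grouped-mode caveat discovered during validation and worth knowing:
because group deviations are computed from sample-centred data, a strong
expression shift in *any* panel gene leaks (divided by $G$) into every
other gene's $\hat d_{ig}$. Among genes with small $\sigma_i$ the
$|\tilde d|$ term is then dominated by this common leakage plus noise, and
the grouped ordering of the quietest genes becomes unstable even at large
$n$. The pooled (ungrouped) ordering does not have this problem; the
parameter-recovery tests use it.

**BestKeeper.** Pure raw-Cq descriptives: per-gene SD of Cq (genes with
SD > 1.5 cycles are excluded from index construction), the BestKeeper
index (per-sample geometric mean of retained genes' Cq), and each gene's
Pearson correlation with the index. Two orderings are reported: by
correlation (the original software's final ranking) and by Cq SD (what
raw-Cq aggregators use). These can differ sharply — a gene with a tight
but panel-independent profile wins by SD and loses by correlation — and
the package reproduces that divergence on constructed data. BestKeeper
never sees the efficiency table, so its output is identical in both
efficiency modes; this invariance is asserted through the pipeline.
An alternative mean-absolute-deviation dispersion is available
(`dispersion = "mad"`), mirroring the original spreadsheet's flavour;
the SD wording is the default.

**Comparative delta-Ct.** The mean over partners of
$\mathrm{SD}_j(Cq_{ij} - Cq_{kj})$. Algebraically this equals the
full-panel geNorm $M$ computed at E = 2, an identity the suite asserts to
1e−12 on every random input.

**Comprehensive ranking.** An emulation of the web-tool aggregation:
geometric mean of the four component ranks obtained from raw Cq (geNorm's
terminal tie contributes 1.5 to both genes; other ties contribute mean
ranks), ties broken by delta-Ct score then input order. The aggregation
is a mere arithmetic combination with no underlying model; every report
carries that caveat, and the ranking is presented as advisory.

## Comparing rankings

`rank_compare` matches two rankings gene by gene. A gene changes whenever
its printed label differs (entering or leaving the "1/2" tie set counts).
The magnitude is the distance to the nearest member of a tie set — the
unique simple convention under which the published major/minor counts in
the bundled ranking table are internally consistent. Changes of one rank
are "minor", more than one "major"; a label change at distance 0 is
classed minor so that changed = minor + major always holds. Percentages
are displayed rounded to integers; exact fractions are retained.

## The synthetic world

`simulate_cq` draws latent log2 abundances
$q_{ij} = L_j + \delta_{ig(j)} + \varepsilon_{ij}$ — a shared loading
factor $L_j \sim N(0, \tau^2)$ standing for input-amount variation, gene-
and group-specific shifts $\delta$, and gene noise
$\varepsilon_{ij} \sim N(0, \sigma_i^2)$ — then converts to cycles via
$Cq_{ij} = b_i - q_{ij} \ln 2 / \ln E_i$ and adds replicate noise in
cycles. Under this model "stability" has an unambiguous ground truth
(small $\sigma_i$, zero $\delta$), the loading factor cancels from all
pairwise statistics, and the efficiency distortion is exactly the
per-gene rescaling $\ln 2 / \ln E_i$ of the uncorrected log quantities —
which is what makes corrected and uncorrected rankings diverge when
efficiencies are heterogeneous and provably coincide when all $E_i = 2$.

The two presets state the emulated designs once: a 14-gene human panel;
`fs1` with three culture groups of 4/4/3 samples, condition-responsive
shifts on IGF1R and SOX9 (biologically plausible responders in a
Sertoli/seminoma co-culture) and a milder one on B2M; `cis` with six
ungrouped biopsies and a larger loading spread ($\tau$ = 0.8 vs 0.5, as
expected for clinical material). Baselines span 18.5–28 cycles; noise SDs
span 0.10 (HMBS, designed most stable) to 0.90 (RLP13, designed outlier);
four assays (RPS18 1.75, TBP 1.87, UBC 2.15, YWHAZ 1.85) deviate by more
than 10% from perfect doubling. Technical triplicates with 0.1-cycle
noise are averaged on import, matching instrument-software practice.

What the generator does *not* emulate: amplification curves and Cq
calling, inhibition, missing reactions, heteroscedastic low-copy noise,
or correlated regulation between panel genes (each gene's noise is
independent given the loading). A green synthetic test therefore
establishes algorithmic correctness and the stated statistical
properties, not performance on pathological real-world plates.

## Numerical and design choices

* SD everywhere uses the n−1 denominator; pairwise SD matrices are
  computed from the covariance matrix with negative round-off clamped at
  zero before the square root.
* Incomplete Cq matrices are fatal, never imputed: all four algorithms
  assume complete panels and silent imputation would corrupt them.
* Efficiencies are accepted as base (1.93) or percent (93), stored as
  base; values outside [1.5, 2.2] are rejected, outside [1.8, 2.1]
  warned about.
* Monte-Carlo tests are scaled: unit tests run reduced replicate counts
  with noise-widened bands and state so in comments; the full-scale
  checks (1000-rep variance recovery at a 5% band, 500-rep group-shift
  detection at 95%, 200-seed efficiency-bias reproduction) live in the
  acceptance test file. For the variance-recovery world the per-gene
  noise grid spans 0.05–0.8 geometrically — the natural spacing for a
  scale parameter, and the one under which the 5% band is statistically
  meaningful for the smallest gene at 1000 replicates.
* The published two-dataset ranking table bundled as `extdata/table2.tsv`
  is replayed, not recomputed: the study's raw Cq tables were only ever
  distributed as supplementary spreadsheets, so the per-gene rankings and
  the published optimal panel sizes (2 and 3 genes) cannot be reproduced
  from deposited data. The replay reproduces the four study-level
  discrepancy statistics exactly; the algorithmic claims behind them are
  covered by the synthetic properties instead.

## Known limitations

* geNorm's pairwise criterion favours co-regulated genes; nothing in the
  package corrects for that (it is a property of the method).
* The comprehensive ranking is an emulation of an undocumented
  aggregation; structure (geometric mean of ranks, raw-Cq components) is
  the contract, not pixel-level agreement with any web tool.
* Grouped NormFinder inherits the deviation-leakage behaviour described
  above; for panels containing strongly regulated genes, interpret the
  grouped ordering of the quietest genes cautiously (or consult the
  pooled ordering).
* BestKeeper correlation p-values use the two-sided t approximation and
  are reported for orientation only.
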
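---
title: "Decomposing sex-biased expression into abundance and regulatory components"
author: "scSexBias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing sex-biased expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scSexBias)
```

## The problem

A gene can look sex-biased in a bulk tissue comparison for two reasons:
its transcription genuinely differs between the sexes within some cell
type (a regulatory difference), or the tissue's cellular composition
differs between the sexes so that a gene expressed preferentially in a
sex-enriched cell type shifts in the tissue average without any regulatory
change. The two causes have different biological interpretations — only
the former is a plausible direct target of sex-specific selection — and
different consequences for downstream analyses such as rates of
coding-sequence evolution. This package separates them using single-cell
count data with cell-type labels: differential expression is assessed both
on whole-tissue pseudobulk and on per-cell-type pseudobulk, differential
cell-type abundance is tested directly, and each gene is assigned to one
of four categories (`bulk_only`, `bulk_and_cell`, `cell_only`,
`unbiased`).

## Models and procedures

### Cell-type abundance

Cells are pooled across replicates within each sex (the replicate
structure is retained only as a Wilson-interval diagnostic,
`abundance_replicate_diagnostics()`). For cell type $k$ with $n_{f,k}$ of
$N_f$ female cells and $n_{m,k}$ of $N_m$ male cells, the package reports
$\log_2\!\frac{p_{f,k} + 10^{-10}}{p_{m,k} + 10^{-10}}$ — the pseudocount
keeps sex-limited cell types finite — and a two-sided two-proportion
z-test, i.e. the pooled $2\times 2$ chi-square. The Yates continuity
correction is on by default (`correct = FALSE` disables it); whether the
original analyses of this kind used the correction is rarely stated, so
both routes are exposed, and the calibration test shows the corrected test
is conservative (false-call rate well below the nominal $\alpha = 0.01$).
No multiple-testing correction is applied across cell types; calls are on
raw p-values, as is conventional for these per-tissue composition scans.

### Pseudobulk differential expression

Raw counts are **summed** (never averaged or pre-normalized) over the
cells of each sample, either tissue-wide or within one cell type. Summing
preserves the count nature of the data and the exact partition identity
$\text{whole tissue} = \sum_k \text{cell type } k$, which the test suite
asserts as integer equality.

Library-size differences between samples are handled with median-of-ratios
size factors: $s_j = \operatorname{median}_g \, x_{gj} / (\prod_{j'}
x_{gj'})^{1/n}$ over genes positive in all samples, with a total-count
fallback (and warning) if no such gene exists.

Each gene is then modeled as $x_{gj} \sim \mathrm{NB}(s_j q_{g,\mathrm{sex}(j)},
\phi_g)$ with variance $\mu + \phi\mu^2$. The sex means are fitted by
Newton iterations on the log scale; the dispersion maximizes the Cox-Reid
adjusted profile likelihood over a fixed 50-point log-spaced grid
($10^{-8}$ to $10^2$). The Wald statistic is
$\log(q_f/q_m)\,/\,\mathrm{SE}$ with the standard-error from the observed
Fisher information, referred to the standard normal; BH adjustment is
applied over tested genes (genes with all-zero counts are reported
`untested`); a sex-biased call requires $|\log_2 FC| \ge 1$ and FDR
$< 0.05$.

**Dispersion moderation.** With three samples per sex, purely gene-wise
dispersion estimates are extremely noisy and the resulting Wald test is
anticonservative (null raw $p<.05$ rate $\approx 0.076$ in our pilots);
full shrinkage pipelines overcorrect here ($\approx 0.02$). The package
therefore maximizes the weighted likelihood
$\mathrm{APL}_g(\phi) + \frac{\text{prior.df}}{\text{residual df}}
\overline{\mathrm{APL}}(\phi)$ with the classic default
$\text{prior.df} = 10$, which restores near-nominal calibration
($\approx 0.05$, verified by the acceptance suite at 2,000 genes, 3 vs 3
samples). Setting `prior_df = 0` recovers the purely gene-wise fit for
users who want no information sharing across genes.

**Sex-limited genes.** When one sex's fitted mean is exactly zero the fold
change is undefined; the package reports the sentinel $\pm 30$ (beyond any
plausible threshold), flags the gene `sex_limited`, and computes the Wald
p after substituting the half-count continuity mean $0.5/\sum_j s_j$ for
the zero group. Whole cell types present in only one sex cannot be tested
at all; such strata are refused with a reportable condition rather than
guessed at, and the pipeline records them in `de_skipped_strata.tsv`.

### Classification

`bulk_only` = biased at bulk, unbiased in every *tested* cell type;
`bulk_and_cell` = biased at bulk and in at least one type; `cell_only` =
biased in at least one type but unbiased **or untested** at bulk (an
all-zero bulk profile should not exclude a gene from the cell-level
union); `unbiased` otherwise. Direction is the bulk direction where bulk
is involved (a disagreeing biased cell type sets `direction_conflict`
rather than changing the category, a case the source analyses do not
discuss); for `cell_only` it is the common direction across biased types,
else `"mixed"`. The summary reports the cell-level union
(`bulk_and_cell` + `cell_only`), the bulk-level count (`bulk_only` +
`bulk_and_cell`), and the fraction of cell-level biased genes unbiased at
bulk — the false-negative proxy for bulk experiments. The association of
`bulk_only` genes with abundance-biased cell types is provided only as a
descriptive expression table (`bulk_only_expression_profile()`); no test
is attached because the criterion used for the corresponding published
comparison is not fully specified.

### Coding-sequence divergence

Per-gene substitution counts ($D_N, D_S$) and site counts ($N, S$) come
from an upstream codon-model fit, consumed as a TSV. Genes with per-gene
$d_S > 2$ are removed (saturation); the boundary value 2 is retained.
Group rates aggregate before dividing: $d_N = \sum D_N / \sum N$, $d_S =
\sum D_S / \sum S$, $\omega = d_N/d_S$, making the estimate a
site-weighted group property robust to unstable per-gene ratios.
Uncertainty is a percentile bootstrap over genes (B = 1000, 95%
equal-tailed) — percentile rather than BCa because it is the simplest
defensible reading of "bootstrapping" and its coverage is verified by
simulation (observed 0.92–0.95 over 200 replications). Group contrasts
are label permutations preserving group sizes with the add-one p-value
$(1 + \#\{|\Delta^{perm}| \ge |\Delta^{obs}|\})/(B+1)$; two-sided by
default (one-sided exposed) since the sidedness of the original tests is
unstated. Replicates with an undefined omega (no synonymous substitutions)
are excluded and counted. Pairwise results across the standard nine
category groups are condensed to a compact letter display
(insert-and-absorb) at $p < .05$.

## The synthetic-data generator

`sim_config()` + `simulate_counts()` state a world in which every
downstream claim is checkable:

* each cell draws its type from its sex's proportion vector
  ($\pi_f, \pi_m$); sex differences in composition are therefore exact and
  known;
* counts are NB with mean $\ell_c \, \mu_{gk} \, 2^{\pm \lambda/2}$:
  per-cell lognormal library factor $\ell_c$ (defaults meanlog 0, sdlog
  0.3 — a modest, realistic depth spread), baseline mean $\mu_{gk}$ drawn
  gamma(shape 2, scale 4) unless supplied (mean 8 counts per cell, right
  skewed, a plausible droplet-data scale), dispersion $\phi = 0.1$, and a
  symmetric regulatory effect $\lambda$ (= `regulatory_lfc`) for flagged
  (gene, type) pairs so the within-type log2 FC equals $\lambda$ exactly;
* the default 8,000 cells per sample matches a typical single 10x lane
  loading; tests and the demo scale this down and say so;
* optional independent dropout zeroes entries post-draw (default off:
  dropout is treated as technical noise absorbed by normalization, not a
  target of inference);
* substitution counts are $D_S \sim \mathrm{Bin}(S, p_s)$, $D_N \sim
  \mathrm{Bin}(N, \omega p_s)$ with group-specific $\omega$, so the
  aggregated group rates have closed-form expectations ($d_S = p_s$,
  $\omega$ itself).

The analytic truth is the mixture identity: the expected bulk mean per
sex is $\sum_k \pi_k \mu_{gk} 2^{\pm\lambda_{gk}/2}$, giving
`expected_bulk_lfc()` in closed form, a `sex_limited` flag instead of an
infinite ratio when one sex's mixture mean is zero, and the truth set of
abundance-driven genes (non-regulatory genes whose analytic |lfc| meets
the calling threshold).

What the generator does **not** emulate: UMI chemistry, ambient RNA,
doublets, batch effects, cell-cycle structure, or empirically estimated
dispersion/library-size distributions (none are published for the tissues
that motivated this design; defaults were chosen for testability). A green
test therefore establishes correctness of the statistical machinery on its
stated model, not robustness to every artifact of real droplet data.

## Numerical and design choices

* Gene/cell filtering (genes detected in ≥ 3 cells, then cells with ≥ 100
  detected genes) is a single ordered pass; the order is the common
  convention, and an `iterate = TRUE` fixpoint mode exists. The single
  pass is deliberately *not* idempotent in general — removing cells can
  push a gene below threshold — which is exactly why the fixpoint mode is
  offered. Filters default to merged-data application; per-sample
  application is a caller-side loop.
* The depth-correlation QC (per-group Pearson r between per-cell totals
  and detected genes) interprets "reads per cell" as total counts, the
  only depth measure present in a count matrix. After pure library-size
  scaling the per-cell totals are constant by construction, so the
  "after normalization" column is reported `NA` — the degenerate limit of
  the decreased-correlation comparison a variance-stabilizing transform
  would show.
* The dispersion grid bounds ($10^{-8}$, $10^2$) act as the floor and
  ceiling of the dispersion estimate; the Newton mean fits are clamped at
  $|\eta| \le 35$ to avoid overflow on all-zero groups.
* Seeding: `sim_config` draws baselines and regulatory flags at
  construction time from `seed`; `simulate_counts` and
  `simulate_divergence` use fixed offsets (+1, +2) of the same seed. The
  pipeline fans a master seed out as
  `stage_seed(master, stage) = (1000 * master + offset) mod (2^31 - 1)`
  with documented per-stage offsets, so any stage rerun in isolation
  reproduces its slice of a full run; `manifest.json` records the resolved
  configuration and md5 of every output.
* `two_proportion_test()` wraps `stats::prop.test` (the field's standard
  implementation of this test); the test suite checks it against an
  independently coded contingency-table oracle to $10^{-10}$, and
  `bh_adjust()` is implemented in-package and checked against a
  brute-force step-up enumeration.

## Known limitations

* DE strata require two samples per sex; sex-limited cell types (e.g.
  gonad-specific populations) are reported, not tested — their genes reach
  the classification only through the whole-tissue stratum.
* No covariate adjustment, paired designs, compositional (log-ratio)
  abundance models, or replicate-aware abundance tests.
* The NB test does not shrink fold changes; genes at the |log2 FC| = 1
  boundary with truth exactly at the boundary are called in ~half of
  realizations (this knife edge is visible in the acceptance suite's
  mechanism demonstration, which pools seeds for that reason).
* Divergence inputs are taken at face value; orthology, alignment and the
  codon model itself are upstream concerns.
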
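---
title: "Methods: pathway bias and differential activation from perturbation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway bias and differential activation from perturbation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilactivr)
```

## The scientific question

Biliary atresia (BA) is a neonatal obstructive cholangiopathy. Bulk
RNA-seq of patient-derived extrahepatic cholangiocyte organoids gives a
snapshot of the transcriptional state of the diseased epithelium, but
the genes that *change* are mostly downstream effects. The question this
package addresses is the inverse one: which upstream regulators, if
perturbed, would reproduce (or oppose) the BA expression signature?

Two arms answer it:

1. **Expression arm** — compare BA vs control organoid counts,
   extract the most extreme up/down genes, and ask which annotated
   pathways are biased toward high or low fold changes.
2. **Activation arm** — take a genome-scale CRISPRi Perturb-seq
   screen (thousands of single-gene knockdowns with single-cell
   transcriptome readout), summarize each knockdown ("factor") by its
   transcriptome-wide effect profile, and ask which factors
   systematically shift the BA gene sets up or down.

## Statistical core

All bias statistics reduce to one primitive, the two-sample Wilcoxon
rank-sum test, with a deliberately separated direction call:

* **p-value** — two-sided. Mid-ranks handle ties. For pooled sample
  sizes up to 20 the null distribution of the rank-sum is enumerated
  exactly over all $\binom{n_1+n_2}{n_1}$ label assignments (a dynamic
  program over half-integer rank sums, so ties are enumerated exactly
  too) and $p = \min\!\big(1,\, 2\min(P(W\le w), P(W\ge w))\big)$.
  Above 20, a tie-corrected normal approximation with a 0.5 continuity
  correction is used; the test suite bounds its deviation from the
  exact p at $n_1=n_2=8$ by 0.02.
* **direction** — the sign of $\mathrm{median}(x)-\mathrm{median}(y)$;
  an exact median tie falls through to the sign of the mean difference,
  then to 0. Reporting a two-sided p plus a separate direction (rather
  than one-sided p-values) keeps every downstream table
  sign-symmetric: negating all inputs flips directions and changes no
  p-value, a property asserted by tests at every level.
* p-values are clamped at $10^{-300}$ before any $\log_{10}$, so signed
  scores stay finite (|score| caps near 300).

Multiple testing uses the Benjamini–Hochberg step-up adjustment, and
over-representation of factor categories uses the upper-tail
hypergeometric probability accumulated in log space. Both are
implemented in the package and verified against independent oracles
(`p.adjust`, `phyper`, and hand enumeration) to $10^{-12}$.

## Expression arm

**Filtration.** Genes with a total of fewer than `min_total = 10` reads
across all samples are removed — the one explicit filtering rule this
kind of dataset ships with. Filtration is idempotent.

**Normalization.** Median-of-ratios size factors: over genes positive
in every sample, each sample's factor is the median ratio of its counts
to the gene's geometric mean, rescaled so the factors have geometric
mean 1.

**DE estimate.** `estimate_de()` is an intentionally lightweight
estimator: `log2fc` is the ratio of pseudocounted normalized group
means, and the p-value is a per-gene rank-sum test across samples when
both groups have at least three samples (exact at these sizes), else a
pooled-variance Wald test on log-normalized means. It makes no claim to
replicate shrinkage-based NB fitters; its role is to produce a sound
`log2fc` ranking on synthetic and exploratory data. For published
analyses, `read_de_table()` accepts an externally computed table
(`gene_id`, `log2fc`, `p`[, `q`]) and every downstream stage runs
unchanged — the contributions of this pipeline are all downstream of
the fold-change ranking.

**Extreme sets.** `select_extreme_sets()` takes the `k = 100` genes
with the highest and lowest `log2fc` (pure ranking over all retained
genes, no significance pre-filter). Boundary ties break by smaller q,
then lexicographic gene id, so the sets are reproducible; the realized
boundary fold changes are logged.

**Pathway bias.** For each pathway with at least `min_overlap = 5`
genes in the DE universe, the in-pathway `log2fc` values are rank-sum
tested against the *remaining measured genes* (the universe minus the
intersection — unmeasured pathway members carry no score and are
ignored). BH correction runs across the tested pathways of one
collection; when KEGG- and GO-style collections are supplied
separately, each repository is corrected separately (they are distinct
hypothesis families; pooled correction is available by concatenating
collections). Pathways with `q < 0.005` are flagged enriched and
labeled up- or downregulated by the direction of the bias.

## Activation arm

**Input contract.** The screen arrives as already-processed per-cell
z-scores (cells × genes) with a per-cell perturbation label and a
reserved, case-insensitive `non-targeting` token. Reproducing the
upstream single-cell filtration/normalization is explicitly out of
scope — the module consumes the processed resource as published.

**Effect profiles.** For factor $r$ and gene $g$: rank-sum test of the
z-scores of $g$ in $r$-perturbed cells against all non-targeting cells;
BH across the genes of that one profile (the correction is "for
multiple genes", not across factors); then

$$\mathrm{score}(r, g) = \mathrm{direction} \times
  \big(-\log_{10} \max(q, 10^{-300})\big).$$

A q of 1 or a tied direction gives exactly 0 — the unique
sign-symmetric "no effect" value. Factors with fewer than
`min_cells = 2` perturbed cells are skipped and logged (the processed
reference resource itself measures factors in as few as 2 cells). The
test mode is `"auto"`: the exact enumeration below pooled $n = 20$
keeps tiny toy screens exactly reproducible, and the normal
approximation takes over at real screen scale where cell counts
routinely exceed it.

**Differential activation.** A factor's effect on a disease gene set is
the rank bias of its effect scores inside the set versus all remaining
screen genes — high in-set scores mean the perturbation upregulates the
set. Gene identifiers are joined case-insensitively after whitespace
stripping, and the realized overlap is logged: with a real cross-dataset
join only a fraction of a 100-gene set may be expressed in the screen
(overlaps as small as 18 and 10 of 100 occur in practice), so the test
runs from a floor of `min_set_genes = 3` but warns loudly below 10.

**Factor categories.** Four directional categories at strict per-category
p-value thresholds:

| category          | set     | direction | threshold |
|-------------------|---------|-----------|-----------|
| `down_on_BA_Down` | BA-Down | down      | p < 0.11  |
| `down_on_BA_Up`   | BA-Up   | down      | p < 0.01  |
| `up_on_BA_Down`   | BA-Down | up        | p < 0.07  |
| `up_on_BA_Up`     | BA-Up   | up        | p < 0.08  |

The thresholds are heterogeneous configuration defaults, not derived
quantities; they are exposed in `default_category_thresholds()` and the
run configuration. Categories are not forced disjoint — a factor can
legitimately downregulate both sets.

**Category enrichment.** Each category is tested against factor-level
pathway collections by the hypergeometric upper tail, with the universe
fixed to all factors profiled in the screen, BH within each category's
tested pathways, and `q < 0.05` flagging the differentially activated
pathways.

## Synthetic data: what it emulates and what it does not

The generators exist so that every stage has planted ground truth.

* `simulate_counts()` — negative binomial counts
  (variance $\mu + \phi\mu^2$), gene means log-uniform on 20–2000,
  dispersion $\phi = 0.02$, default design 5 cases vs 3 controls
  mirroring a small organoid cohort, planted genes at
  $|\mathrm{log2fc}| = 3$. The mean floor of ~20 reads reflects a
  *post-filtration* expression range, and together with the dispersion
  keeps the null fold-change noise small
  (mean $|\mathrm{log2fc}| < 0.2$ at 2000 genes, 6+6 samples — a design
  property of the generator, asserted by test). Lower floors put genes
  into a Poisson-noise regime where 6-sample fold changes are
  dominated by shot noise regardless of dispersion.
* `simulate_screen()` — z-scores simulated directly at the z level
  (Gaussian baseline, planted factors add a constant shift to their
  module genes), because the analysis consumes pre-normalized z-scores;
  UMI chemistry, guide assignment and cell filtering are deliberately
  not emulated. Default scale — 500 genes, 50 factors, 20 cells per
  factor, 100 non-targeting cells — is the published screen scaled
  down by roughly 30× so a full calibration run takes seconds on one
  core.
* `simulate_pathways()` — uniform random sets plus an optional planted
  set appended verbatim.

All generators are pure functions of their configuration (the RNG state
is saved, seeded and restored), so reruns are byte-identical.

Passing the planted-recovery and calibration tests therefore shows the
machinery is correct and calibrated under idealized noise; it does not
show that real organoid cohorts or real Perturb-seq screens satisfy the
generators' independence and distributional assumptions (no correlated
gene modules under the null, no batch structure, no mean–variance
quirks beyond NB).

## Numerical and degenerate-input choices

* Exact rank-sum enumeration switches to the normal approximation at
  pooled $n > 20$ (above that, $\binom{n}{k}$ enumeration buys little
  and the approximation error is far below any decision threshold
  used here).
* All-tied inputs give $p = 1$, direction 0, score 0.
* `size_factors()` requires at least one gene positive in all samples
  and points the user at a pseudocount otherwise; `estimate_de()`'s
  Wald fallback maps a zero pooled variance to $p = 1$ (no difference)
  or the $10^{-300}$ floor (exact separation).
* Top-k boundary ties and effect-matrix row order are resolved
  deterministically (q then id; lexicographic factors), making whole
  pipeline runs byte-identical under a fixed configuration — asserted
  at the md5 level.
* Category thresholds use strict inequality; a p exactly at a
  threshold is excluded.

## Reference problem sizes

The shipped test and acceptance runs use: the 36-cell grid of group
sizes ≤ 6 for exact-oracle equivalence; a 50-factor × 20-cell ×
500-gene null screen plus 200 gene-label permutations × 40 pathways on
a 2000-gene universe for calibration; 20 replicates each of the
planted-activator screen (Δ = 3, 25-gene module, 40 perturbed vs 100
control cells among 5 factors) and the planted pathway (+2 log2fc shift
in 40 of 1000 genes, among 50 null pathways); and a small two-arm file
bundle run twice for determinism. These sizes were chosen to make the
sampling error of each rate small relative to its acceptance margin
while keeping a full run desk-scale.

## Known limitations

* The DE stand-in has no dispersion shrinkage and supports only a
  two-group, single-factor design (no batch covariate — matching the
  cohort it emulates, where all samples were processed together).
* The activation test treats genes as exchangeable under the null;
  correlated gene modules inflate the effective significance of the
  bias statistic, which is one reason the four category thresholds are
  configuration, not calibrated quantities.
* Competitive vs self-contained enrichment variants, permutation-based
  GSEA and leading-edge analysis are out of scope.
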
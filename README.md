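# bilactivr

Differential-activation analysis for biliary atresia (BA) organoid
transcriptomics: from a bulk RNA-seq count matrix and a CRISPRi
Perturb-seq screen to the upstream regulators ("factors") whose
perturbation shifts the disease expression signature.

## Who it is for

Computational biologists who have (a) a small case/control bulk RNA-seq
cohort — here, extrahepatic cholangiocyte organoids from BA patients
versus controls — and (b) access to a processed genome-scale
perturbation screen (per-cell gene z-scores with per-cell perturbation
labels and non-targeting controls), and who want a tested, reproducible
implementation of the discovery pipeline rather than a one-off script.

## What it computes

**Expression arm.** Genes with fewer than 10 total reads are removed;
counts are normalized by median-of-ratios size factors; a lightweight
rank-based estimator (or an externally supplied DE table) produces
per-gene log2 fold changes with BH q-values, positive = up in BA. The
100 genes with the highest / lowest log2FC form the **BA-Up** /
**BA-Down** sets. Each pathway *P* is tested for rank bias:

> *p(P)* = two-sided Wilcoxon rank-sum of { log2FC : g ∈ P } vs
> { log2FC : g ∉ P }, BH-corrected across the pathways of a collection;
> pathways with q < 0.005 are "differentially expressed pathways",
> up- or downregulated by the direction of the bias.

**Activation arm.** For each factor *r* and gene *g*, the z-scores of
*g* in *r*-perturbed cells are rank-sum tested against all
non-targeting cells, with BH correction across genes within the
profile. The **perturbation effect score** is

> score(r, g) = sign(median shift) × (−log10 q(r, g)),

clamped so |score| ≤ ~300 and exactly 0 when q = 1 or the direction
ties. The *differential activation* of a BA gene set under factor *r*
is the rank bias of score(r, ·) inside the set versus the remaining
screen genes. Factors are classified into four categories
(down-on-BA-Down p < 0.11, down-on-BA-Up p < 0.01, up-on-BA-Down
p < 0.07, up-on-BA-Up p < 0.08, strict inequalities), and each
category is tested for pathway over-representation by the
hypergeometric upper tail (BH within category, enriched at q < 0.05).

All rank tests use exact enumeration at pooled n ≤ 20 and a
tie-corrected, continuity-corrected normal approximation above; the
statistical primitives are implemented in the package and verified
against independent oracles to 1e-12. Synthetic-data generators with
planted ground truth (`simulate_counts()`, `simulate_screen()`,
`simulate_pathways()`) make every stage testable without downloads.

## Worked example

```r
library(bilactivr)

## expression arm on synthetic data with 30 planted up / 30 down genes
sim  <- simulate_counts(n_genes = 1000, n_case = 5, n_control = 3,
                        n_up = 30, n_down = 30, effect_log2fc = 3, seed = 7)
de   <- estimate_de(filter_genes(sim$cm))
sets <- select_extreme_sets(de, k = 30)
#> extreme sets: BA-Up log2fc >= 2.692; BA-Down log2fc <= -2.198

coll <- simulate_pathways(30, c(10, 40), universe = de$gene_id,
                          planted = gene_set("planted_up",
                                             sim$truth$gene_id[sim$truth$log2fc > 0]),
                          seed = 8)
classify_pathways(de, coll)
#> pathway_bias_table: 31 pathways tested, 1 enriched at q < 0.005
#>       pathway n_in         p         q direction median_in median_out enriched
#> 31 planted_up   30 9.775e-21 3.030e-19        up   2.99691  -0.012691     TRUE
#> 6       PW006   32 1.587e-01 8.154e-01      down  -0.03077  -0.006142    FALSE
#> ...

## activation arm: factor F004 planted to raise the BA-Up genes by +3
scr <- simulate_screen(n_genes = 1000, n_factors = 10, cells_per_factor = 40,
                       n_nt_cells = 100,
                       planted = list(list(factor_id = "F004",
                                           module = sets$up$genes, delta = 3)),
                       seed = 9)
em   <- effect_matrix(scr$screen)
act  <- activation_table(em, list(sets$up, sets$down))
classify_factors(act)
#> factor_categories:
#>   down_on_BA_Down  (p < 0.11 ): 0 factors
#>   down_on_BA_Up    (p < 0.01 ): 0 factors
#>   up_on_BA_Down    (p < 0.07 ): 0 factors
#>   up_on_BA_Up      (p < 0.08 ): 1 factors
```

The one factor in `up_on_BA_Up` is the planted activator `F004`: its
knockdown cells shift the BA-Up module upward, so its effect-score
profile is rank-biased high on that set — exactly the signature the
pipeline is built to detect. The first table shows the planted pathway
dominating the bias ranking (q ≈ 3e-19, direction up) while null
pathways sit at q ≈ 1; the boundary log2FC values printed by
`select_extreme_sets()` describe the realized cutoffs of the extreme
sets.

File-based runs use `run_config()` + `run_expression_arm()` /
`run_activation_arm()`, which read TSV/GMT/MatrixMarket inputs and
write every stage table, a run log, provenance JSON and the resolved
configuration into the output directory; reruns with the same
configuration are byte-identical.

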
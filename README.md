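# coresist

Co-resistance analysis of cell-line × drug response panels.

## The problem

Large pharmacogenomic screens (GDSC-style: ~1000 cancer cell lines × ~265
drugs) record one summary response per cell line and drug — a log IC50 in µM,
or an activity-area score. When the same cell line is classified resistant to
two chemically different drugs, that pair shares a *co-resistance* signature;
aggregated over the panel, these signatures reveal likely collateral
resistance between drug classes (e.g. antimitotic chemotherapy and EGFR
tyrosine-kinase inhibitors), candidate bypass genes, and rational drug
combinations. `coresist` packages that analysis for researchers in
pharmacogenomics and drug-resistance biology:

1. **Binarization (waterfall method).** Each drug's responses are sorted in
   decreasing order. If the sorted curve is near-linear — absolute Pearson
   correlation *r* with its rank index ≥ 0.95 — the sensitive/resistant
   cutoff is the median; otherwise it is the major inflection point, the
   sorted value with maximal perpendicular distance to the chord joining the
   first and last points (both axes min–max rescaled). Polarity is explicit:
   on log IC50, low = sensitive; on activity area, high = sensitive.
2. **Co-resistance quantification.** For a drug pair (a, b), the
   co-resistance count is |lines resistant to both| over the lines evaluable
   for both; counts are min–max scaled to [0, 1] across the pair family and
   binned (< 10%, < 60%, ≥ 60%). A focal drug is ranked within the resistant
   panel of another drug by the conditional frequency
   (panel lines resistant to d) / (panel lines measured for d), with
   optional exclusion of the focal drug's chemical-similarity group.
3. **Genomic association.** Per co-resistance case, within-case alteration
   frequencies (copy-number amplification/deletion segments, driver
   mutations, CpG hypermethylation) are correlated across cases (Pearson by
   default); mutation-type profiles (missense, nonsense, essential splicing,
   frameshift) are tallied; cell lines are stratified by a gene's raw
   expression intensity (cutoff 4) and 22 receptor tyrosine kinases are
   ranked by case/stratum-standardized mean expression.
4. **Gene-set matching.** Each case's top-k (default 1000) upregulated genes
   (mean difference, co-resistant vs other evaluable lines) are intersected
   with annotated sets (e.g. EMT, cancer stem cell programs); the reported
   proportion is |top ∩ set| / |set|.
5. **Dose–response analytics.** Four-parameter logistic fits
   f(d) = bottom + (top − bottom)/(1 + (d/m)^h), closed-form ICx inversion
   ICx = m·(x/(1−x))^(1/h), IC50 fold-change resistance calls, and
   Chou–Talalay combination indices CI = d_a/Dx_a + d_b/Dx_b
   (CI < 1 synergy, = 1 additive, > 1 antagonism).

A synthetic-data generator (`sim_config()`, `simulate_bundle()`) emulates the
screen's shape — per-drug bimodal sensitive/resistant response mixtures,
planted co-resistant pairs via shared latent states, alteration and
expression signals coupled to resistance, a planted AXL–EGFR expression
correlation — with full ground truth, so the whole pipeline is testable
offline.

## Worked example

```r
library(coresist)

cfg    <- sim_config(n_cell_lines = 300, n_drugs = 20, n_genes = 500, seed = 42)
bundle <- simulate_bundle(cfg)            # planted pairs: D001:D002, D003:D004, D005:D006

calls <- binarize_response(bundle$response)
calls$thresholds[["D001"]]
#> waterfall threshold [D001]
#>   n = 285, linearity r = -0.9670, rule = median
#>   threshold = -5.3187
```

285 non-missing responses; the sorted curve was near-linear (|r| ≥ 0.95), so
the cutoff is the median log IC50, −5.32 µM: lines above it are called
resistant.

```r
pairs <- normalize_frequencies(coresistance_pairs(calls, colnames(calls$calls)))
tab   <- coresistance_table(pairs)
head(tab[order(-tab$count), ], 4)
#>  drug_a drug_b count n_evaluable normalized_frequency degree_bin
#>    D001   D002    98         271            1.0000000       high
#>    D005   D006    96         272            0.9672131       high
#>    D003   D004    92         271            0.9016393       high
#>    D002   D014    82         271            0.7377049       high

rank_drug_in_panel(calls, "D001", "D002")
#> rank of D002 in D001-resistant panel (142 lines): 1 of 19
```

The three planted pairs top the network's high degree bin, and the planted
partner D002 ranks first among the 19 drugs scored in D001-resistant lines.

```r
case   <- coresistance_count(calls, "D001", "D002")
strata <- stratify_by_expression(bundle$expression, "EGFR", 4)
head(rank_rtks(bundle$expression, list(case), strata, cfg$rtk_genes)$ranking, 3)
#>   gene mean_zscore rank
#>    AXL   3.5572341    1
#>   INSR   0.7884184    2
#>  ERBB2   0.3004117    3
```

AXL — planted 3 sd above the other RTKs in co-resistant lines — ranks first.
The case's top-50 upregulated genes recover 98% of the planted set
(`match_proportion`). Dose–response analytics are exact on clean curves:

```r
d   <- 10^seq(-3, 2, length.out = 8)
fit <- fit_logistic4(d, 1 / (1 + (d / 0.5)^1.5))
inhibitory_concentration(fit, c(0.10, 0.25, 0.50, 0.75))
#>      IC10      IC25      IC50      IC75
#> 0.1155602 0.2403749 0.5000000 1.0400419

combination_index(0.3, 0.4, 1.2, 1.5)
#>        dose_a dose_b Dx_a Dx_b        CI verdict
#> dose_a    0.3    0.4  1.2  1.5 0.5166667 synergy
```

`run_pipeline()` drives all stages from a JSON config and writes calls,
thresholds, pair tables, GraphML/edge-list networks, association matrices,
RTK rankings, gene-set match tables and a run manifest with input checksums.
A command-line front end lives at `inst/cli/coresist.R`
(`simulate`, `binarize`, `coresist`, `rank`, `doseresponse`, `ci`, `run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full analysis from scratch at the given seed: it simulates a
panel-scale bundle (1001 cell lines × 265 drugs, three planted
antimitotic ↔ RTK-inhibitor pairs), runs every pipeline stage
(binarize → co-resistance → association → gene sets) plus the dose–response
analytics, and writes the JSON report to `--out`.

## Real data

The package reads GDSC-style flat tables (CSV matrices, long TSV mutation
calls, one-gene-per-line sets); it does not download them. Point
`run_pipeline()` at locally saved exports of the screen and expression
archive to reproduce the analysis on real data.
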
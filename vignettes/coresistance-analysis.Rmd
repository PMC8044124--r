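---
title: "Co-resistance analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-resistance analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresist)
```

This vignette is the package's account of its science: the statistical
procedures, the parameters that matter and their defaults, what the synthetic
generator does and does not emulate, and the design choices made where the
underlying methodology is conventionally under-specified.

## 1. Waterfall binarization

A drug's response vector (one summary score per cell line) rarely comes with
a principled sensitive/resistant cutoff. The waterfall method supplies one
from the shape of the sorted response curve:

1. Sort the $n$ non-missing values in decreasing order, $v_1 \ge \dots \ge
   v_n$, and compute the Pearson correlation $r$ between the sorted values
   and their rank index.
2. If $|r| \ge$ `linearity_cutoff`, the curve is effectively linear — there
   is no distinguished inflection — and the threshold is the **median**.
3. Otherwise the threshold is the **major inflection point**: the sorted
   value whose point has maximal perpendicular distance to the chord joining
   $(1, v_1)$ and $(n, v_n)$, with both axes min–max rescaled to $[0,1]$
   first. Ties take the smallest index.

**Parameters.** `linearity_cutoff` defaults to 0.95, the convention of the
large cell-line panels in which this discretization originates; it is exposed
because reasonable panels differ. Axis rescaling before the distance
computation is deliberate: unscaled, the index axis (1..n, often hundreds of
units) dominates the response axis (a few log units) and the "inflection"
degenerates to whichever end of the curve is steeper. The perpendicular
(rather than vertical) distance makes the geometry symmetric in both axes;
a brute-force chord-distance oracle in the tests pins this definition.

**Polarity** is an explicit argument because the two response conventions
disagree: on an activity-area scale high values mean sensitive, on log IC50
low values mean sensitive. Both are supported (`high_is_sensitive`,
`low_is_sensitive`); neither is guessed from the data. A value exactly at
the threshold is always called *sensitive* — an arbitrary but fixed and
tested convention; under polarity flips the boundary call therefore stays
sensitive while all other calls mirror.

Degenerate inputs (fewer than 3 finite values, zero variance) are errors at
the single-drug level; the matrix-level wrapper `binarize_response()`
downgrades them to all-missing calls with a warning so one broken column
does not abort a 265-drug panel.

## 2. Co-resistance quantification

Two frequency notions coexist and are deliberately kept apart:

- **Network edges** use the min–max-normalized joint count: the number of
  lines resistant to both drugs, rescaled to $[0,1]$ across the pair family
  being compared, then binned low $[0, 0.10)$ / mid $[0.10, 0.60)$ / high
  $[0.60, 1]$. The high bin is closed at 0.60 to match the "≥ 60%"
  convention. Min–max scaling is order-preserving but depends on the pair
  set supplied — it is a display normalization, not a probability.
- **Panel ranking** uses the conditional frequency among the panel drug's
  resistant lines: $\mathrm{score}(d) = $ (panel lines resistant to $d$,
  measured for $d$) / (panel lines measured for $d$). This is the only
  reading under which "the rank of drug Y among lines resistant to drug X"
  is well defined when missingness differs by drug.

Lines missing either call are excluded from numerator and denominator
(evaluable-lines semantics). Rank ties are broken deterministically: higher
evaluable count first, then lexicographic drug id — the underlying
methodology is silent here and any fixed rule serves; removing non-focal
drugs can then never worsen the focal drug's rank, a property the tests
check. Per-lineage frequencies are reported relative to the pan-cancer
frequency; lineages with fewer than `min_evaluable` (default 3) evaluable
lines are flagged unreliable rather than dropped, and a zero pan-cancer
frequency yields a missing ratio rather than an error. For ranking one drug
family by co-resistance with another, both the mean and the sum of
normalized frequencies are emitted, since either aggregate is defensible.

## 3. Genomic association

"Association" between co-resistance cases is computed as: within-case
alteration frequency vectors (fraction of the case's co-resistant lines
carrying each feature, denominators recorded), then Pearson correlation
between cases over their shared features. This reading — fractions in
gene/feature space, then cross-case correlation — is the default;
Spearman and Jaccard (on profiles binarized at frequency > 0) are exposed
as alternatives, and correlating in cell-line space is possible by
transposing the feature matrix. Features with data in none of the case's
lines are omitted, not reported as zero: missing is not absence. Entries
with fewer than 3 shared features or a zero-variance vector are flagged
missing, never silently imputed.

Mutation-type profiles tally records over the four canonical types;
gene–gene mutation correlations drop bins where either gene has no input
data pairwise (a real phenomenon in public panels, where e.g. nonsense
calls may simply be absent for a gene) and require at least 3 paired bins.

Expression stratification uses a raw log-intensity cutoff, default 4, the
conventional microarray "expressed" baseline; a value exactly at the cutoff
goes to the *high* stratum (fixed convention). RTK ranking z-scores the
per-RTK mean expression within each (case, stratum) cell across the RTK
list before averaging across cases: without standardization, cross-case
averages would be dominated by cases with globally brighter arrays.
Empty cells are flagged missing and skipped in the averaging.

## 4. Gene-set matching

"Upregulated" is operationalized as the mean expression difference between
the case's co-resistant lines and the remaining *evaluable* lines (those
with calls for both drugs but not co-resistant) on the log-intensity scale.
The rest group could alternatively be restricted to lines sensitive to both
drugs; the broader group is the default because it uses all information and
is the more conservative contrast. Fold change and pooled-sd-standardized
difference are selectable alternatives. The top-k list (default
k = 1000) breaks score ties lexicographically so results are deterministic.

The match proportion divides by the annotated set size,
$|{\rm top} \cap {\rm set}| / |{\rm set}|$ — the direct reading of
"proportion of annotated genes matched" — with the alternative
normalization by $k$ emitted alongside. No enrichment p-value is computed:
the analysis reports proportions, and adding a hypergeometric test would
suggest an inferential claim the design does not support.

## 5. Dose–response analytics

The viability model is the four-parameter logistic
$f(d) = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom}) / (1 + (d/m)^h)$
with midpoint $m > 0$ and Hill slope $h > 0$; the constrained variant
(top = 1, bottom = 0) is available. Fitting is multi-start least squares:
starts iterate in fixed order over $h \in \{0.5, 1, 2, 4\}$ and five
midpoints spanning the geometric dose range; each start is refined by BFGS
on the parameterization (bottom, log span, log m, log h) — so
bottom ≤ top and $m, h > 0$ hold by construction — and the winner gets a
derivative-free polish, which is robust near zero residual where
gradient-based steps stall. `nls()` was rejected as the backend because its
failure modes on noiseless (zero-residual) curves make exact-recovery
contracts unreliable. The convergence flag is honest: it reports the
optimizer's own status, and non-convergence blocks ICx computation.

ICx inversion is closed-form, $\mathrm{IC}_x = m\,(x/(1-x))^{1/h}$, where
$x$ is the fraction of the top-to-bottom span lost; IC50 = $m$ exactly.
Fold-change resistance is the plain IC50 ratio versus a reference
(parental) line. The combination index uses the Chou–Talalay mutually
exclusive form $CI = d_a/D_{x,a} + d_b/D_{x,b}$ without an interaction
term; the effect level $x$ at which $D_x$ values are taken is a required
user input, not a hidden default. Additivity is declared within a $10^{-6}$
tolerance of $CI = 1$.

## 6. The synthetic generator: what it emulates, what it does not

`sim_config()` states a world and the generator realizes it:

- **Responses.** Per drug, each line is latently resistant with probability
  `resistant_fraction` (default 0.3); observed log IC50 is Gaussian around
  the state's location (defaults: sensitive −6, resistant −2, sd 1 — a 4 sd
  mode separation on the µM log scale, the regime the waterfall method is
  designed to split, with thresholds landing near −4 to −5). Two Gaussians
  are the simplest bimodal family consistent with the discretization's
  assumptions; the real screen's response distributions are messier.
- **Planted pairs.** For a pair (a, b, κ), drug b's latent state copies
  drug a's with probability κ and is redrawn independently otherwise, so
  κ = 1 duplicates the column and κ = 0 is independence; the planted
  co-resistance count is monotone in κ (property-tested).
- **Missingness** is uniform at random, per drug column (rate 0.05);
  real missingness is structured by assay batches, which is out of scope.
- **Genomic features.** Binary alteration probability is base rate
  (default 0.1) plus an additive enrichment δ (default 0.2) in lines
  co-resistant to at least one planted pair; mutations follow the same
  logic at per-(line, gene) rates, with types drawn from configured
  proportions whose defaults keep missense dominant (0.55) and essential
  splicing rare (0.03), as in real panels.
- **Expression.** Independent Gaussians at mean 5, sd 1.5 on the
  log-intensity scale — chosen to span the stratification cutoff of 4 —
  except: AXL and EGFR are drawn jointly at correlation ρ (default 0.8);
  AXL (configurable via `rtk_case_shift`) gains 3 sd in co-resistant lines;
  each planted pair gets a disjoint planted upregulated set (default 50
  genes, +2 sd in the case's co-resistant lines). The gene universe default
  is 2000 — scaled down from a real transcriptome (~17,000) purely for
  memory and runtime; nothing downstream depends on the universe size
  beyond top-k saturation.
- **Determinism.** One master seed spawns fixed substream families
  (per drug, per gene, per planted pair), so identical configs produce
  byte-identical bundles and *adding* drugs or genes leaves existing
  columns untouched.

A green test on this world therefore establishes that the pipeline's
machinery recovers planted structure of the stated effect sizes; it does
not establish anything about effect sizes, lineage composition, drug
chemistry or assay noise in real screens, and the generator's `AXL`/`EGFR`
coupling is a stand-in for a correlation that in real data emerges from
biology, not construction. Note one interaction worth knowing: the
case-conditional AXL shift inflates AXL's marginal variance, so the
realized AXL–EGFR sample correlation is attenuated below ρ whenever both
signals are planted at once; recovery of ρ itself is assessed with the
shift disabled.

## 7. Numerical and degenerate-input policy

- Min–max scaling with all counts equal is an error (callers may fall back
  to raw fractions), not a silent division by zero.
- Association entries that cannot be computed (shared features < 3, zero
  variance) are `NA`, and every association matrix is symmetric with unit
  diagonal by construction.
- Mutation-type proportions sum to 1 to within 1e−12.
- The 4PL start grid is fixed and ordered, so fits are reproducible;
  noiseless curves are recovered to ≤ 1e−6 relative error and ICx
  round-trips through the curve to 1e−9 (both under test).
- All tabular outputs of `run_pipeline()` are re-readable by the package's
  own readers; schema violations (duplicate ids, non-numeric cells, unknown
  mutation types) name the offending row/column.

## 8. Known limitations

- The waterfall cutoff is scale-equivariant but not robust to heavy tails;
  a single extreme response can relocate the chord. Real screens cap tested
  concentrations, which truncates exactly those tails.
- Min–max normalization makes edge weights incomparable across different
  pair families; comparisons must stay within one normalization set.
- The association stage treats alteration frequencies as exchangeable
  across features; no linkage or pathway structure is modeled.
- Combination-index verdicts inherit all assumptions of the mutually
  exclusive Chou–Talalay form; Bliss/Loewe response-surface models are
  out of scope.
- The pipeline consumes pre-summarized response scores; refitting IC50s
  from raw dose–response plates belongs to the dose–response module and is
  not wired into the screen-level pipeline.
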
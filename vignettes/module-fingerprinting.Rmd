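---
title: "Module repertoire fingerprinting: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module repertoire fingerprinting: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txfingerprint)
```

## The statistic

A module repertoire is a fixed collection of co-expressed gene sets, each
pinned to a grid position (an aggregate row and a column). For one
case/control cohort, the pipeline asks of every module: *what fraction of
its member transcripts changes significantly, and in which direction?*

1. **Per-transcript direction calling.** Each gene is compared between
   cases and controls with a two-sample test on log2-scale abundances. A
   gene is called +1 (increased) when its adjusted p-value is at most
   `alpha` *and* its |log2 fold change| reaches `min_abs_log2fc`, with the
   sign of the call taken from the fold change; otherwise 0.
2. **Percent response.** With `n_detected` module members present in the
   data, `percent_up` and `percent_down` are the percentages of detected
   members called +1 and -1. The module's signed response retains the
   dominant trend: `+percent_up` if increases dominate, `-percent_down` if
   decreases do. Both percentages are kept alongside the signed value, so
   the mixed case (both directions present) is never lost.
3. **Fingerprint.** The vector of responses over all modules, drawn on the
   fixed grid, is the cohort's fingerprint; stacking fingerprints row-wise
   gives the cohorts-by-modules matrix used for cross-disease comparison
   and aggregate formation.

The analysis is group-level by design: a fingerprint describes a cohort
contrast, not an individual sample. Per-sample scores are out of scope.

## Statistical choices and their defaults

The percent-response definition leaves the inner significance test open,
so the package makes it explicit and configurable, and embeds the config
in every output:

- **Test: Welch's t (default).** Unequal-variance t is the safest default
  for log-intensity data with modest group sizes; Student's t and the
  Wilcoxon rank-sum test are available where pooled variance or rank
  robustness is preferred. All tests are two-sided because both increases
  and decreases are reported.
- **Multiplicity: Benjamini–Hochberg at `alpha = 0.05` (default).** The
  step-up FDR is implemented in-house (it is part of the package's core
  statistic path) and checked in the tests against both a literal
  suffix-minimum oracle and `stats::p.adjust`. Setting
  `multiplicity = "none"` gates on raw p-values instead.
- **Fold-change floor: `min_abs_log2fc = 0.5` (default).** A modest floor
  keeps trivially small but significant shifts from inflating responses in
  large cohorts. Set it to 0 to gate purely on significance.
- **RNA-seq inputs.** Linear-scale abundances (RPKM-like) should be run
  with `rnaseq_transform = "log2_plus1"`, which maps x to log2(x + 1)
  before testing so microarray and RNA-seq cohorts are compared on the
  same scale. Negative inputs under this transform are an error, not a
  silent fix.
- **Degenerate genes.** A gene with zero variance in both groups gets the
  limit p-value: 1 when the group means agree, 0 when they differ. The
  pipeline never emits NaN.

Published fingerprints computed with other gates (raw p, different
thresholds) may differ from the defaults here; the config exists precisely
so such settings can be reproduced.

## Denominator, coverage, and the tie rule

- **Denominator = detected members.** Percentages use the number of module
  members actually present in the data, not the module's declared size.
  This keeps responses comparable across platforms that cover a module
  unevenly; coverage is reported separately so nothing is hidden. The
  declared-size alternative can be read off the output, since `n_members`,
  `n_detected`, and the percentages are all present.
- **Low coverage.** A module with fewer than `min_coverage_genes = 5`
  detected members is flagged and its response left undefined (NA), never
  zero-filled: "no information" and "no change" are different statements.
  Five genes is a deliberate floor — the smallest packaged module has 14
  members, so a five-gene minimum keeps percentages meaningful without
  silently dropping modules on sparse platforms.
- **Tie rule.** When `percent_up == percent_down != 0`, the direction
  whose significant members carry the larger summed |log2 fold change|
  wins; an exact tie yields 0. This rule is deterministic, uses available
  effect-size evidence, and is antisymmetric under a case/control label
  swap — a property the tests exercise on random direction tables.

## Aggregate formation and co-clustering

Aggregates group modules whose response profiles across a reference panel
of cohorts are similar. The reference procedure is hierarchical
agglomerative clustering of module columns with distance
1 − Pearson correlation and complete linkage, cut at a chosen `k`;
correlation distance matches the idea of "similar patterns" regardless of
response amplitude, and complete linkage keeps aggregates compact. Both
are configurable (Euclidean distance, any `hclust` linkage). Missing
entries are tolerated up to a per-module fraction (default 0.5) via
pairwise-complete correlations; emptier columns are excluded with a
warning.

Aggregate labels are positional — "A1", "A2", ... in order of first
appearance along the dendrogram leaf ordering — and deterministic for
fixed input. They make no identity claim about any published aggregate
numbering; a published assignment, where available, is supplied by the
user as data. Heatmap ordering clusters rows and columns independently
with the same metric; a degenerate axis keeps its input order with a
warning.

## The synthetic-cohort generator

`generate_cohort()` realises a simple, fully controlled generative model
on the log2 scale: each gene draws a baseline mean uniformly from
`baseline_mean_range` (default 6–12, typical log2 microarray intensities)
and an SD from `baseline_sd_range` (default 0.25–1); all samples are
independent Gaussians; each planted effect shifts the case means of a
seeded random subset of `round(fraction_affected * module_size)` member
genes by `shift` per-gene SDs. Defaults of 30 cases vs 30 controls and
1000 background genes mimic a modest whole-blood cohort. One master seed
feeds named substreams (baselines, subset choice, noise) so perturbing one
component leaves the others' draws untouched, and the truth table records
exactly which genes moved.

This model is deliberately idealised. It emulates coordinated within-module
shifts — the structure the statistic assumes — but not count-level noise,
platform or batch effects, gene–gene correlation beyond the planted
blocks, or heteroscedastic effects (shifts move means only, giving the
clean recovery limit `response -> 100 * fraction_affected` when per-gene
power is near 1). Passing recovery tests therefore demonstrates
correctness of the pipeline's computations, not robustness to every
real-data pathology.

`generate_reference_panel()` plants block structure directly at the
response level: modules in a block share a cohort profile (profiles are
centred and orthogonalised, so between-block correlation is exactly zero
by construction) plus independent noise (default profile SD 30, noise SD
5, giving within-block correlations around 0.97). This is the ground truth
against which aggregate recovery is scored by adjusted Rand index.

## Visual semantics

Grid plots follow the fingerprint conventions: a red spot for a
predominantly increased module, blue for decreased, spot radius scaling
linearly from 0 at |response| = 0 to the cell radius at 100, and a display
floor (default |response| >= 15) below which no spot is drawn, so only
predominant changes are visible. Two near-synonymous "no change" renderings
are disambiguated deliberately: **white** background means evaluated but
unchanged, **gray** means not evaluable in this dataset (low coverage).
Output is SVG because vector output is byte-stable for identical input on
a given platform, which makes rendering testable by checksum; the plotting
functions also return their cell geometry invisibly so the fixed-position
guarantee can be asserted without parsing SVG.

## Problem sizes used by the test suite

The shipped tests run the pipeline at sizes chosen to give the statistics
room to converge while keeping the suite quick: BH agreement on 1,000
random p-vectors of lengths 1–1000; response recount and antisymmetry on
500 random direction tables; planted-fraction recovery at fractions 0.25 /
0.5 / 1.0, shift 10 SD, 30 vs 30 samples, module size 20, over 20 seeds;
null calibration on 5,000 genes at 20 vs 20; and 2- and 4-block aggregate
recovery over 16 cohorts and 20 seeds. At a 10-SD shift per-gene power is
essentially 1, so recovered responses concentrate on 100 × fraction and
the Monte-Carlo standard errors are tiny; the recovery assertions use
those errors, not looser bands.

## Known limitations

- Group-level contrasts only; no paired designs, covariates, or
  longitudinal trajectories.
- No count-model differential expression; RNA-seq inputs are assumed
  pre-normalised to an abundance scale.
- Gene identifiers are opaque case-sensitive symbols; mapping across
  annotation versions is upstream's job.
- The packaged A35 fixture carries only the published representative genes
  per module (flagged non-exhaustive); full repertoire memberships must be
  supplied by the user to fingerprint real cohorts at full coverage.
- Choosing the number of aggregates `k` is the user's decision; no gap
  statistic or automatic cut is provided.
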
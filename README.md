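# txfingerprint

Group-level blood transcriptome fingerprinting against a fixed repertoire
of transcriptional modules.

Whole-blood transcriptome profiles can be compared across diseases in a
way tissue biopsies cannot, but gene-by-gene comparisons travel poorly
between platforms. A *module repertoire* fixes that frame of reference: a
pre-determined collection of co-expressed gene sets (modules), each with a
permanent position on a grid (a row per *module aggregate*, a column per
module). For a case/control cohort, each module is summarised by its
**percent response**

```
percent_up   = 100 * (# member transcripts significantly increased) / (# detected members)
percent_down = 100 * (# member transcripts significantly decreased) / (# detected members)
response     = +percent_up  if increases dominate
             = -percent_down if decreases dominate      (range -100 .. +100)
```

with the **dominant trend retained** when a module contains both increased
and decreased transcripts. Because module positions on the grid are fixed,
fingerprints computed for independent cohorts — even on different
platforms — are directly comparable cell by cell, and a cohorts-by-modules
matrix of responses can be co-clustered to compare diseases.

`txfingerprint` implements this pipeline end to end:

- **Repertoire I/O** — GMT gene memberships plus a grid-layout/annotation
  TSV, validated and round-trippable (`read_gmt()`, `read_grid_layout()`,
  `assemble_repertoire()`); a packaged 21-module inflammation-associated
  grid row ships as a fixture (`load_packaged_a35()`).
- **Direction calling** — per-transcript case-vs-control calls in
  {-1, 0, +1} via Welch (default), Student, or Wilcoxon tests, an in-house
  Benjamini–Hochberg step-up FDR, and an optional log2(x+1) transform for
  linear-scale RNA-seq abundances (`call_directions()`, `bh_adjust()`).
- **Fingerprinting** — the percent-response statistic
  (`module_response()`), whole-cohort fingerprints
  (`fingerprint_cohort()`), and cross-cohort stacking
  (`stack_fingerprints()`).
- **Aggregate clustering** — hierarchical clustering of module response
  profiles across a reference cohort panel (1 − Pearson correlation,
  complete linkage by default) to form aggregates (`build_aggregates()`),
  plus row/column co-clustering for heatmaps (`cocluster_matrix()`).
- **Synthetic cohorts** — a Gaussian generator with planted module effects
  and a truth table (`generate_cohort()`), a Monte-Carlo response oracle
  (`expected_response()`), and planted-block reference panels
  (`generate_reference_panel()`).
- **Plots & CLI** — fixed-position grid plots and clustered heatmaps as
  byte-stable SVG (`plot_fingerprint_grid()`,
  `plot_fingerprint_heatmap()`), and a `txfp` command-line wrapper
  (`inst/cli/txfp`) with `fingerprint`, `simulate`, `aggregate`,
  `plot-grid`, `plot-heatmap`, and `validate` subcommands.

## Worked example

Simulate a 30-vs-30 cohort over a 4-module repertoire in which all of
module M2 is shifted up by 4 baseline SDs and half of M3 is shifted
strongly down, then fingerprint it:

```r
library(txfingerprint)

genes <- setNames(lapply(1:4, function(i) sprintf("M%d_G%02d", i, 1:20)),
                  paste0("M", 1:4))
layout <- data.frame(module_id = names(genes), aggregate = "A1",
                     column = 1:4, n_transcripts = 20L,
                     annotation = NA_character_)
toy <- assemble_repertoire(genes, layout)

spec <- synthetic_cohort_spec(
  toy, n_cases = 30, n_controls = 30,
  effects = list(planted_effect("M2", fraction_affected = 1,   shift = 4),
                 planted_effect("M3", fraction_affected = 0.5, shift = -10)),
  background_genes = 500, seed = 42)
sim <- generate_cohort(spec)
fp <- fingerprint_cohort(sim$expr, sim$groups, toy, cohort = "simulated")
as.data.frame(fp)
```

```
  module_id aggregate column n_members n_detected coverage percent_up
1        M1        A1      1        20         20        1          0
2        M2        A1      2        20         20        1        100
3        M3        A1      3        20         20        1          0
4        M4        A1      4        20         20        1          0
  percent_down response low_coverage
1            0        0        FALSE
2            0      100        FALSE
3           50      -50        FALSE
4            0        0        FALSE
```

The fully planted module reads +100 (every member significantly up), the
half-planted module reads −50 (the planted half significantly down, the
rest unchanged), and the untouched modules read 0. `plot_fingerprint_grid(fp,
"fp.svg")` renders this as one red spot and one blue spot at their fixed
grid cells.

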
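# glycoNTC

Statistical toolkit for studies linking **glycolysis to proliferation
during neural tube closure**. When cranial neural tube closure fails — as
in the *miR-302* knockout mouse — the question is whether the ectoderm has
shifted toward glycolytic metabolism and faster cycling. Answering it from
the standard assays takes a chain of small bespoke analyses that are easy
to get subtly wrong; glycoNTC implements that chain as tested, reusable
functions:

- **Single-cell QC and normalization** — strict UMI filters (cells with
  < 200 or > 2500 total UMIs removed, boundaries kept), mitochondrial-gene
  removal by prefix, and counts-per-10k `log1p` normalization
  (`qc_filter`, `log_normalize`).
- **Differential expression** — per-gene two-sided Wilcoxon rank-sum test
  (normal approximation, tie-corrected) with BH adjustment, and
  high-expressor cell subsetting (`differential_expression`,
  `subset_by_expression`).
- **Pathway scoring** — per-population mean expression over gene sets,
  normalization to the lowest-expressing population, stage ratios, and
  knockout/wildtype fold changes computed *per gene per population first*,
  then averaged to pathway / population / ectoderm level:

  FC(g, p) = (mean KO expr + ε) / (mean WT expr + ε), ε = 1e-9,

  with means taken on the de-logged (normalized-counts) scale so a k-fold
  change in counts reports as k (`population_pathway_mean`,
  `normalize_to_min_population`, `stage_change`, `genotype_fold_change`,
  `subpathway_fold_change`).
- **Threshold co-expression** — cells where both genes of a pair exceed an
  expression threshold (default > 1 on the log scale), with KO/WT ratios
  on fractions and counts (`coexpression_count`, `coexpression_panel`).
- **miRNA-target overlap** — exact intersection of predicted-target lists
  with pathway and sub-pathway sets (`intersect_targets`).
- **Metabolomics** — pooled-QC injection-order drift normalization,
  per-metabolite Student t-tests at α = 0.05 (no multiple-testing
  correction, by protocol), pathway summaries with both "cumulative"
  fold-change definitions, and top-changed ranking
  (`qc_drift_normalize`, `differential_abundance`,
  `pathway_metabolite_summary`, `rank_top_changed`).
- **PFK kinetics** — sliding-window OLS over A340 traces (r² ≥ 0.95 gate,
  |slope| maximization) to estimate phosphofructokinase activity and its
  genotype ratio (`fit_linear_region`, `pfk_activity`,
  `activity_fold_change`).
- **Simulators with ground truth** — negative-binomial single-cell
  datasets, drifting LC/MS runs with pooled QCs, and lag/linear/plateau
  absorbance traces, each serializing every injected effect
  (`generate_sc_dataset`, `generate_metabolite_dataset`,
  `generate_pfk_traces`, `generate_target_list`).

A command-line front end (`exec/glycoNTC`) exposes each stage as a
subcommand (`simulate`, `qc`, `normalize`, `de`, `pathscore`, `coexpr`,
`targets`, `metab`, `pfk`) with YAML config support and full
config-and-seed logging.

## Worked example

Simulate a two-genotype embryo dataset in which three upper-glycolysis
genes are knocked up (Pfkp 4.5×, Pfkfb3 2.5×, Hk1 2×) and the knockout has
1.6× more cells in a cycling state, then recover those effects:

```r
library(glycoNTC)

sim <- generate_sc_dataset(sc_sim_config(seed = 42, cells_per_population = 300))
qw  <- qc_filter(sim$wt, sim$annot_wt)
qw$report
#>   n_input_cells n_low_complexity_removed n_doublet_removed n_mito_genes_removed n_output_cells
#> 1          1800                       36                36                    5           1728

qk <- qc_filter(sim$ko, sim$annot_ko)
lw <- log_normalize(qw$matrix); lk <- log_normalize(qk$matrix)

fc <- genotype_fold_change(lw, lk, qw$annot, qk$annot,
                           sim$catalog["glycolysis"], level = "ectoderm")
fc[fc$gene %in% c("Hk1", "Pfkfb3", "Pfkp"), ]
#>       pathway   gene fold_change n_averaged
#> 45 glycolysis    Hk1        1.96          5
#> 53 glycolysis Pfkfb3        4.18          5
#> 56 glycolysis   Pfkp        4.15          5
```

Hk1 and Pfkp recover their injected multipliers (2 and 4.5) within
sampling error. Pfkfb3 reports ~4.2, not 2.5: it is also a member of a
co-expression pair, and the knockout's larger cycling fraction raises its
marginal mean — the generator records this closed-form marginal truth
(`sim$truth$gene_marginal_fc$Pfkfb3` ≈ 4.0), and the estimate matches it.

```r
cw <- coexpression_count(lw, "Ccnd1", "Ccnb1")
ck <- coexpression_count(lk, "Ccnd1", "Ccnb1")
coexpression_genotype_ratio(cw, ck)$ratio
#> fraction WT 0.104, KO 0.163 -> ratio 1.57   (injected 1.6)

res <- differential_abundance(qc_drift_normalize(
         generate_metabolite_dataset(seed = 42)$table))
head(rank_top_changed(res)$up[, c("metabolite", "fold_change")], 3)
#>               metabolite fold_change
#> 9  docosapentaenoic_acid        2.19
#> 4                    atp        1.91
#> 12 fructose_bisphosphate        1.87

act <- pfk_activity(generate_pfk_traces(seed = 42)$traces)
activity_fold_change(act[act$genotype == "WT", ], act[act$genotype == "KO", ])
#> ratio KO/WT 1.48 (p = 4.5e-07)   -- injected slopes -0.02 vs -0.03
```

Each number is the estimator reading back a known injected effect: the
fold changes within a few percent of truth, the co-expression ratio within
2% of the latent 1.6×, the top metabolite the injected 2.2× fatty acid,
and the PFK activity ratio within 2% of the 1.5× slope ratio.

## Layout

```
R/                  implementation (io/cli, sc QC+norm, DE, pathway scoring,
                    co-expression, target overlap, metabolomics, PFK, simulators)
exec/glycoNTC       command-line entry point
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests (fixtures built in code)
vignettes/          methods vignette: models, parameters, design choices
```
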
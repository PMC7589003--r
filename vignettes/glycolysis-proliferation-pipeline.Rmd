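---
title: "Linking glycolysis to proliferation in the closing neural tube: methods and design"
author: "glycoNTC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking glycolysis to proliferation in the closing neural tube: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoNTC)
```

# Scope

glycoNTC packages the downstream statistics used to ask whether failed
cranial neural tube closure is accompanied by a glycolytic and proliferative
shift in the ectoderm: per-population metabolic pathway scoring of single-cell
expression, knockout/wildtype fold-change aggregation, threshold
co-expression of cell-cycle gene pairs, pooled-QC-normalized differential
metabolite abundance, and phosphofructokinase (PFK) activity estimation from
coupled-assay absorbance traces. Upstream processing (alignment, clustering,
embedding, compound identification) is out of scope: population labels,
gene-set catalogs, predicted miRNA-target lists and metabolite annotations
enter as inputs.

# Single-cell quality control and normalization

Cells are filtered on total UMI count with strict inequalities: fewer than
`qc_min_umi` (default 200) removes low-complexity cells, more than
`qc_max_umi` (default 2500) removes putative doublets/triplets; boundary
values survive. We read the published wording of both filters as strict and
treat the upper bound as the *only* doublet rule — no statistical doublet
detection is layered on top. Mitochondrial genes are removed by symbol
prefix; the mouse convention `mt-` is the default because the organism is
mouse and no other convention is implied. Per-cell totals are computed on
the input matrix *before* mitochondrial removal: the UMI total is a property
of the sequencing library, and this choice makes the filter independent of
which genes are later retained (a property the test suite asserts).

Normalization is counts-per-`scale_factor` followed by `log1p`:
\[
x_{gc} = \ln\!\left(1 + \frac{k_{gc}\,s}{\sum_g k_{gc}}\right),
\]
with \(s = 10{,}000\) by default — the de facto standard for this
transformation. All expression thresholds in the package (the ">1"
co-expression rule, high-expressor subsetting) are defined on this scale.

# Fold changes: scale and aggregation order

Two deliberate choices shape every fold-change number the package reports.

**Means are de-logged.** Wherever a ratio of expression levels is formed
(differential expression `log2FC`, genotype fold changes), per-group means
are taken after undoing the log transform (`expm1`), i.e. on the
normalized-counts scale. A mean of logged values compresses ratios — a gene
whose counts rise 4.5-fold would report far less than 4.5 — whereas the
de-logged mean keeps a k-fold change in counts a k-fold change in the
reported value. This matches the convention of the widely used single-cell
toolkits. The per-population pathway *score* tables, in contrast, average
the log-scale values themselves: they feed the min-population normalization
and stage ratios, where the log-scale mean is the field's standard "average
expression" readout.

**Genes first, then means.** The genotype fold change is computed for each
gene individually within each population,
\(\mathrm{FC}_{g,p} = (\bar{x}^{KO}_{g,p} + \varepsilon) /
(\bar{x}^{WT}_{g,p} + \varepsilon)\) with \(\varepsilon = 10^{-9}\), and
only then averaged — arithmetically, each gene weighted equally — up to
pathway, population, or ectoderm level. The pseudocount keeps genes silent
in one genotype finite; genes silent in both report FC 1 (or log2FC 0 with
p = 1 in differential expression). A geometric-mean alternative is exposed
via `agg = "geometric"` for users who prefer ratio-symmetric averaging, but
the arithmetic mean is the default because the aggregation is described in
that order. The `"ectoderm"` level averages a gene's per-population fold
changes across the ectoderm-derived populations (all labels except
`non_ectoderm`), which is the natural reading of a single fold change quoted
"across all ectoderm-derived cell populations".

Pathway scores are normalized within each pathway to the lowest-expressing
population (`normalize_to_min_population`), so the minimal population scores
exactly 1 and other populations read as fold differences against it; a
non-positive minimum is an error naming the pathway rather than a silent
NaN.

# Differential expression

`differential_expression` is a two-sided Wilcoxon rank-sum test per gene on
the log-normalized values, using the normal approximation with tie
correction and no continuity correction — the default test of the standard
single-cell marker machinery, implemented here as an explicit contract
rather than a bit-level clone of any tool. P-values are Benjamini–Hochberg
adjusted across tested genes. No min-fraction or min-log-fold-change
prefilter is applied by default; both exist as arguments. Groups smaller
than three cells are refused: a rank test on fewer exchangeable units is
noise.

# Threshold co-expression

`coexpression_count` counts cells in which both genes of a pair exceed the
threshold (default 1.0, strict) on the log-normalized scale, and reports
each gene's mean expression within the co-expressing subset. Genotype
comparisons default to ratios of *fractions* because wildtype and knockout
datasets rarely contain equal cell numbers; the raw-count ratio is always
co-reported for comparability with cell-count bar charts whose
normalization is unstated.

# Metabolomics

**Drift correction.** Untargeted LC/MS runs drift with injection order;
pooled-QC samples injected at the start, every sixth injection, and at the
end provide an internal standard. Per metabolite, each value is divided by
the linear interpolation between flanking QC values at its injection order
(the nearest QC is reused beyond the ends) and rescaled by the metabolite's
median QC value to stay on the original abundance scale. The transform maps
every QC value onto that median, so a second application is a no-op — an
idempotence the tests assert to 1e-9 relative. Metabolites with a zero in
any QC sample are flagged and left untouched rather than divided by zero.

**Differential abundance.** A two-sided two-sample Student t-test (pooled
variance; Welch via `var_equal = FALSE`) per metabolite at
\(\alpha = 0.05\), on natural-scale abundances by default — a log transform
is available but not default, since the upstream protocol specifies plain
Student t-tests without one. Deliberately, *no multiple-testing correction*
drives the significance flag, mirroring the metabolomics protocol being
reimplemented; a BH column is emitted alongside for the reader. Degenerate
zero-variance metabolites report p = 1 when group means agree.

**Summaries.** "Cumulative" pathway fold change is under-determined in
common usage, so both candidates are always computed: the default is the
ratio of summed group means (reads as "total pathway metabolites", weights
abundant metabolites more), with the unweighted mean of per-metabolite fold
changes alongside. The two diverge whenever abundances are unequal — e.g.
WT means {1, 3} and KO means {2, 3} give 1.25 by sums and 1.5 by mean of
ratios — which is why neither is reported without the other.

# PFK kinetics

A coupled enzymatic cascade converts PFK flux into an NADH absorbance
change at 340 nm, read every minute for an hour. "The linear portion of the
curve" is not a formal object, so the package makes it one: every contiguous
window spanning `pfk_window_minutes` (default 10, at least 5 points) is fit
by ordinary least squares; among windows with \(r^2 \ge 0.95\) the one
maximizing |slope| is reported, falling back to the maximum-\(r^2\) window
when none qualifies. The gate keeps the search inside genuinely linear
stretches; the |slope| objective picks the steady-state phase rather than
the lag or plateau shoulders. Activity is |slope|, keeping the module
agnostic about whether the cascade consumes or produces NADH. An
all-constant trace is flagged and reported with slope 0 and \(r^2\) 0
instead of NaN. Genotype comparison is the ratio of mean activities with a
Student t-test on the per-embryo activities (designed for small groups,
e.g. 3 vs 3).

# The simulators, and what passing tests mean

Every stage is exercised against `generate_*` simulators that serialize
their ground truth, so recovery is checked against known injections rather
than against the package's own output.

**Single cell.** Counts are negative binomial (dispersion 0.5 — typical
scRNA-seq overdispersion) with mean = gene baseline × population effect ×
stage effect × genotype multiplier × cell library factor. Six populations
(five ectoderm-derived, one rest) × two stages × two genotypes, 300 cells
per population by default. Baselines are log-normal around 0.15 counts for
the ~400 catalog genes and 0.3 for 2,500 background genes; the background
dominates the library on purpose, so that injected multipliers perturb
per-cell totals — and hence the depth normalization — only mildly (a few
percent under the strongest injections). Without that padding,
composition shift would systematically deflate every normalized fold
change, which is a real analytical caveat of depth normalization, not a
simulator artifact. Library factors are log-normal (sdlog 0.3) with small
forced fractions at extreme factors so totals span both UMI thresholds and
the QC filter removes a predictable, truth-recorded cell set. Defaults
inject the headline pattern Pfkp 4.5×, Pfkfb3 2.5×, Hk1 2×; a 1.2×
glycolysis lift in neuroepithelium/neural crest over non-neural ectoderm;
and a 1.3× folic-acid stage effect.

Co-expression is induced by a latent Bernoulli "cycling" state that raises
both genes of a pair to a high mean (60 counts) in a controlled fraction of
cells (defaults 0.10 WT, 0.16 KO — a 1.6× shift). Pair genes get a low
off-state baseline (0.02 counts) because cyclins are effectively bimodal;
this also makes the latent fraction the expected co-expression fraction
almost exactly. Because the on-state mean scales with any genotype
multiplier, a gene that is both a pair member and a knockout target
(Pfkfb3) has a *marginal* fold change different from its injected baseline
multiplier; the generator records this closed-form marginal value in the
truth (`gene_marginal_fc`) so recovery tests compare against the right
number.

**Metabolomics.** Log-normal abundances (per-metabolite base level,
multiplicative noise at the configured CV, default 10%), a linear
multiplicative injection-order drift, and noise-free pooled-QC rows at pool
mean × drift — a deliberate idealization that makes exact drift removal a
sharp test. Defaults: n = 5 per group, QC every sixth injection, glycolysis
injections 1.9× (fructose bisphosphate), 1.8× (ATP), 1.4× (pyruvate) among
10 glycolytic metabolites, 2.2× docosapentaenoic acid. At these settings
three of the ten glycolysis metabolites are reliably significant at 0.05,
reproducing the 3-of-10 pattern the summary code is designed to count; the
seven null metabolites each still carry the nominal 5% false-positive risk,
so structural-fixture tests pin the seed.

**Kinetics.** Piecewise flat/linear/plateau traces at 1-minute steps over
60 minutes (5-minute lag, 30-minute linear phase) with Gaussian noise
(σ = 0.002 by default), three embryos per genotype at slopes −0.02 (WT) and
−0.03 (KO), i.e. a 1.5× activity ratio.

What these simulations do *not* emulate: ambient RNA, batch effects, UMI
saturation, doublet expression profiles (doublets exist only as large
libraries), correlated gene modules beyond the explicit cycling state,
heavy-tailed or missing metabolite intensities, QC-sample noise, and
instrument artifacts beyond smooth linear drift. Passing recovery tests
therefore demonstrates that the estimators are correct and well-calibrated
under the stated generative model — not that real data meet that model.

# Numerical and testing choices

Problem sizes in the shipped tests were chosen so the full suite runs in a
few minutes: oracle-equivalence fixtures are at most 20 × 50 (checked
exactly for integers, 1e-9 relative for floats against brute-force loops,
`stats::wilcox.test`, and `lm`); fold-change recovery uses 500 cells per
population over two populations and ten seeds with a ±10% pathway-level
tolerance; type-I error calibration uses 1,000 null metabolites at n = 4
per group against the exact binomial 95% band; slope recovery uses ten
seeds at σ = 0.002 with a ±5% tolerance. The small-sample ratio bias of
fold-change estimators (E[1/x̄] > 1/E[x̄]) is visible below ~200 cells per
population and is the reason recovery tolerances are stated at the cell
counts they are.

Known limitations: fold-change aggregation order (genes-then-cells vs
cells-then-genes) matters in principle — the package fixes genes-outer and
exposes the per-gene table so users can re-aggregate; the co-expression
threshold is applied to log-normalized values and is not depth-adaptive;
drift correction assumes piecewise-linear drift between QCs; the PFK window
rule can clip a curved but monotone trace to its steepest locally-linear
stretch, which is the intended behavior but means the reported window is
not a mechanistic "reaction phase".
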
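---
title: "Methods: cross-study consistency scoring for microbiome biomarkers"
author: "crossbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study consistency scoring for microbiome biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Single-cohort microbiome studies of obesity-associated metabolic disease
(obesity, type 2 diabetes, NAFLD) routinely nominate differentially
abundant taxa, but small sample sizes and cohort-specific confounding make
individual findings fragile. A biomarker worth pursuing should move in the
same direction across independent case-versus-control comparisons.
`crossbiome` operationalizes that idea: it standardizes the per-study
differential-abundance analysis and then scores each feature's
cross-comparison consistency.

## Consistency scores

For one feature evaluated across a set of independent comparisons, let
$n_1$ be the number of comparisons with a statistically significant
increase in the case group and $n_2$ the number with a significant
decrease. The consistency score is

$$\mathrm{CS} = \frac{n_1 - n_2}{\#},$$

where $\#$ counts the statistically significant comparisons
($n_1 + n_2$). CS ranges from $-1$ to $1$; $\pm 1$ means every significant
comparison agreed in direction. Because a single significant comparison
trivially yields $|\mathrm{CS}| = 1$, selection additionally requires
significance in at least `min_projects = 3` comparisons and
$|\mathrm{CS}|$ strictly greater than `min_abs_cs = 0.6`.

Two genuinely open readings were settled as follows and are exposed as
options rather than hidden:

* **Denominator.** Dividing by the significant comparisons ($n_1+n_2$) is
  the default; dividing by all evaluated comparisons is available via
  `denominator = "total"` in `consistency_table()`. The significant-only
  reading makes the $\pm 1$ bounds attainable and leans on the
  `min_projects` gate to suppress single-hit artifacts.
* **Weighting.** The weighted score is implemented as
  $$\mathrm{WCS} = \frac{\sum_i \log_2 \mathrm{FC}_i}{\sum_i
  |\log_2 \mathrm{FC}_i|}$$
  over significant comparisons, i.e. the up/down coefficient $a_i$ is the
  sign already carried by the fold change. A literal product of $a_i$ with
  a signed fold change would be degenerate (identically 1), so the
  signed-sum reading is used and recorded in every run manifest.

Features absent from a comparison's table reduce that feature's
`n_total` but never count toward $n_1$ or $n_2$: absence of evidence is
not evidence of change.

This is deliberately a vote-counting-plus-weighting scheme, not a formal
random-effects meta-analysis; it asks "does the direction replicate?"
rather than "what is the pooled effect?".

## The per-comparison pipeline

Each comparison is processed identically:

1. **Prevalence filter.** Features with zeros in *strictly more than* 80%
   of samples are removed (`max_missing_fraction = 0.80`; a feature zero
   in exactly 80% is kept). Zeros are treated as missing, since abundance
   tables encode absence as 0. Filtering happens at the analysis rank,
   after taxonomic collapsing.
2. **Zero replacement.** Remaining zeros become one tenth of the smallest
   positive value in the table (a single global minimum, the simpler
   reading of "minimum abundance"), so ratios and log fold changes are
   defined.
3. **Total-sum scaling.** Columns are divided by their totals. Rarefaction
   (exact multivariate-hypergeometric subsampling, seed recorded) and
   median-of-ratios size factors are available alternatives for count
   input.
4. **Testing.** Kruskal–Wallis by default (tie-corrected, chi-square
   reference), Wilcoxon rank-sum (exact for untied groups of at most 25),
   or the LEfSe-style LDA effect size. Significance uses raw `p < 0.05`
   by default to mirror common reporting practice in this literature;
   Benjamini–Hochberg q-values are computed always and can drive the call
   via `use_fdr = TRUE`.
5. **Effect size.** `log2FC` is the log2 ratio of arithmetic group means
   of the TSS abundances after zero replacement; its sign defines the
   `up`/`down` direction consumed by CS/WCS.

Alpha diversity (Shannon, natural log; Simpson in the Gini–Simpson form
$1-\sum p_i^2$, so larger = more diverse) is computed on TSS relative
abundances. Beta diversity offers Bray–Curtis on abundances and unweighted
Jaccard on presence/absence; Jaccard should be computed before zero
replacement, which destroys absences. Ordination is classical PCoA
(negative eigenvalues dropped and their magnitude reported) or NMDS
(Kruskal stress-1, 20 seeded restarts). Group separation is tested with
ANOSIM (999 permutations by default, seed recorded). UniFrac and PERMANOVA
are deliberately out of scope.

## LEfSe-style effect sizes

The functional-table analysis follows the LEfSe recipe in its common
two-class form: abundances are scaled to parts-per-million, features are
gated by a Kruskal–Wallis test at $\alpha = 0.05$, and surviving features
are scored by bootstrapped (30 rounds, 2/3 subsampling) two-class linear
discriminant analysis; the reported score is the log10 of the average
effect, and "significant" requires both `log10(LDA) > 2` (strict) and
`p < 0.05`. Two implementation choices matter:

* The discriminant direction is computed directly as the two-class Fisher
  solution $w = (S_W + \lambda I)^{-1}(m_1 - m_2)$ with a small ridge
  ($\lambda = 10^{-6} \times \overline{\mathrm{diag}(S_W)}$), because
  bootstrap resamples routinely contain collinear or constant features
  where an unregularized fit fails.
* The subclass (one-against-all) stage of the original LEfSe is omitted:
  the comparisons here are plain two-class designs without subclasses.

## Co-abundance networks

Per group, nodes are the `top_n = 30` most abundant taxa (30 and 50 are
both common conventions; `top_n` is a plain argument, so either is one
keystroke away) and edges are Spearman correlations
with $|\rho| \ge 0.3$ and BH $q < 0.05$. The correlation and q thresholds
are conventions of the co-occurrence literature, not derived quantities;
both are arguments. Negative correlations stay in the graph with a sign
attribute; community detection (greedy modularity, deterministic) and
centralities (degree; closeness $(n_c-1)/\sum d$ within components;
normalized betweenness; eigenvector centrality as the principal
eigenvector of the absolute-weight adjacency, L2-normalized) use absolute
weights. Topologies are compared across groups by Wilcoxon tests on the
per-node property distributions.

## The synthetic cohort generator

`simulation_spec()` + `simulate_multiproject()` emulate the structure of a
curated multi-project case/control database: a shared taxon namespace, a
lognormal (sdlog 1.2) global rank-abundance curve, project-specific
baselines drawn from a Dirichlet around the global base (concentration
200, mimicking between-study batch effects), planted directional effects
that multiply case compositions by $2^{\pm\mathrm{lfc}}$ before
renormalization, within-group Dirichlet overdispersion (concentration 50),
and negative-binomial sequencing depths (mean 20000, size 10). All
randomness derives from one mandatory seed; per-project streams are
deterministic functions of it, so projects can be regenerated in any
order.

Two properties of real data it deliberately does **not** reproduce:
phylogenetically structured effects (planted taxa are exchangeable) and
technical artifacts such as batch-specific extraction or primer biases
beyond a baseline shift. Passing the planted-recovery suites therefore
demonstrates that the pipeline's statistics behave as designed under a
compositional count model — not that any specific biological claim
replicates.

Because compositions renormalize, planting a large one-sided effect drags
every other taxon's relative abundance in the opposite direction. The
validation suites plant balanced up/down effects on mid-abundance taxa so
that this spillover stays well below the detection limit at the simulated
sample sizes; an unbalanced design would make "null" taxa genuinely
non-null in relative-abundance space, which is a property of
compositional data, not a pipeline artifact.

## Numerical choices

* Tables are validated on construction: non-negative, finite, unique ids;
  relative columns must sum to at most $1 + 10^{-6}$.
* A feature whose range is below $10^{-12}$ of its magnitude is treated
  as constant (H = 0, p = 1, flagged): per-million rescaling of exactly
  constant features leaves floating-point residue that must not be
  mistaken for signal.
* Node selection ties (equal mean abundance) break alphabetically;
  consistency records order by descending $|\mathrm{CS}|$, then
  $|\mathrm{WCS}|$, then name — all exports are deterministic.
* If the greedy modularity cut scores below the trivial single-community
  partition (possible on dense graphs), the single community is returned.
* Rarefaction uses sequential hypergeometric draws — exact
  without-replacement subsampling in O(features) memory.

## Validation problem sizes

The shipped suites size their simulations as follows: statistical
calibration uses 500 null Dirichlet-multinomial cohorts of 10 + 10
samples over 20 taxa (Kruskal–Wallis rejection rate and 999-permutation
ANOSIM rejection rate both required to land in [0.03, 0.07] at
$\alpha = 0.05$); planted-truth recovery uses 20 replicates of 6 projects
with 20 + 20 samples over 60 taxa and $|\log_2\mathrm{FC}| = 1.5$
(selection sensitivity $\ge 0.9$, null pass rate $\le 0.01$); the LDA
gate uses 100 seeded 20 + 20 cohorts with a 16-fold planted shift
(score above 2 in at least 95 of 100). These sizes were chosen as the
smallest at which the binomial noise of the check is comfortably below
the tolerance being checked.

## Limitations

* Consistency scoring is vote counting: it ignores per-study precision
  and cannot detect a replicated but sub-significant effect.
* Raw-p significance mirrors the source conventions but inflates the
  family-wise error of the per-comparison calls; use `use_fdr = TRUE` for
  rigorous single-study claims.
* The LEfSe re-implementation is two-class, single-level; multi-class
  one-against-all designs are not supported.
* Compositional effects are handled by convention (TSS + ratios), not by
  a compositional model (no CLR/ALR, no ANCOM-BC/DESeq2 models).
* F/B ratios match phylum names exactly; taxonomies using "Bacteroidota"
  must pass the name explicitly.
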
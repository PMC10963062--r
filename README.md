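# crossbiome

Cross-study consistency analysis of microbiome differential abundance.

Gut-microbiome biomarkers of obesity-associated metabolic disease
(obesity, type 2 diabetes, NAFLD) rarely survive contact with a second
cohort: single studies are small and confounded. `crossbiome` is an
offline toolkit for researchers who want to validate a candidate taxon,
KO module, or pathway against several independent case-versus-control
comparisons at once. It standardizes the per-study analysis —
compositional preprocessing, nonparametric differential abundance,
alpha/beta diversity with ordination and ANOSIM, LEfSe-style LDA effect
sizes, per-group co-abundance networks — and then scores each feature's
cross-comparison consistency.

## The scores

For a feature tested across independent comparisons, with `n1` significant
increases and `n2` significant decreases in the case groups:

```
CS  = (n1 - n2) / #            # = number of significant comparisons
WCS = Σ log2FC_i / Σ |log2FC_i|   over significant comparisons i
```

Both range over [-1, 1]; ±1 means perfect directional agreement, and WCS
rewards biomarkers whose *larger* fold changes agree. A feature is called
consistent when it is significant in ≥ 3 comparisons with |CS| > 0.6
(both thresholds are arguments). Stratified variants score consistency
separately per phenotype or per intervention strategy to ask whether a
biomarker generalizes. The methods vignette
(`vignettes/crossbiome-methods.Rmd`) documents every modeling choice.

## Worked example

Simulate five independent projects with one genus planted up (log2FC = 2)
and one planted down in every case group, run the standard pipeline per
project, and score consistency:

```r
library(crossbiome)

spec <- simulation_spec(
  n_projects = 5, n_taxa = 40, samples_per_group = 15, depth_mean = 10000,
  effects = list(list(taxon = "Taxon_006", signs = 1,  lfc = 2),
                 list(taxon = "Taxon_009", signs = -1, lfc = 2)),
  seed = 20)
sim <- simulate_multiproject(spec)

results <- lapply(sim$projects, function(p) {
  ft <- preprocess(p$table)   # filter -> impute zeros -> TSS
  design <- enumerate_comparisons(p$meta, "case", "control")[1, ]
  compare_features(ft, p$meta, design, method = "kw")
})

ct <- consistency_table(results)
select_consistent(ct, min_projects = 3, min_abs_cs = 0.6)
#>     feature n_sig CS WCS
#> 1 Taxon_006     5  1   1
#> 2 Taxon_009     4 -1  -1
```

Both planted taxa are recovered with unanimous direction (`CS = ±1`);
`Taxon_009` reached significance in 4 of the 5 projects. Sporadic false
positives appear in the full table with `n_sig = 1` and are exactly what
the `≥ 3 comparisons` gate removes. Diversity analysis on the first
project:

```r
p1 <- sim$projects[[1]]
ft1 <- preprocess(p1$table)
head(alpha_diversity(ft1), 3)
#>     sample_id shannon simpson
#> 1 P01_case_01    2.72   0.917
#> 2 P01_case_02    2.71   0.917
#> 3 P01_case_03    2.81   0.919

anosim_test(beta_distance(ft1, "bray_curtis"), p1$meta$group, seed = 20)
#> ANOSIM R = 0.455, p = 0.001
```

The planted composition shift separates case from control communities
(R well above 0 at the permutation floor p = 1/1000).

Config-driven workflows (`run_analyze`, `run_crossval`, `run_advanced`,
`run_simulate`) orchestrate the same steps over YAML configs and write
TSV/JSON exports plus a run manifest; `inst/cli/crossbiome` is a thin
shell entry point over them.

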
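# Shared fixture builders: everything is generated in code, no files.

make_ft <- function(values, units = "counts", rank = NULL,
                    features = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- features %||% sprintf("f%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  }
  feature_table(values, units = units, rank = rank)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Metadata for one project with two groups of given sizes.
make_meta <- function(case_n, control_n, project = "P01",
                      phenotype = "obesity", intervention = "none") {
  data.frame(
    sample_id = c(sprintf("%s_case_%02d", project, seq_len(case_n)),
                  sprintf("%s_control_%02d", project, seq_len(control_n))),
    group = rep(c("case", "control"), c(case_n, control_n)),
    project = project, phenotype = phenotype, intervention = intervention,
    role = rep(c("case", "control"), c(case_n, control_n)),
    stringsAsFactors = FALSE)
}

# A comparison_result with the given per-feature calls, for feeding the
# consistency module directly.
make_result <- function(comparison_id, features, log2fc, significant,
                        p = NULL) {
  direction <- ifelse(log2fc > 0, "up", "down")
  if (is.null(p)) p <- ifelse(significant, 0.01, 0.5)
  comparison_result(comparison_id, data.frame(
    feature = features, log2FC = log2fc, p = p,
    significant = significant, direction = direction,
    stringsAsFactors = FALSE))
}

# Simulation spec used by the planted-recovery suites: balanced up/down
# effects on mid-abundance taxa so compositional renormalization stays
# close to mass-neutral.
planted_spec <- function(seed, n_projects = 6, samples_per_group = 20,
                         lfc = 1.5) {
  up <- sprintf("Taxon_%03d", c(6, 10, 14, 18))
  down <- sprintf("Taxon_%03d", c(8, 12, 16, 20))
  effects <- c(
    lapply(up, function(t) list(taxon = t, signs = 1, lfc = lfc)),
    lapply(down, function(t) list(taxon = t, signs = -1, lfc = lfc)))
  simulation_spec(n_projects = n_projects, n_taxa = 60,
                  samples_per_group = samples_per_group,
                  depth_mean = 20000, effects = effects, seed = seed)
}

planted_truth_taxa <- function() {
  list(up = sprintf("Taxon_%03d", c(6, 10, 14, 18)),
       down = sprintf("Taxon_%03d", c(8, 12, 16, 20)))
}

# Run the default pipeline + KW differential for every project of a
# simulated multi-project dataset; returns the comparison_result list.
run_planted_pipeline <- function(sim, alpha = 0.05) {
  lapply(sim$projects, function(p) {
    ft <- preprocess(p$table)
    des <- enumerate_comparisons(p$meta, "case", "control")[1, ]
    compare_features(ft, p$meta, des, method = "kw", alpha = alpha)
  })
}
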
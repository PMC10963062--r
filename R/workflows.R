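# Workflow orchestration over YAML configs: single-project analysis,
# cross-project validation, stratified (advanced) validation, and
# simulation. Each workflow writes plain-text exports plus a JSON run
# manifest into an output directory; all randomness flows from the
# config-level seed.

default_thresholds <- function() {
  list(max_missing_fraction = 0.80, alpha = 0.05, use_fdr = FALSE,
       lda_threshold = 2, min_projects = 3, min_abs_cs = 0.6,
       top_n = 30, min_abs_rho = 0.3, permutations = 999,
       cs_denominator = "significant")
}

merge_thresholds <- function(config) {
  th <- default_thresholds()
  for (nm in names(config$thresholds)) th[[nm]] <- config$thresholds[[nm]]
  th
}

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- data.frame(stats::setNames(list(rownames(df)), rownames_as), df,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir, workflow, stages, seed, config) {
  manifest <- list(
    package = "crossbiome",
    version = as.character(utils::packageVersion("crossbiome")),
    workflow = workflow, stages = stages, seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    wcs_note = paste("WCS computed as sum(signed log2FC)/sum(|log2FC|)",
                     "over significant comparisons"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

read_config <- function(config) {
  if (is.character(config)) yaml::read_yaml(config) else config
}

# Load the project list named by a config: either per-project table/
# metadata (+ optional taxonomy) files, or an embedded simulation spec.
load_projects <- function(config) {
  if (!is.null(config$simulate)) {
    s <- config$simulate
    spec <- simulation_spec(
      n_projects = s$n_projects %||% 6, n_taxa = s$n_taxa %||% 60,
      samples_per_group = s$samples_per_group %||% 20,
      depth_mean = s$depth_mean %||% 20000,
      depth_dispersion = s$depth_dispersion %||% 10,
      concentration = s$concentration %||% 50,
      baseline_concentration = s$baseline_concentration %||% 200,
      effects = s$effects %||% list(),
      phenotypes = unlist(s$phenotypes %||% "obesity"),
      interventions = unlist(s$interventions %||% "none"),
      seed = s$seed %||% config$seed %||% 1)
    sim <- simulate_multiproject(spec)
    tax <- synth_taxonomy(spec)
    return(list(projects = lapply(sim$projects, function(p) {
      list(table = p$table, meta = p$meta, taxonomy = tax)
    }), truth = sim$truth, spec = spec))
  }
  if (is.null(config$projects)) {
    stop("config must name `projects` or an embedded `simulate` spec",
         call. = FALSE)
  }
  projects <- lapply(config$projects, function(p) {
    ft <- read_feature_table(p$table, units = p$units %||% "counts")
    tax <- attr(ft, "taxonomy")
    if (!is.null(p$taxonomy)) tax <- read_taxonomy(p$taxonomy)
    meta <- read_sample_metadata(p$metadata)
    list(table = ft, meta = meta, taxonomy = tax)
  })
  list(projects = projects, truth = NULL, spec = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset one comparison's samples, optionally collapse to a rank, and run
# the default preprocessing pipeline (filter -> impute -> TSS).
prepare_comparison <- function(proj, design, rank, th) {
  ids <- proj$meta$sample_id[proj$meta$group %in%
                               c(design$case_group, design$control_group)]
  al <- align_samples(subset_samples(proj$table,
                                     intersect(sample_ids(proj$table), ids)),
                      proj$meta)
  ft <- al$table
  if (!is.null(rank) && !is.null(proj$taxonomy)) {
    ft <- collapse_to_rank(ft, proj$taxonomy, rank)
  }
  ft <- preprocess(ft, max_missing_fraction = th$max_missing_fraction,
                   impute = TRUE, normalize = "tss")
  list(table = ft, meta = al$meta)
}

#' Run the single-project analysis workflow
#'
#' Executes preprocessing, per-feature differential analysis, alpha/beta
#' diversity with ordination and ANOSIM, optional functional (LEfSe)
#' analysis, and optional per-group co-abundance networks, writing all
#' exports and a run manifest to `outdir`.
#'
#' @param config Path to a YAML config, or an equivalent list. Keys:
#'   `projects` (a single entry: `table`, `metadata`, optional `taxonomy`,
#'   `units`) or `simulate`; `case_group`/`control_group`; optional `rank`;
#'   optional `functional_table`; `network: true/false`; `seed`;
#'   `thresholds` overriding the named defaults.
#' @param outdir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_analyze <- function(config, outdir) {
  config <- read_config(config)
  th <- merge_thresholds(config)
  seed <- config$seed %||% 1
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  loaded <- load_projects(config)
  proj <- loaded$projects[[1]]
  case <- config$case_group %||% "case"
  ctrl <- config$control_group %||% "control"
  designs <- enumerate_comparisons(proj$meta, case, ctrl)
  if (!nrow(designs)) stop("no comparison found in metadata", call. = FALSE)
  design <- designs[1, ]
  stages <- character()

  prep <- prepare_comparison(proj, design, config$rank, th)
  write_tsv(data.frame(feature_id = feature_ids(prep$table),
                       prep$table$values, check.names = FALSE),
            file.path(outdir, "composition.tsv"))
  stages <- c(stages, "preprocess")

  res <- compare_features(prep$table, prep$meta, design, method = "kw",
                          alpha = th$alpha, use_fdr = th$use_fdr)
  write_tsv(res$table, file.path(outdir, "differential.tsv"))
  stages <- c(stages, "feature")

  write_tsv(alpha_diversity(prep$table), file.path(outdir, "alpha_diversity.tsv"))
  dm <- beta_distance(prep$table, "bray_curtis")
  write_tsv(as.data.frame(as.matrix(dm)), file.path(outdir, "bray_curtis.tsv"),
            rownames_as = "sample_id")
  ord <- pcoa(dm, k = 2)
  write_tsv(as.data.frame(ord$coordinates), file.path(outdir, "pcoa.tsv"),
            rownames_as = "sample_id")
  an <- anosim_test(dm, prep$meta$group, permutations = th$permutations,
                    seed = seed)
  jsonlite::write_json(an, file.path(outdir, "anosim.json"),
                       auto_unbox = TRUE)
  stages <- c(stages, "diversity")

  if (!is.null(config$functional_table)) {
    fft <- read_feature_table(config$functional_table,
                              units = config$functional_units %||% "counts")
    al <- align_samples(fft, prep$meta)
    fprep <- preprocess(al$table,
                        max_missing_fraction = th$max_missing_fraction)
    fres <- compare_features(fprep, al$meta, design, method = "lefse",
                             alpha = th$alpha,
                             lda_threshold = th$lda_threshold, seed = seed)
    write_tsv(fres$table, file.path(outdir, "functional_differential.tsv"))
    stages <- c(stages, "functional")
  }

  if (isTRUE(config$network %||% TRUE)) {
    for (grp in c(case, ctrl)) {
      ids <- prep$meta$sample_id[prep$meta$group == grp]
      net <- build_coabundance(
        prep$table, ids,
        top_n = min(th$top_n, nrow(prep$table$values)),
        min_abs_rho = th$min_abs_rho, alpha = th$alpha, group = grp)
      comm <- suppressWarnings(detect_communities(net))
      props <- node_properties(net)
      props$community <- comm[props$feature]
      write_tsv(net$edges, file.path(outdir, paste0("network_edges_", grp, ".tsv")))
      write_tsv(props, file.path(outdir, paste0("network_nodes_", grp, ".tsv")))
    }
    stages <- c(stages, "network")
  }
  invisible(write_manifest(outdir, "analyze", stages, seed, config))
}

#' Run the cross-project validation workflow
#'
#' Computes per-comparison differential results across >= 2 projects, the
#' consistency table with the selection rule applied, the cross-project
#' F/B fold-change table, a significance-masked log2FC heatmap matrix, and
#' the cross-comparison network-degree matrix.
#'
#' @param config YAML path or list; as [run_analyze()] but with >= 2
#'   projects (or a multi-project `simulate` spec). `local_project` may
#'   name a project whose comparisons are marked with `#` in exports.
#' @param outdir Output directory.
#' @return The manifest, invisibly (with the consistency table attached as
#'   attribute `"consistency"`).
#' @export
run_crossval <- function(config, outdir) {
  config <- read_config(config)
  th <- merge_thresholds(config)
  seed <- config$seed %||% 1
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  loaded <- load_projects(config)
  case <- config$case_group %||% "case"
  ctrl <- config$control_group %||% "control"

  results <- list(); preps <- list(); design_rows <- list()
  for (proj in loaded$projects) {
    designs <- enumerate_comparisons(proj$meta, case, ctrl)
    for (i in seq_len(nrow(designs))) {
      design <- designs[i, ]
      prep <- prepare_comparison(proj, design, config$rank, th)
      res <- compare_features(prep$table, prep$meta, design, method = "kw",
                              alpha = th$alpha, use_fdr = th$use_fdr)
      results[[design$comparison_id]] <- res
      preps[[design$comparison_id]] <- c(prep, list(project = proj))
      design_rows[[design$comparison_id]] <- design
    }
  }
  if (length(results) < 2) {
    stop("cross-project validation needs >= 2 comparisons", call. = FALSE)
  }
  designs <- do.call(rbind, design_rows)

  label <- function(id, project) {
    if (!is.null(config$local_project) && project == config$local_project) {
      paste0("#", id)
    } else id
  }

  dir.create(file.path(outdir, "comparisons"), showWarnings = FALSE)
  for (id in names(results)) {
    write_tsv(results[[id]]$table,
              file.path(outdir, "comparisons", paste0(id, ".tsv")))
  }

  ct <- consistency_table(results, denominator = th$cs_denominator)
  sel <- select_consistent(ct, min_projects = th$min_projects,
                           min_abs_cs = th$min_abs_cs)
  write_tsv(ct[, setdiff(names(ct), "sig_log2fcs")],
            file.path(outdir, "consistency_table.tsv"))
  write_tsv(sel[, setdiff(names(sel), "sig_log2fcs")],
            file.path(outdir, "selected_features.tsv"))

  # features x comparisons signed-log2FC heatmap, masked by significance
  feats <- ct$feature
  hm <- matrix(NA_real_, length(feats), length(results),
               dimnames = list(feats, vapply(seq_along(results), function(j) {
                 label(names(results)[j], designs$project[j])
               }, character(1))))
  for (j in seq_along(results)) {
    tab <- results[[j]]$table
    ok <- tab$significant & tab$feature %in% feats
    hm[tab$feature[ok], j] <- tab$log2FC[ok]
  }
  write_tsv(as.data.frame(hm), file.path(outdir, "consistency_heatmap.tsv"),
            rownames_as = "feature")

  stages <- c("feature", "consistency")

  tax_ok <- !vapply(loaded$projects, function(p) is.null(p$taxonomy),
                    logical(1))
  if (all(tax_ok)) {
    ptabs <- lapply(names(results), function(id) {
      proj <- preps[[id]]$project
      des <- design_rows[[id]]
      ids <- proj$meta$sample_id[proj$meta$group %in%
                                   c(des$case_group, des$control_group)]
      al <- align_samples(subset_samples(proj$table,
                                         intersect(sample_ids(proj$table), ids)),
                          proj$meta)
      impute_zeros(tss_normalize(collapse_to_rank(al$table, proj$taxonomy,
                                                  "phylum")))
    })
    fb <- fb_ratio_cross_project(ptabs,
                                 lapply(names(results),
                                        function(id) preps[[id]]$meta),
                                 designs)
    write_tsv(fb, file.path(outdir, "fb_cross_project.tsv"))
    stages <- c(stages, "diversity")
  }

  deg <- network_degree_matrix(lapply(preps, function(p) p$table),
                               lapply(preps, function(p) p$meta), designs,
                               top_n = th$top_n,
                               min_abs_rho = th$min_abs_rho,
                               alpha = th$alpha)
  write_tsv(as.data.frame(deg), file.path(outdir, "network_degree.tsv"),
            rownames_as = "feature")
  stages <- c(stages, "network")

  manifest <- write_manifest(outdir, "crossval", stages, seed, config)
  attr(manifest, "consistency") <- ct
  attr(manifest, "selected") <- sel
  invisible(manifest)
}

#' Run the advanced (stratified) validation workflow
#'
#' Groups comparisons into strata by phenotype or intervention and
#' computes per-stratum consistency with cross-stratum concordance.
#'
#' @param config YAML path or list; as [run_crossval()] plus
#'   `stratify_by: phenotype` (or `intervention`).
#' @param outdir Output directory.
#' @return The manifest, invisibly (stratified result attached as
#'   attribute `"stratified"`).
#' @export
run_advanced <- function(config, outdir) {
  config <- read_config(config)
  th <- merge_thresholds(config)
  seed <- config$seed %||% 1
  strat <- config$stratify_by %||% "phenotype"
  if (!strat %in% c("phenotype", "intervention")) {
    stop("stratify_by must be 'phenotype' or 'intervention'", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  loaded <- load_projects(config)
  case <- config$case_group %||% "case"
  ctrl <- config$control_group %||% "control"

  by_stratum <- list()
  for (proj in loaded$projects) {
    lab <- unique(proj$meta[[strat]])
    lab <- lab[!is.na(lab)]
    if (!length(lab)) {
      stop("metadata lacks values in stratification column '", strat, "'",
           call. = FALSE)
    }
    designs <- enumerate_comparisons(proj$meta, case, ctrl)
    for (i in seq_len(nrow(designs))) {
      design <- designs[i, ]
      prep <- prepare_comparison(proj, design, config$rank, th)
      res <- compare_features(prep$table, prep$meta, design, method = "kw",
                              alpha = th$alpha, use_fdr = th$use_fdr)
      by_stratum[[lab[1]]] <- c(by_stratum[[lab[1]]], list(res))
    }
  }
  sc <- stratified_consistency(by_stratum, min_projects = th$min_projects,
                               min_abs_cs = th$min_abs_cs,
                               denominator = th$cs_denominator)
  write_tsv(as.data.frame(sc$cs_matrix),
            file.path(outdir, "stratified_cs.tsv"), rownames_as = "feature")
  write_tsv(data.frame(feature = names(sc$concordant),
                       concordant = sc$concordant, row.names = NULL),
            file.path(outdir, "stratified_concordance.tsv"))
  manifest <- write_manifest(outdir, "advanced", "stratified_consistency",
                             seed, config)
  attr(manifest, "stratified") <- sc
  invisible(manifest)
}

#' Run the simulation workflow
#'
#' Simulates a multi-project dataset from the config's `simulate` spec and
#' writes per-project abundance and metadata TSVs, the taxonomy map, the
#' planted-truth table, and the resolved spec.
#'
#' @param config YAML path or list with a `simulate` key (see
#'   [simulation_spec()] for fields).
#' @param outdir Output directory.
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  config <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  loaded <- load_projects(config)
  if (is.null(loaded$spec)) stop("config has no `simulate` spec", call. = FALSE)
  for (nm in names(loaded$projects)) {
    p <- loaded$projects[[nm]]
    write_feature_table(p$table, file.path(outdir, paste0(nm, "_counts.tsv")))
    write_tsv(p$meta, file.path(outdir, paste0(nm, "_metadata.tsv")))
  }
  tax <- loaded$projects[[1]]$taxonomy
  write_tsv(data.frame(
    feature_id = tax$feature_id,
    lineage = apply(tax[CANONICAL_RANKS], 1, format_lineage),
    stringsAsFactors = FALSE), file.path(outdir, "taxonomy.tsv"))
  write_tsv(loaded$truth, file.path(outdir, "truth.tsv"))
  spec <- loaded$spec
  yaml::write_yaml(spec[setdiff(names(spec), "taxa")],
                   file.path(outdir, "spec_resolved.yaml"))
  invisible(write_manifest(outdir, "simulate", "simulate", spec$seed, config))
}
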
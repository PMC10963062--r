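# Seeded Dirichlet-multinomial simulator of multi-project case/control
# cohorts with planted directional effects, so every pipeline stage can be
# exercised against known ground truth.

#' Define a multi-project simulation
#'
#' The generative model: a global base composition (lognormal rank
#' abundance) is resampled per project from a Dirichlet with concentration
#' `baseline_concentration` (project-to-project "batch" variability);
#' case-group compositions multiply each planted taxon by
#' `2^(sign * lfc)` and renormalize; each sample's composition is drawn
#' from a Dirichlet with concentration `concentration` around its group
#' composition (within-group overdispersion); finally counts are drawn
#' multinomially at a negative-binomial sequencing depth.
#'
#' @param n_projects Number of independent projects (default 6).
#' @param n_taxa Number of taxa shared across projects (default 60).
#' @param samples_per_group Samples in each of case and control
#'   (default 20).
#' @param depth_mean,depth_dispersion Mean and negative-binomial size of
#'   the per-sample sequencing depth (defaults 20000 and 10). Means below
#'   100 are rejected as degenerate.
#' @param concentration Within-group Dirichlet concentration (default 50,
#'   moderate overdispersion).
#' @param baseline_concentration Project-level Dirichlet concentration
#'   around the global base (default 200).
#' @param effects List of planted effects, each a list with `taxon`
#'   (taxon name), `signs` (vector of -1/0/+1 per project, recycled to
#'   `n_projects`), and `lfc` (positive |log2 fold change|).
#' @param phenotypes,interventions Per-project labels (recycled).
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_projects = 6, n_taxa = 60,
                            samples_per_group = 20,
                            depth_mean = 20000, depth_dispersion = 10,
                            concentration = 50,
                            baseline_concentration = 200,
                            effects = list(),
                            phenotypes = "obesity",
                            interventions = "none",
                            seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (depth_mean < 100) {
    stop("depth_mean < 100 would produce degenerate tables", call. = FALSE)
  }
  taxa <- sprintf("Taxon_%03d", seq_len(n_taxa))
  for (e in effects) {
    if (!e$taxon %in% taxa) {
      stop("planted taxon '", e$taxon, "' is not among the ", n_taxa,
           " simulated taxa", call. = FALSE)
    }
    if (e$lfc <= 0) stop("planted |log2FC| must be positive", call. = FALSE)
  }
  structure(list(
    n_projects = n_projects, n_taxa = n_taxa, taxa = taxa,
    samples_per_group = samples_per_group,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    concentration = concentration,
    baseline_concentration = baseline_concentration,
    effects = effects,
    phenotypes = rep_len(phenotypes, n_projects),
    interventions = rep_len(interventions, n_projects),
    seed = as.integer(seed)), class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %d projects x %d taxa, %d+%d samples, %d planted effect(s), seed %d\n",
    x$n_projects, x$n_taxa, x$samples_per_group, x$samples_per_group,
    length(x$effects), x$seed))
  invisible(x)
}

# Dirichlet draw via normalized gamma variates.
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Global base composition shared by all projects: lognormal rank-abundance
# curve, deterministic in the spec seed.
global_base <- function(spec) {
  set.seed(spec$seed)
  ab <- sort(stats::rlnorm(spec$n_taxa, meanlog = 0, sdlog = 1.2),
             decreasing = TRUE)
  # keep rank-abundance shape but assign taxa in fixed order
  stats::setNames(ab / sum(ab), spec$taxa)
}

#' Simulate one project
#'
#' @param spec A `simulation_spec`.
#' @param project_index Project number in `1..n_projects`; the project's
#'   RNG stream is derived deterministically from the spec seed and this
#'   index, so projects can be generated independently or in any order.
#' @return List with `table` (a counts `feature_table`), `meta` (sample
#'   metadata data frame), and `truth` (planted effects active in this
#'   project: taxon, project, sign, lfc).
#' @export
simulate_project <- function(spec, project_index) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (project_index < 1 || project_index > spec$n_projects) {
    stop("project_index out of range", call. = FALSE)
  }
  base <- global_base(spec)
  set.seed(spec$seed + 7919L * project_index)
  proj_base <- drop(rdirichlet(1, spec$baseline_concentration * base))
  names(proj_base) <- spec$taxa

  case_base <- proj_base
  truth <- data.frame(taxon = character(), project = character(),
                      sign = integer(), lfc = numeric(),
                      stringsAsFactors = FALSE)
  proj_id <- sprintf("P%02d", project_index)
  for (e in spec$effects) {
    s <- rep_len(e$signs, spec$n_projects)[project_index]
    if (s == 0) next
    case_base[e$taxon] <- case_base[e$taxon] * 2^(s * e$lfc)
    truth <- rbind(truth, data.frame(taxon = e$taxon, project = proj_id,
                                     sign = s, lfc = e$lfc,
                                     stringsAsFactors = FALSE))
  }
  case_base <- case_base / sum(case_base)

  n <- spec$samples_per_group
  draw_group <- function(group_base, label) {
    comp <- rdirichlet(n, spec$concentration * group_base)
    depth <- pmax(100L, stats::rnbinom(n, mu = spec$depth_mean,
                                       size = spec$depth_dispersion))
    counts <- vapply(seq_len(n), function(j) {
      drop(stats::rmultinom(1, depth[j], comp[j, ]))
    }, numeric(spec$n_taxa))
    colnames(counts) <- sprintf("%s_%s_%02d", proj_id, label, seq_len(n))
    rownames(counts) <- spec$taxa
    counts
  }
  counts <- cbind(draw_group(case_base, "case"),
                  draw_group(proj_base, "control"))
  meta <- data.frame(
    sample_id = colnames(counts),
    group = rep(c("case", "control"), each = n),
    project = proj_id,
    phenotype = spec$phenotypes[project_index],
    intervention = spec$interventions[project_index],
    role = rep(c("case", "control"), each = n),
    stringsAsFactors = FALSE)
  list(table = feature_table(counts, units = "counts"), meta = meta,
       truth = truth)
}

#' Simulate all projects of a spec
#'
#' @param spec A `simulation_spec`.
#' @return List with `projects` (list of `simulate_project()` outputs, one
#'   per project) and `truth` (row-bound truth table across projects).
#' @export
simulate_multiproject <- function(spec) {
  projects <- lapply(seq_len(spec$n_projects), function(i) {
    simulate_project(spec, i)
  })
  names(projects) <- sprintf("P%02d", seq_len(spec$n_projects))
  truth <- do.call(rbind, lapply(projects, function(p) p$truth))
  rownames(truth) <- NULL
  list(projects = projects, truth = truth)
}

#' Taxonomy map for simulated taxa
#'
#' Assigns each simulated taxon a full lineage: genus equal to the taxon
#' name and phyla cycling through Firmicutes, Bacteroidetes,
#' Proteobacteria, and Actinobacteria, so phylum collapsing and the
#' Firmicutes/Bacteroidetes ratio are exercisable on synthetic data.
#'
#' @param spec A `simulation_spec`.
#' @return A `taxonomy_map` data frame.
#' @export
synth_taxonomy <- function(spec) {
  phyla <- rep_len(c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                     "Actinobacteria"), spec$n_taxa)
  strings <- stats::setNames(
    sprintf("k__Bacteria|p__%s|c__|o__|f__|g__%s", phyla, spec$taxa),
    spec$taxa)
  taxonomy_from_strings(strings)
}
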
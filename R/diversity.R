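# Alpha diversity, the Firmicutes/Bacteroidetes ratio, beta diversity with
# ordination (PCoA, NMDS), and ANOSIM group-separation testing.

#' Shannon diversity index
#'
#' Entropy of the relative-abundance vector, H = -sum p_i log p_i over
#' positive entries. Natural log by default (ecology convention); `base = 2`
#' gives bits.
#'
#' @param p Non-negative abundance vector with positive sum (renormalized
#'   internally, so counts are accepted).
#' @param base Logarithm base (default `exp(1)`).
#' @return Non-negative scalar; 0 for a single-taxon community, `log(k)`
#'   for a uniform community of k taxa.
#' @export
shannon_index <- function(p, base = exp(1)) {
  if (any(p < 0)) stop("abundances must be non-negative", call. = FALSE)
  s <- sum(p)
  if (s <= 0) stop("all-zero abundance vector", call. = FALSE)
  p <- p[p > 0] / s
  -sum(p * log(p, base = base))
}

#' Simpson diversity index (Gini-Simpson form)
#'
#' 1 - sum p_i^2: the probability that two randomly drawn reads belong to
#' different taxa. Larger values mean more diversity; 0 for a single taxon.
#' `form` selects the classical D (`"D"`) or inverse Simpson (`"inverse"`).
#'
#' @param p Non-negative abundance vector with positive sum.
#' @param form `"gini"` (1 - D, default), `"D"`, or `"inverse"` (1/D).
#' @return Scalar diversity value.
#' @export
simpson_index <- function(p, form = c("gini", "D", "inverse")) {
  form <- match.arg(form)
  if (any(p < 0)) stop("abundances must be non-negative", call. = FALSE)
  s <- sum(p)
  if (s <= 0) stop("all-zero abundance vector", call. = FALSE)
  p <- p / s
  D <- sum(p^2)
  switch(form, gini = 1 - D, D = D, inverse = 1 / D)
}

#' Per-sample alpha diversity of a feature table
#'
#' @param ft A `feature_table` (relative abundances recommended; counts are
#'   renormalized per sample).
#' @return Data frame with `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(ft) {
  data.frame(
    sample_id = sample_ids(ft),
    shannon = apply(ft$values, 2, shannon_index),
    simpson = apply(ft$values, 2, simpson_index),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Firmicutes/Bacteroidetes ratio per sample
#'
#' Computed on a phylum-rank table as the ratio of the (exactly named)
#' Firmicutes row to the Bacteroidetes row. Synonyms such as "Bacteroidota"
#' are not matched implicitly; pass the names your taxonomy uses.
#'
#' @param ft A phylum-rank `feature_table`.
#' @param firmicutes,bacteroidetes Row names of the two phyla.
#' @return Named numeric vector of per-sample ratios.
#' @export
fb_ratio <- function(ft, firmicutes = "Firmicutes",
                     bacteroidetes = "Bacteroidetes") {
  v <- ft$values
  for (nm in c(firmicutes, bacteroidetes)) {
    if (!nm %in% rownames(v)) {
      stop("phylum row '", nm, "' not found in table (is it collapsed to ",
           "phylum rank?)", call. = FALSE)
    }
  }
  den <- v[bacteroidetes, ]
  if (any(den == 0)) {
    stop("zero Bacteroidetes abundance in sample(s) ",
         paste(colnames(v)[den == 0], collapse = ", "),
         "; run impute_zeros() first", call. = FALSE)
  }
  v[firmicutes, ] / den
}

#' Between-sample distance matrix
#'
#' Bray-Curtis on abundances (1 - 2*sum min(x,y) / (sum x + sum y)) or
#' Jaccard on presence/absence (1 - |intersection|/|union|). Jaccard should
#' be computed on a pre-imputation table, since zero replacement destroys
#' absence information.
#'
#' @param ft A `feature_table` with at least two samples.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return A symmetric `dist`-backed object of class `distance_matrix` with
#'   attributes `metric` and `sample_ids`.
#' @export
beta_distance <- function(ft, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  if (ncol(ft$values) < 2) stop("need at least two samples", call. = FALSE)
  x <- t(ft$values)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(x, method = "bray"),
    jaccard = vegan::vegdist(x > 0, method = "jaccard"))
  structure(d, metric = metric, sample_ids = sample_ids(ft),
            class = c("distance_matrix", class(d)))
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers the squared-distance matrix and eigendecomposes it; axes
#' are ordered by decreasing eigenvalue. Negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are dropped from the
#' coordinates and their total magnitude reported.
#'
#' @param dm A `distance_matrix` (or `dist`).
#' @param k Number of axes requested (default 2). If fewer positive
#'   eigenvalues exist, the returned axes are truncated with a warning.
#' @return List with `coordinates` (samples x axes), `eigenvalues`,
#'   `variance_explained` (shares of the positive eigenvalue total), and
#'   `negative_eigenvalue_magnitude`.
#' @export
pcoa <- function(dm, k = 2) {
  stopifnot(k >= 1)
  n <- attr(dm, "Size")
  fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            length(pos), " axes", call. = FALSE)
    k <- length(pos)
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       eigenvalues = eig,
       variance_explained = eig[pos] / sum(eig[pos]),
       negative_eigenvalue_magnitude = sum(abs(eig[eig < 0])))
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 over `restarts` random starts (plus a metric
#' start) and returns the best configuration. Stress is reported as a
#' fraction in [0, 1].
#'
#' @param dm A `distance_matrix` (or `dist`).
#' @param k Target dimension (default 2).
#' @param restarts Number of random restarts (default 20).
#' @param seed Integer seed; fixed seeds give identical results.
#' @return List with `coordinates`, `stress`, `converged`.
#' @export
nmds <- function(dm, k = 2, restarts = 20, seed = 1) {
  n <- attr(dm, "Size")
  if (n < k + 1) stop("need at least k+1 samples for k-dimensional NMDS", call. = FALSE)
  set.seed(seed)
  fit <- suppressMessages(suppressWarnings(
    vegan::metaMDS(stats::as.dist(dm), k = k, try = restarts,
                   trymax = restarts, trace = 0, autotransform = FALSE,
                   wascores = FALSE)))
  if (!fit$converged) {
    warning("NMDS did not converge in ", restarts,
            " restarts; returning best iterate", call. = FALSE)
  }
  coords <- fit$points
  colnames(coords) <- paste0("NMDS", seq_len(k))
  list(coordinates = coords, stress = fit$stress,
       converged = isTRUE(fit$converged))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. R = (mean between-group rank -
#' mean within-group rank) / (M/2), M = n(n-1)/2; R is in [-1, 1] and the
#' permutation p-value is (1 + #permuted R >= observed) / (permutations+1).
#'
#' @param dm A `distance_matrix` (or `dist`).
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `R`, `p`, `permutations`, `seed`.
#' @export
anosim_test <- function(dm, groups, permutations = 999, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least two samples", call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(dm), grouping = groups,
                       permutations = permutations)
  list(R = unname(fit$statistic), p = unname(fit$signif),
       permutations = permutations, seed = seed)
}
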
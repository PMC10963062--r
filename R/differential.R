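# Per-comparison differential abundance: rank tests, fold changes,
# multiplicity control, and assembly into comparison_result objects that
# feed the consistency module.

#' Kruskal-Wallis scan over features
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k-1 degrees
#' of freedom, computed independently per feature. A feature constant
#' across all samples gets H = 0, p = 1 and is flagged.
#'
#' @param ft A `feature_table`.
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @return Data frame with `feature`, `H`, `p`, `constant`.
#' @export
kruskal_wallis_scan <- function(ft, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples", call. = FALSE)
  if (length(groups) != ncol(ft$values)) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  res <- apply(ft$values, 1, function(x) {
    # features constant up to floating-point residue carry no signal
    if (max(x) - min(x) <= 1e-12 * max(abs(x), 1e-300)) {
      return(c(H = 0, p = 1, constant = 1))
    }
    kw <- stats::kruskal.test(x, groups)
    c(H = unname(kw$statistic), p = kw$p.value, constant = 0)
  })
  data.frame(feature = feature_ids(ft), H = res["H", ], p = res["p", ],
             constant = res["constant", ] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test. The exact null distribution is used when
#' both samples have at most `exact_threshold` observations and there are
#' no ties; otherwise the tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param exact_threshold Maximum per-group size for the exact test
#'   (default 25).
#' @return List with `U` (the Mann-Whitney statistic for `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 25) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_threshold && length(y) <= exact_threshold
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Log2 fold change between group means
#'
#' @param mean_case,mean_control Positive means (run [impute_zeros()] first
#'   if zeros are possible).
#' @return `log2(mean_case / mean_control)`.
#' @export
log2_fold_change <- function(mean_case, mean_control) {
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    stop("means must be positive; replace zeros first (impute_zeros())",
         call. = FALSE)
  }
  log2(mean_case / mean_control)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate q-values via [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Assemble a per-comparison differential-abundance result
#'
#' Runs the chosen test feature-by-feature for one case-vs-control
#' comparison and assembles means, log2 fold changes, raw and BH-adjusted
#' p-values, direction, and the significance call. With `method = "lefse"`
#' the LEfSe-style LDA effect size is added and significance additionally
#' requires `lda_log10 > lda_threshold`.
#'
#' @param ft A preprocessed `feature_table` (zero-imputed relative
#'   abundances for meaningful fold changes).
#' @param meta Metadata aligned with the table (see [align_samples()]).
#' @param design One row of [enumerate_comparisons()] output (or a list
#'   with `comparison_id`, `case_group`, `control_group`).
#' @param method `"kw"` (Kruskal-Wallis, default), `"wilcoxon"`, or
#'   `"lefse"`.
#' @param alpha Significance level on p (or q) (default 0.05).
#' @param use_fdr Call significance on BH q-values instead of raw p
#'   (default `FALSE`, mirroring raw `P < 0.05` reporting).
#' @param lda_threshold Gate on log10 LDA effect size for `"lefse"`
#'   (default 2, strict).
#' @param seed Seed for the LEfSe bootstrap.
#' @return A `comparison_result`: list with `comparison_id`, `design`, and
#'   `table` (feature, mean_case, mean_control, log2FC, p, q, lda_log10,
#'   significant, direction).
#' @export
compare_features <- function(ft, meta, design,
                             method = c("kw", "wilcoxon", "lefse"),
                             alpha = 0.05, use_fdr = FALSE,
                             lda_threshold = 2, seed = 1) {
  method <- match.arg(method)
  case_ids <- meta$sample_id[meta$group == design$case_group]
  ctrl_ids <- meta$sample_id[meta$group == design$control_group]
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    stop("comparison '", design$comparison_id,
         "': both groups need >= 2 samples", call. = FALSE)
  }
  vc <- ft$values[, case_ids, drop = FALSE]
  vk <- ft$values[, ctrl_ids, drop = FALSE]
  mean_case <- rowMeans(vc)
  mean_control <- rowMeans(vk)
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    stop("zero group means; run impute_zeros() before compare_features()",
         call. = FALSE)
  }
  lfc <- log2_fold_change(mean_case, mean_control)

  p <- switch(method,
    kw = {
      sub <- feature_table(cbind(vc, vk), units = ft$units, rank = ft$rank)
      kruskal_wallis_scan(sub, c(rep("case", ncol(vc)),
                                 rep("control", ncol(vk))))$p
    },
    wilcoxon = vapply(seq_len(nrow(vc)), function(i) {
      wilcoxon_rank_sum(vc[i, ], vk[i, ])$p
    }, numeric(1)),
    lefse = {
      sub <- feature_table(cbind(vc, vk), units = ft$units, rank = ft$rank)
      kruskal_wallis_scan(sub, c(rep("case", ncol(vc)),
                                 rep("control", ncol(vk))))$p
    })
  q <- bh_adjust(p)

  lda <- rep(NA_real_, length(p))
  if (method == "lefse") {
    sub <- feature_table(cbind(vc, vk), units = ft$units, rank = ft$rank)
    lda <- lda_effect_size(sub,
                           groups = c(rep("case", ncol(vc)),
                                      rep("control", ncol(vk))),
                           case_label = "case", alpha = alpha,
                           seed = seed)$lda_log10
  }

  crit <- if (use_fdr) q else p
  significant <- crit < alpha
  if (method == "lefse") {
    significant <- significant & !is.na(lda) & lda > lda_threshold
  }
  tab <- data.frame(
    feature = feature_ids(ft),
    mean_case = mean_case, mean_control = mean_control,
    log2FC = lfc, p = p, q = q, lda_log10 = lda,
    significant = significant,
    direction = ifelse(lfc > 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
  comparison_result(design$comparison_id, tab, design = design)
}

#' Construct a comparison_result
#'
#' Container for the per-feature statistics of one two-group comparison.
#' Normally produced by [compare_features()]; the constructor is exported
#' so results can also be assembled from externally computed statistics.
#'
#' @param comparison_id Identifier of the comparison.
#' @param table Data frame with at least `feature`, `log2FC`, `p`,
#'   `significant`, `direction` columns (`direction` in `up`/`down`, `up`
#'   meaning higher in the case group).
#' @param design Optional design row the comparison came from.
#' @return An object of class `comparison_result`.
#' @export
comparison_result <- function(comparison_id, table, design = NULL) {
  needed <- c("feature", "log2FC", "p", "significant", "direction")
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    stop("comparison_result table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(table$direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'", call. = FALSE)
  }
  bad <- table$direction == "up" & table$log2FC < 0 |
    table$direction == "down" & table$log2FC > 0
  if (any(bad)) {
    stop("direction must match the sign of log2FC", call. = FALSE)
  }
  structure(list(comparison_id = comparison_id, table = table,
                 design = design),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %d features, %d significant\n",
              x$comparison_id, nrow(x$table), sum(x$table$significant)))
  invisible(x)
}
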
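# Cross-comparison consistency scoring: the consistency score (CS) and
# weighted consistency score (WCS), selection of consistent features,
# cross-project F/B and pathway summaries, and stratified validation.

#' Consistency score (CS)
#'
#' For one feature evaluated across several independent case-vs-control
#' comparisons, `CS = (n1 - n2) / denominator`, where `n1` counts the
#' comparisons with a statistically significant increase in the case group
#' and `n2` those with a significant decrease. The default denominator is
#' the number of significant comparisons (`n1 + n2`), so CS reaches +1/-1
#' exactly at unanimity; `denominator` may instead be supplied as the total
#' number of comparisons evaluated.
#'
#' @param n1 Number of significant increases.
#' @param n2 Number of significant decreases.
#' @param denominator Divisor; defaults to `n1 + n2`. Must be
#'   `>= n1 + n2 >= 1`.
#' @return CS in `[-1, 1]`.
#' @export
consistency_score <- function(n1, n2, denominator = n1 + n2) {
  if (n1 < 0 || n2 < 0) stop("n1 and n2 must be non-negative counts", call. = FALSE)
  if (n1 + n2 < 1) stop("CS is undefined without a significant comparison", call. = FALSE)
  if (denominator < n1 + n2) {
    stop("denominator must be at least n1 + n2", call. = FALSE)
  }
  (n1 - n2) / denominator
}

#' Weighted consistency score (WCS)
#'
#' Fold-change-weighted analogue of CS: the sum of the signed log2 fold
#' changes of the significant comparisons divided by the sum of their
#' absolute values, so a biomarker with larger fold changes in the
#' dominant direction scores closer to +1/-1.
#'
#' @param sig_log2fcs Signed log2 fold changes of the significant
#'   comparisons (nonempty, nonzero).
#' @return WCS in `[-1, 1]`.
#' @export
weighted_consistency_score <- function(sig_log2fcs) {
  if (!length(sig_log2fcs)) {
    stop("WCS is undefined without a significant comparison", call. = FALSE)
  }
  if (any(sig_log2fcs == 0)) {
    stop("significant log2 fold changes must be nonzero", call. = FALSE)
  }
  sum(sig_log2fcs) / sum(abs(sig_log2fcs))
}

#' Cross-comparison consistency table
#'
#' Aggregates a list of per-comparison results into one record per feature
#' that is significant in at least one comparison: counts of significant
#' increases (`n1`) and decreases (`n2`), the number of comparisons in
#' which the feature was evaluated (`n_total`; features absent from a
#' comparison's table are simply not counted for it), and the CS and WCS
#' scores. Records are ordered by descending `|CS|`, then descending
#' `|WCS|`, then feature name.
#'
#' @param results List of `comparison_result` objects (>= 1).
#' @param denominator `"significant"` (default; CS divides by `n1 + n2`) or
#'   `"total"` (divides by `n_total`).
#' @return Data frame of consistency records: `feature`, `n1`, `n2`,
#'   `n_sig`, `n_total`, `CS`, `WCS`, plus the per-comparison signed
#'   log2FCs as a list column `sig_log2fcs`.
#' @export
consistency_table <- function(results, denominator = c("significant", "total")) {
  denominator <- match.arg(denominator)
  if (!length(results)) stop("need at least one comparison result", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "comparison_result")))

  feats <- sort(unique(unlist(lapply(results, function(r) r$table$feature))))
  n1 <- n2 <- n_total <- stats::setNames(integer(length(feats)), feats)
  fcs <- stats::setNames(vector("list", length(feats)), feats)
  for (r in results) {
    tab <- r$table
    idx <- match(tab$feature, feats)
    n_total[idx] <- n_total[idx] + 1L
    sig <- which(tab$significant)
    for (i in sig) {
      f <- tab$feature[i]
      if (tab$direction[i] == "up") n1[f] <- n1[f] + 1L else n2[f] <- n2[f] + 1L
      fcs[[f]] <- c(fcs[[f]], tab$log2FC[i])
    }
  }
  keep <- n1 + n2 >= 1L
  feats <- feats[keep]
  if (!length(feats)) {
    out <- data.frame(feature = character(), n1 = integer(), n2 = integer(),
                      n_sig = integer(), n_total = integer(),
                      CS = numeric(), WCS = numeric(),
                      stringsAsFactors = FALSE)
    out$sig_log2fcs <- list()
    return(out)
  }
  n1 <- n1[feats]; n2 <- n2[feats]; n_total <- n_total[feats]
  denom <- if (denominator == "significant") n1 + n2 else n_total
  cs <- mapply(consistency_score, n1, n2, denom)
  wcs <- vapply(fcs[feats], weighted_consistency_score, numeric(1))
  out <- data.frame(feature = feats, n1 = unname(n1), n2 = unname(n2),
                    n_sig = unname(n1 + n2), n_total = unname(n_total),
                    CS = unname(cs), WCS = unname(wcs),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$sig_log2fcs <- unname(fcs[feats])
  ord <- order(-abs(out$CS), -abs(out$WCS), out$feature)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "denominator") <- denominator
  out
}

#' Select consistently varied features
#'
#' Keeps features significant in at least `min_projects` comparisons whose
#' consistency score exceeds `min_abs_cs` in absolute value (strictly, per
#' the "more than 0.6" convention).
#'
#' @param records Output of [consistency_table()].
#' @param min_projects Minimum number of significant comparisons
#'   (default 3).
#' @param min_abs_cs Strict lower bound on `|CS|` (default 0.6).
#' @return The filtered records.
#' @export
select_consistent <- function(records, min_projects = 3, min_abs_cs = 0.6) {
  if (min_projects < 1) stop("`min_projects` must be >= 1", call. = FALSE)
  if (min_abs_cs < 0 || min_abs_cs > 1) {
    stop("`min_abs_cs` must lie in [0, 1]", call. = FALSE)
  }
  keep <- records$n_sig >= min_projects & abs(records$CS) > min_abs_cs
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-project Firmicutes/Bacteroidetes fold changes
#'
#' For each comparison, computes the per-sample F/B ratio on the supplied
#' phylum-rank table, the fold change of the case median over the control
#' median, a Wilcoxon rank-sum p-value, and `log2(p)` for display export.
#' Comparisons whose table lacks either phylum are skipped with a warning.
#'
#' @param tables List of phylum-rank `feature_table`s, one per comparison
#'   (zero-imputed so the ratio is defined).
#' @param metas List of aligned metadata data frames, one per comparison.
#' @param designs Data frame of comparison designs
#'   ([enumerate_comparisons()]).
#' @param firmicutes,bacteroidetes Phylum row names.
#' @return Data frame with `comparison_id`, `fold_change`, `p`, `log2_p`.
#' @export
fb_ratio_cross_project <- function(tables, metas, designs,
                                   firmicutes = "Firmicutes",
                                   bacteroidetes = "Bacteroidetes") {
  out <- data.frame(comparison_id = character(), fold_change = numeric(),
                    p = numeric(), log2_p = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(designs))) {
    des <- designs[i, ]
    ft <- tables[[i]]
    meta <- metas[[i]]
    ratios <- tryCatch(
      fb_ratio(ft, firmicutes = firmicutes, bacteroidetes = bacteroidetes),
      error = function(e) NULL)
    if (is.null(ratios)) {
      warning("comparison '", des$comparison_id,
              "' skipped: F/B ratio unavailable", call. = FALSE)
      next
    }
    rc <- ratios[meta$sample_id[meta$group == des$case_group]]
    rk <- ratios[meta$sample_id[meta$group == des$control_group]]
    p <- wilcoxon_rank_sum(rc, rk)$p
    out <- rbind(out, data.frame(
      comparison_id = des$comparison_id,
      fold_change = stats::median(rc) / stats::median(rk),
      p = p, log2_p = log2(p), stringsAsFactors = FALSE))
  }
  out
}

#' Cross-comparison pathway LDA matrix
#'
#' Builds a pathways x comparisons matrix of signed log10 LDA effect
#' sizes from functional-table comparison results, masked (set to NA) where
#' the entry does not meet both significance gates: `lda_log10` strictly
#' above `lda_threshold` and `p < alpha`. Rows are ordered by descending
#' count of significant comparisons.
#'
#' @param results List of `comparison_result`s carrying `lda_log10`.
#' @param lda_threshold Strict gate on log10 LDA (default 2).
#' @param alpha Gate on raw p (default 0.05).
#' @return Numeric matrix (possibly 0-row) with comparisons as columns;
#'   entries are `lda_log10` signed by direction (+ = up in case).
#' @export
pathway_consistency <- function(results, lda_threshold = 2, alpha = 0.05) {
  stopifnot(all(vapply(results, inherits, logical(1), "comparison_result")))
  ids <- vapply(results, function(r) r$comparison_id, character(1))
  feats <- sort(unique(unlist(lapply(results, function(r) r$table$feature))))
  mat <- matrix(NA_real_, nrow = length(feats), ncol = length(results),
                dimnames = list(feats, ids))
  for (j in seq_along(results)) {
    tab <- results[[j]]$table
    if (!"lda_log10" %in% names(tab)) next
    ok <- !is.na(tab$lda_log10) & tab$lda_log10 > lda_threshold &
      tab$p < alpha
    if (!any(ok)) next
    signed <- ifelse(tab$direction[ok] == "up", 1, -1) * tab$lda_log10[ok]
    mat[tab$feature[ok], j] <- signed
  }
  n_sig <- rowSums(!is.na(mat))
  mat <- mat[n_sig > 0, , drop = FALSE]
  if (nrow(mat)) {
    mat <- mat[order(-rowSums(!is.na(mat)), rownames(mat)), , drop = FALSE]
  }
  mat
}

#' Stratified (cross-phenotype / cross-intervention) consistency
#'
#' Computes consistency tables independently within each stratum (e.g. one
#' per phenotype, or one per intervention strategy), keeps features passing
#' [select_consistent()] in at least one stratum, and flags cross-stratum
#' concordance (same CS sign in every stratum where the feature was
#' selected).
#'
#' @param results_by_stratum Named list (>= 2 strata) mapping stratum label
#'   to a list of `comparison_result`s; strata with zero comparisons are
#'   dropped with a warning.
#' @param min_projects,min_abs_cs Selection thresholds per stratum
#'   (defaults 3 and 0.6).
#' @param denominator Passed to [consistency_table()].
#' @return List with `cs_matrix` (features x strata CS values, NA where a
#'   feature has no significant comparison in the stratum), `selected`
#'   (logical matrix of the per-stratum selection), and `concordant`
#'   (logical vector).
#' @export
stratified_consistency <- function(results_by_stratum, min_projects = 3,
                                   min_abs_cs = 0.6,
                                   denominator = "significant") {
  empty <- vapply(results_by_stratum, function(x) length(x) == 0, logical(1))
  if (any(empty)) {
    warning("dropping stratum(s) with no comparisons: ",
            paste(names(results_by_stratum)[empty], collapse = ", "),
            call. = FALSE)
    results_by_stratum <- results_by_stratum[!empty]
  }
  if (length(results_by_stratum) < 2) {
    stop("stratified validation needs at least two strata", call. = FALSE)
  }
  tabs <- lapply(results_by_stratum, consistency_table,
                 denominator = denominator)
  sels <- lapply(tabs, select_consistent, min_projects = min_projects,
                 min_abs_cs = min_abs_cs)
  feats <- sort(unique(unlist(lapply(sels, function(s) s$feature))))
  strata <- names(results_by_stratum)
  cs <- matrix(NA_real_, length(feats), length(strata),
               dimnames = list(feats, strata))
  sel <- matrix(FALSE, length(feats), length(strata),
                dimnames = list(feats, strata))
  for (s in strata) {
    tab <- tabs[[s]]
    hit <- tab$feature %in% feats
    cs[tab$feature[hit], s] <- tab$CS[hit]
    sel[sels[[s]]$feature, s] <- TRUE
  }
  concordant <- vapply(seq_along(feats), function(i) {
    signs <- sign(cs[i, sel[i, ]])
    length(unique(signs)) == 1
  }, logical(1))
  names(concordant) <- feats
  list(cs_matrix = cs, selected = sel, concordant = concordant)
}
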
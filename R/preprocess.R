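# Predefined preprocessing: prevalence filter, zero replacement, and the
# three user-selectable normalizations (TSS, rarefaction, median-of-ratios).
# The default pipeline order is filter -> impute -> TSS.

#' Remove features that are missing in too many samples
#'
#' A feature's "missing" samples are those where its abundance is zero.
#' Features whose missing fraction is strictly greater than
#' `max_missing_fraction` are removed; a feature zero in exactly that
#' fraction of samples is retained. Samples are never removed.
#'
#' @param ft A `feature_table`.
#' @param max_missing_fraction Maximum tolerated zero fraction, in `[0, 1]`
#'   (default 0.80).
#' @return The filtered `feature_table`.
#' @export
filter_low_prevalence <- function(ft, max_missing_fraction = 0.80) {
  if (!is.numeric(max_missing_fraction) || max_missing_fraction < 0 ||
      max_missing_fraction > 1) {
    stop("`max_missing_fraction` must lie in [0, 1]", call. = FALSE)
  }
  zero_frac <- rowMeans(ft$values == 0)
  keep <- zero_frac <= max_missing_fraction
  feature_table(ft$values[keep, , drop = FALSE], units = ft$units,
                rank = ft$rank)
}

#' Replace zeros with a pseudo-abundance
#'
#' Every zero entry is replaced by one tenth of the smallest positive value
#' in the whole table; positive entries are untouched. This makes
#' log-fold-changes and ratios well defined downstream.
#'
#' @param ft A `feature_table` with at least one positive entry.
#' @return The imputed `feature_table`.
#' @export
impute_zeros <- function(ft) {
  v <- ft$values
  pos <- v[v > 0]
  if (!length(pos)) stop("cannot impute an all-zero table", call. = FALSE)
  v[v == 0] <- min(pos) / 10
  feature_table(v, units = ft$units, rank = ft$rank)
}

#' Total-sum scaling (TSS) normalization
#'
#' Divides each sample column by its total so columns sum to 1; the result
#' is a relative-abundance table. Within-column rank order is preserved.
#'
#' @param ft A `feature_table` whose columns all have positive sums.
#' @return A `feature_table` with `units = "relative"`.
#' @export
tss_normalize <- function(ft) {
  cs <- colSums(ft$values)
  if (any(cs <= 0)) {
    stop("zero-sum sample column(s): ",
         paste(colnames(ft$values)[cs <= 0], collapse = ", "), call. = FALSE)
  }
  feature_table(sweep(ft$values, 2, cs, "/"), units = "relative",
                rank = ft$rank)
}

#' Rarefy a count table to even depth
#'
#' Each sample is subsampled without replacement (multivariate
#' hypergeometric) to `depth` reads, so all retained columns sum to exactly
#' `depth`. Samples shallower than `depth` are dropped with a warning.
#'
#' @param ft A `feature_table` with `units = "counts"` and integer-valued
#'   entries.
#' @param depth Target depth, or `"min"` for the minimum column sum.
#' @param seed Integer seed; rarefaction is random and the seed is recorded
#'   as attribute `"rarefaction_seed"` on the result.
#' @return The rarefied `feature_table`.
#' @export
rarefy <- function(ft, depth = "min", seed) {
  if (ft$units != "counts") {
    stop("rarefaction requires a count table (units = 'counts')", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required for rarefaction", call. = FALSE)
  v <- round(ft$values)
  totals <- colSums(v)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  shallow <- totals < depth
  if (any(shallow)) {
    warning("dropping ", sum(shallow), " sample(s) below depth ", depth, ": ",
            paste(colnames(v)[shallow], collapse = ", "), call. = FALSE)
    v <- v[, !shallow, drop = FALSE]
  }
  set.seed(seed)
  out <- apply(v, 2, rarefy_column, depth = depth)
  dimnames(out) <- list(rownames(v), colnames(v))
  res <- feature_table(out, units = "counts", rank = ft$rank)
  attr(res, "rarefaction_seed") <- seed
  res
}

# Draw a without-replacement subsample of size `depth` from one sample's
# counts via sequential hypergeometric draws (exact, O(#features)).
rarefy_column <- function(counts, depth) {
  remaining_total <- sum(counts)
  remaining_draw <- depth
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (remaining_draw == 0L) break
    ci <- counts[i]
    other <- remaining_total - ci
    x <- stats::rhyper(1, m = ci, n = other, k = remaining_draw)
    out[i] <- x
    remaining_draw <- remaining_draw - x
    remaining_total <- other
  }
  out
}

#' Median-of-ratios normalization
#'
#' Per-sample size factors are the medians, over features positive in every
#' sample, of the ratio between the sample's count and the feature's
#' geometric mean across samples; columns are divided by their size factor.
#' This is the standard size-factor estimator used for sequencing count
#' data.
#'
#' @param ft A `feature_table` with `units = "counts"`.
#' @return A `feature_table` of normalized counts, with the per-sample size
#'   factors attached as attribute `"size_factors"`.
#' @export
median_of_ratios_normalize <- function(ft) {
  if (ft$units != "counts") {
    stop("median-of-ratios normalization expects a count table", call. = FALSE)
  }
  v <- ft$values
  all_pos <- rowSums(v > 0) == ncol(v)
  if (!any(all_pos)) {
    stop("no feature is positive in all samples; impute zeros first ",
         "(impute_zeros())", call. = FALSE)
  }
  ref <- v[all_pos, , drop = FALSE]
  log_gm <- rowMeans(log(ref))
  sf <- apply(ref, 2, function(col) exp(stats::median(log(col) - log_gm)))
  out <- sweep(v, 2, sf, "/")
  res <- feature_table(out, units = "counts", rank = ft$rank)
  attr(res, "size_factors") <- sf
  res
}

#' Default preprocessing pipeline
#'
#' Applies, in order: the strict >`max_missing_fraction` prevalence filter,
#' zero replacement by min-positive/10, and the selected normalization
#' (TSS by default).
#'
#' @param ft A `feature_table`.
#' @param max_missing_fraction Prevalence-filter threshold (default 0.80).
#' @param impute Replace zeros before normalization (default `TRUE`).
#' @param normalize `"tss"`, `"mor"` (median-of-ratios), `"rarefy"`, or
#'   `"none"`.
#' @param depth,seed Passed to [rarefy()] when `normalize = "rarefy"`.
#' @return The preprocessed `feature_table`.
#' @export
preprocess <- function(ft, max_missing_fraction = 0.80, impute = TRUE,
                       normalize = c("tss", "mor", "rarefy", "none"),
                       depth = "min", seed = NULL) {
  normalize <- match.arg(normalize)
  out <- filter_low_prevalence(ft, max_missing_fraction)
  if (normalize == "rarefy") {
    # rarefaction needs raw counts; impute afterwards if requested
    out <- rarefy(out, depth = depth, seed = seed)
    if (impute) out <- impute_zeros(out)
    return(out)
  }
  if (impute) out <- impute_zeros(out)
  switch(normalize,
         tss = tss_normalize(out),
         mor = median_of_ratios_normalize(out),
         none = out)
}
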
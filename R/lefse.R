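# LEfSe-style linear discriminant effect size: a Kruskal-Wallis gate
# followed by bootstrapped two-class LDA on per-million-scaled abundances,
# reporting log10 effect sizes. Single-level (no subclass stage).

#' LEfSe-style LDA effect size
#'
#' Features are first gated by a per-feature Kruskal-Wallis test at
#' `alpha`; only passing features receive a score. Passing features enter
#' `n_boot` bootstrap rounds: in each round a fraction `boot_fraction` of
#' every class is subsampled, the two-class Fisher discriminant direction
#' is fit on the gated features jointly (ridge-regularized pooled
#' within-class covariance, so collinear or constant bootstrap draws are
#' handled), and each feature's effect is the average of its class-mean
#' difference and its contribution to the class separation along the
#' discriminant axis. The reported score is
#' `log10(1 + mean absolute effect over bootstraps)` on the per-million
#' abundance scale, so the conventional `log10(LDA) > 2` gate corresponds
#' to an effect of roughly 100 parts per million.
#'
#' @param ft A `feature_table`; counts are TSS-normalized internally, then
#'   abundances are scaled to sum to 1e6 per sample (LEfSe convention).
#' @param groups Class label per sample; exactly two classes, each with at
#'   least 3 samples.
#' @param case_label Label treated as the case class (direction `up` means
#'   higher in this class). Defaults to the first level.
#' @param alpha Kruskal-Wallis gate level (default 0.05).
#' @param n_boot Bootstrap rounds (default 30, the LEfSe default).
#' @param boot_fraction Per-class subsample fraction (default 2/3).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Data frame with `feature`, `kw_p`, `lda_log10` (NA for features
#'   failing the gate), `direction`.
#' @export
lda_effect_size <- function(ft, groups, case_label = NULL, alpha = 0.05,
                            n_boot = 30, boot_fraction = 2 / 3, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("LEfSe scoring needs exactly two classes", call. = FALSE)
  if (any(table(groups) < 3)) {
    stop("every class needs >= 3 samples to bootstrap", call. = FALSE)
  }
  if (is.null(case_label)) case_label <- levels(groups)[1]
  if (!case_label %in% levels(groups)) stop("unknown case label", call. = FALSE)

  rel <- if (ft$units == "counts") tss_normalize(ft) else ft
  v <- sweep(rel$values, 2, colSums(rel$values), "/") * 1e6  # per-million

  kw <- kruskal_wallis_scan(feature_table(v, units = "counts"), groups)
  gate <- kw$p < alpha & !kw$constant
  lda_log10 <- rep(NA_real_, nrow(v))

  case <- groups == case_label
  mean_diff_all <- rowMeans(v[, case, drop = FALSE]) -
    rowMeans(v[, !case, drop = FALSE])

  if (any(gate)) {
    sel <- which(gate)
    x <- t(v[sel, , drop = FALSE])   # samples x gated features
    idx_case <- which(case)
    idx_ctrl <- which(!case)
    n_case <- max(2L, ceiling(boot_fraction * length(idx_case)))
    n_ctrl <- max(2L, ceiling(boot_fraction * length(idx_ctrl)))
    set.seed(seed)
    scores <- matrix(0, nrow = n_boot, ncol = length(sel))
    for (b in seq_len(n_boot)) {
      ic <- sample(idx_case, n_case)
      ik <- sample(idx_ctrl, n_ctrl)
      scores[b, ] <- fisher_lda_effects(x[ic, , drop = FALSE],
                                        x[ik, , drop = FALSE])
    }
    lda_log10[sel] <- log10(1 + colMeans(scores))
  }

  data.frame(feature = feature_ids(ft), kw_p = kw$p,
             lda_log10 = lda_log10,
             direction = ifelse(mean_diff_all > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Per-feature absolute LDA effects for one bootstrap draw.
# xc, xk: samples x features matrices for the two classes.
# Returns |(class-mean difference + feature's share of the LD-axis
# separation) / 2| per feature.
fisher_lda_effects <- function(xc, xk) {
  m1 <- colMeans(xc)
  m2 <- colMeans(xk)
  d <- m1 - m2
  p <- length(d)
  sw <- (crossprod(sweep(xc, 2, m1)) + crossprod(sweep(xk, 2, m2))) /
    (nrow(xc) + nrow(xk) - 2)
  ridge <- max(mean(diag(sw)), 1e-8) * 1e-6
  w <- solve(sw + diag(ridge, p), d)
  w_unit <- w / sqrt(sum(w^2))
  # class separation along the discriminant axis
  sep <- abs(sum(w_unit * d))
  abs((d + w_unit * sep) / 2)
}
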
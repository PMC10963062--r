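# CS/WCS scoring, record aggregation, selection, and the cross-project
# summary exports.

test_that("consistency_score follows (n1 - n2)/denominator with its bounds", {
  expect_equal(consistency_score(3, 0, 3), 1)
  expect_equal(consistency_score(0, 2, 2), -1)
  expect_equal(consistency_score(4, 1, 5), 0.6)
  expect_equal(consistency_score(2, 1), 1 / 3)      # default denominator n1+n2
  expect_equal(consistency_score(2, 1, denominator = 6), 1 / 6)  # total
  expect_error(consistency_score(0, 0), "undefined")
  expect_error(consistency_score(2, 1, denominator = 2), "at least")
  expect_error(consistency_score(-1, 0), "non-negative")
})

test_that("weighted_consistency_score weights by fold-change magnitude", {
  expect_equal(weighted_consistency_score(c(2, 1, -1)), 0.5)
  expect_equal(weighted_consistency_score(c(0.4, 2.2, 1)), 1)
  expect_equal(weighted_consistency_score(c(-0.4, -3)), -1)
  expect_equal(weighted_consistency_score(c(1.7, -1.7)), 0)
  expect_error(weighted_consistency_score(numeric(0)), "undefined")
  expect_error(weighted_consistency_score(c(1, 0)), "nonzero")
})

test_that("consistency_table aggregates mixed calls with the right counts and order", {
  feats <- c("gA", "gB", "gC", "gD")
  results <- list(
    make_result("c1", feats, c(2, -1, 0.5, 1), c(TRUE, TRUE, TRUE, FALSE)),
    make_result("c2", feats, c(1.5, -2, -0.7, 1), c(TRUE, TRUE, TRUE, FALSE)),
    make_result("c3", feats, c(1, -0.5, 0.9, 1), c(TRUE, TRUE, TRUE, FALSE)),
    # gA absent from the fourth comparison: n_total drops to 3 for it
    make_result("c4", feats[-1], c(-1, 0.8, 1), c(TRUE, FALSE, FALSE)))
  ct <- consistency_table(results)
  expect_equal(ct$feature[1:2], c("gA", "gB"))   # |CS| = 1 first
  gA <- ct[ct$feature == "gA", ]
  expect_equal(gA$n1, 3); expect_equal(gA$n2, 0)
  expect_equal(gA$n_total, 3)
  expect_equal(gA$CS, 1); expect_equal(gA$WCS, 1)
  gB <- ct[ct$feature == "gB", ]
  expect_equal(gB[, c("n1", "n2", "n_total")],
               data.frame(n1 = 0, n2 = 4, n_total = 4), ignore_attr = TRUE)
  expect_equal(gB$CS, -1)
  gC <- ct[ct$feature == "gC", ]
  expect_equal(gC$CS, (2 - 1) / 3)
  expect_equal(gC$WCS, (0.5 - 0.7 + 0.9) / (0.5 + 0.7 + 0.9))
  # never-significant features are not reported
  expect_false("gD" %in% ct$feature)
  # alternative denominator: divide by all evaluated comparisons
  ct_tot <- consistency_table(results, denominator = "total")
  expect_equal(ct_tot$CS[ct_tot$feature == "gC"], (2 - 1) / 4)
  expect_error(consistency_table(list()), "at least one")
})

test_that("CS and WCS stay in [-1, 1] and agree in sign with n1 - n2", {
  set.seed(20)
  for (rep in 1:50) {
    k <- sample(1:6, 1)
    lfc <- runif(k, 0.1, 4) * sample(c(-1, 1), k, replace = TRUE)
    n1 <- sum(lfc > 0); n2 <- sum(lfc < 0)
    cs <- consistency_score(n1, n2)
    wcs <- weighted_consistency_score(lfc)
    expect_gte(cs, -1); expect_lte(cs, 1)
    expect_gte(wcs, -1); expect_lte(wcs, 1)
    expect_equal(sign(cs), sign(n1 - n2))
    if (n1 == 0 || n2 == 0) expect_equal(abs(cs), 1)
    if (n1 == 0 || n2 == 0) expect_equal(abs(wcs), 1)
  }
})

test_that("select_consistent applies the >=3 projects and strict |CS| > 0.6 rule", {
  rec <- data.frame(
    feature = c("kept", "few", "boundary", "strong_neg"),
    n1 = c(3, 2, 5, 0), n2 = c(0, 0, 1, 4),
    n_sig = c(3, 2, 6, 4), n_total = c(4, 2, 6, 4),
    CS = c(0.61, 1.0, 0.6, -1), WCS = c(0.7, 1, 0.65, -1),
    stringsAsFactors = FALSE)
  # CS = 0.6 wouldn't arise from n1=5,n2=1 but the rule is tested as stated
  sel <- select_consistent(rec)
  expect_setequal(sel$feature, c("kept", "strong_neg"))
  expect_error(select_consistent(rec, min_abs_cs = 2), "\\[0, 1\\]")
})

test_that("cross-project F/B summary reports fold change, p, and log2 p", {
  set.seed(6)
  n <- 12
  make_phylum_table <- function(fb_shift) {
    f <- c(rexp(n, 1) + 1, (rexp(n, 1) + 1) * fb_shift)
    b <- rep(1, 2 * n)
    v <- rbind(Firmicutes = f, Bacteroidetes = b,
               Proteobacteria = rexp(2 * n, 1) + 0.2)
    colnames(v) <- c(sprintf("P01_case_%02d", 1:n),
                     sprintf("P01_control_%02d", 1:n))
    feature_table(v, units = "counts", rank = "phylum")
  }
  meta <- make_meta(n, n)
  designs <- enumerate_comparisons(meta, "case", "control")
  # case F/B doubled relative to control
  out <- fb_ratio_cross_project(list(make_phylum_table(0.5)), list(meta),
                                designs)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$fold_change - 2), 0.8)
  expect_equal(out$log2_p, log2(out$p))
  # p = 0.05 maps to log2 p ~ -4.32
  expect_equal(log2(0.05), -4.3219, tolerance = 1e-4)
  # missing phylum row: comparison skipped with a warning
  broken <- make_phylum_table(1)
  broken$values <- broken$values[-1, , drop = FALSE]
  expect_warning(out2 <- fb_ratio_cross_project(list(broken), list(meta),
                                                designs), "skipped")
  expect_equal(nrow(out2), 0)
})

test_that("pathway matrix masks entries failing the strict LDA and p gates", {
  paths <- c("ko1", "ko2", "ko3")
  mk <- function(id, lda, p, lfc) {
    tab <- data.frame(feature = paths, log2FC = lfc, p = p,
                      significant = p < 0.05, lda_log10 = lda,
                      direction = ifelse(lfc > 0, "up", "down"),
                      stringsAsFactors = FALSE)
    comparison_result(id, tab)
  }
  results <- list(
    mk("c1", c(3.1, 2.0, NA), c(0.01, 0.01, 0.5), c(-1, 1, 1)),
    mk("c2", c(2.8, 2.5, 1.0), c(0.01, 0.2, 0.01), c(-2, 1, 1)),
    mk("c3", c(4.0, NA, NA), c(0.001, 0.9, 0.9), c(-1, 1, 1)),
    mk("c4", c(2.2, NA, NA), c(0.04, 0.9, 0.9), c(-0.5, 1, 1)))
  mat <- pathway_consistency(results)
  # ko1 planted down in all four comparisons: 4 negative unmasked entries
  expect_equal(sum(!is.na(mat["ko1", ])), 4)
  expect_true(all(mat["ko1", ] < 0))
  # lda exactly 2.0 is masked out (strict > 2), as is high p or low lda
  expect_false("ko2" %in% rownames(mat))
  expect_false("ko3" %in% rownames(mat))
  # nothing passing -> empty but well-formed matrix
  none <- pathway_consistency(list(mk("c1", c(1, 1, 1), rep(0.5, 3),
                                      c(1, 1, 1))))
  expect_equal(nrow(none), 0)
  expect_equal(ncol(none), 1)
})

test_that("stratified consistency keeps per-stratum scores and flags concordance", {
  feats <- c("gA", "gB")
  stratum <- function(prefix, signs_a, signs_b) {
    lapply(1:3, function(i) {
      make_result(paste0(prefix, i), feats,
                  c(signs_a[i] * 1.5, signs_b[i] * 1.2),
                  c(signs_a[i] != 0, signs_b[i] != 0))
    })
  }
  res <- list(
    obesity = stratum("ob", c(-1, -1, -1), c(1, 1, 1)),
    NAFLD = stratum("na", c(-1, -1, -1), c(0, 0, 0)))
  sc <- stratified_consistency(res, min_projects = 3, min_abs_cs = 0.6)
  # gA planted down in both strata: CS <= -0.6 in both, concordant
  expect_equal(unname(sc$cs_matrix["gA", ]), c(-1, -1))
  expect_true(sc$concordant[["gA"]])
  expect_true(all(sc$selected["gA", ]))
  # gB selected only in the stratum with an effect
  expect_true(sc$selected["gB", "obesity"])
  expect_false(sc$selected["gB", "NAFLD"])
  expect_error(stratified_consistency(res["obesity"]), "two strata")
  expect_warning(
    stratified_consistency(c(res, list(empty = list())))$cs_matrix,
    "no comparisons")
})
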
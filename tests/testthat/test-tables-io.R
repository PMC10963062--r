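# Reading, writing, validating and collapsing the tabular inputs.

test_that("feature table read-write-read is the identity", {
  m <- matrix(c(1, 2, 0, 3, 4.25, 0.125, 7, 1e-4, 9), 3, 3,
              dimnames = list(c("fA", "fB", "fC"), c("s1", "s2", "s3")))
  ft <- feature_table(m, units = "counts")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  ft2 <- read_feature_table(path, units = "counts")
  expect_identical(feature_ids(ft2), feature_ids(ft))
  expect_identical(sample_ids(ft2), sample_ids(ft))
  expect_lt(max(abs(ft2$values - ft$values)), 1e-12)
  # integer entries round-trip bit-exactly
  expect_identical(ft2$values["fA", ], ft$values["fA", ])
})

test_that("table validation rejects bad inputs", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s3_class(feature_table(m, "counts"), "feature_table")
  m_neg <- m; m_neg[1, 1] <- -1
  expect_error(feature_table(m_neg, "counts"), "negative")
  m_dup <- m; rownames(m_dup) <- c("a", "a")
  expect_error(feature_table(m_dup, "counts"), "duplicate feature")
  m_dups <- m; colnames(m_dups) <- c("s1", "s1")
  expect_error(feature_table(m_dups, "counts"), "duplicate sample")
  m_rel <- matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(feature_table(m_rel, "relative"), "sum above 1")

  neg_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "fA\t-3\t1", "fB\t2\t2"), neg_tsv)
  expect_error(read_feature_table(neg_tsv, "counts"), "negative")
})

test_that("lineage strings are extracted from MetaPhlAn-style tables and round-trip", {
  strings <- c(
    "k__Bacteria|p__Firmicutes|c__Bacilli|o__Lactobacillales|f__Lactobacillaceae|g__Lactobacillus|s__Lactobacillus_reuteri",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__|f__|g__Dubosiella",
    "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__|g__Bacteroides",
    "k__Bacteria|p__Verrucomicrobia|c__|o__|f__|g__Akkermansia",
    "k__Bacteria|p__Proteobacteria|c__|o__|f__|g__")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2",
               paste(strings, 1:5, 6:10, sep = "\t")), path)
  ft <- read_feature_table(path, units = "counts")
  tax <- attr(ft, "taxonomy")
  expect_s3_class(tax, "taxonomy_map")
  expect_equal(tax$genus[1:4],
               c("Lactobacillus", "Dubosiella", "Bacteroides", "Akkermansia"))
  expect_equal(tax$phylum[5], "Proteobacteria")
  # formatting the parsed lineage reproduces the original string
  for (s in strings[1:4]) {
    expect_identical(format_lineage(parse_lineage(s)), s)
  }
  # QIIME dialect round-trips too
  q <- "k__Bacteria; p__Firmicutes; c__Bacilli"
  expect_identical(format_lineage(parse_lineage(q), sep = "; "), q)
})

test_that("collapse_to_rank sums lineage groups and conserves column totals", {
  m <- matrix(c(0.2, 0.3, 0.1, 0.15,
                0.4, 0.1, 0.2, 0.05), 4, 2,
              dimnames = list(c("g1", "g2", "g3", "g4"), c("s1", "s2")))
  tax <- taxonomy_from_strings(stats::setNames(c(
    "k__Bacteria|p__Firmicutes|c__|o__|f__|g__A",
    "k__Bacteria|p__Firmicutes|c__|o__|f__|g__B",
    "k__Bacteria|p__Bacteroidetes|c__|o__|f__|g__C",
    "k__Bacteria|p__|c__|o__|f__|g__D"), paste0("g", 1:4)))
  ft <- feature_table(m, units = "relative")
  ph <- collapse_to_rank(ft, tax, "phylum")
  # two same-phylum genera (0.2, 0.3) collapse to one 0.5 row
  expect_equal(unname(ph$values["Firmicutes", "s1"]), 0.5)
  # unannotated feature lands in Unclassified, values preserved
  expect_equal(unname(ph$values["Unclassified", ]), unname(m["g4", ]))
  # column totals conserved exactly
  expect_equal(colSums(ph$values), colSums(m))
  # collapsing a table already at the rank is the identity up to row order
  gtab <- collapse_to_rank(ft, tax, "genus")
  tax_g <- taxonomy_from_strings(stats::setNames(
    sprintf("k__Bacteria|p__|c__|o__|f__|g__%s", feature_ids(gtab)),
    feature_ids(gtab)))
  again <- collapse_to_rank(gtab, tax_g, "genus")
  expect_equal(again$values[feature_ids(gtab), ], gtab$values)
  expect_error(collapse_to_rank(ft, tax, "tribe"), "unknown rank")
})

test_that("enumerate_comparisons finds one design per qualifying project", {
  meta <- do.call(rbind, lapply(c("P03", "P01", "P02"), function(p) {
    make_meta(3, 3, project = p)
  }))
  des <- enumerate_comparisons(meta, "case", "control")
  expect_equal(nrow(des), 3)
  expect_equal(des$project, c("P01", "P02", "P03"))  # deterministic order
  expect_true(all(des$case_group == "case"))

  # multi-timepoint project: one comparison per requested label pair
  tp <- data.frame(sample_id = paste0("s", 1:9),
                   group = rep(c("pre", "post1", "post2"), each = 3),
                   project = "PX", phenotype = NA, intervention = NA,
                   role = NA, stringsAsFactors = FALSE)
  d1 <- enumerate_comparisons(tp, "post1", "pre")
  d2 <- enumerate_comparisons(tp, "post2", "pre")
  expect_equal(nrow(d1) + nrow(d2), 2)

  expect_warning(
    empty <- enumerate_comparisons(make_meta(2, 2), "HFD", "ND"),
    "no project")
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(suppressWarnings(
    enumerate_comparisons(make_meta(1, 1)[0, ], "a", "b"))), 0)
})

test_that("samples absent from metadata are dropped with a warning", {
  ft <- make_ft(matrix(1:6, 2, 3), samples = c("s1", "s2", "extra"))
  meta <- data.frame(sample_id = c("s1", "s2"), group = c("case", "control"),
                     project = "P01", stringsAsFactors = FALSE)
  expect_warning(al <- align_samples(ft, meta), "absent from metadata")
  expect_equal(sample_ids(al$table), c("s1", "s2"))
  expect_equal(al$meta$sample_id, c("s1", "s2"))
})
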
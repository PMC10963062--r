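# Tabular input/output: feature tables, sample metadata, taxonomy lineages,
# and the comparison design derived from metadata.

CANONICAL_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")
RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Read a feature abundance table from TSV
#'
#' Expects a UTF-8 TSV whose header row holds sample ids (first header cell
#' `feature_id` or similar) and whose first column holds feature ids. Tables
#' whose first column carries rank-prefixed lineage strings (QIIME
#' `k__...; p__...` or MetaPhlAn `k__...|p__...` dialects) are detected
#' automatically and the lineages are extracted into a taxonomy map.
#'
#' @param path Path to the TSV file.
#' @param units `"counts"` or `"relative"`; stored on the returned table and
#'   validated (relative columns must sum to at most 1).
#' @param lineage `"auto"` (detect lineage strings in the first column),
#'   `"never"`, or `"always"`.
#' @return A `feature_table`. If lineages were extracted, the taxonomy map
#'   (see [read_taxonomy()]) is attached as attribute `"taxonomy"`.
#' @export
read_feature_table <- function(path, units = c("counts", "relative"),
                               lineage = c("auto", "never", "always")) {
  units <- match.arg(units)
  lineage <- match.arg(lineage)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("feature table needs at least one sample column", call. = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    storage.mode(mat) <- "double"
    if (any(is.na(mat))) stop("non-numeric abundance values in ", path, call. = FALSE)
  }
  rownames(mat) <- ids

  has_lineage <- lineage == "always" ||
    (lineage == "auto" && any(grepl("(k__|p__|g__)", ids)) &&
       any(grepl("[|;]", ids)))
  tax <- NULL
  if (has_lineage) {
    tax <- taxonomy_from_strings(ids)
  }
  ft <- feature_table(mat, units = units)
  if (!is.null(tax)) attr(ft, "taxonomy") <- tax
  ft
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: first header cell is `feature_id`,
#' remaining header cells are sample ids. Values are written at full double
#' precision so that read-write-read round-trips are exact for integers and
#' within 1e-12 for decimals.
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(feature_id = feature_ids(ft), ft$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a rank-prefixed taxonomy lineage string
#'
#' Accepts both the QIIME/greengenes dialect (`k__Bacteria; p__Firmicutes`,
#' semicolon-separated, optional spaces) and the MetaPhlAn dialect
#' (`k__Bacteria|p__Firmicutes`, pipe-separated). The separator is detected
#' per string. Rank prefixes are stripped; missing trailing levels are
#' returned as empty strings.
#'
#' @param x A single lineage string.
#' @return Named character vector over the seven canonical ranks.
#' @export
parse_lineage <- function(x) {
  stopifnot(length(x) == 1L)
  sep <- if (grepl("|", x, fixed = TRUE)) "\\|" else ";"
  parts <- trimws(strsplit(x, sep)[[1]])
  out <- stats::setNames(character(7L), CANONICAL_RANKS)
  for (p in parts) {
    hit <- which(startsWith(p, RANK_PREFIXES))
    if (length(hit) == 1L) {
      out[names(RANK_PREFIXES)[hit]] <- substring(p, 4L)
    }
  }
  # prefix-less dialects: fill positionally
  if (!any(nzchar(out)) && length(parts)) {
    n <- min(length(parts), 7L)
    out[seq_len(n)] <- parts[seq_len(n)]
  }
  out
}

#' Format a lineage vector back into a prefixed string
#'
#' @param levels Character vector over the canonical ranks (as returned by
#'   [parse_lineage()]); trailing empty levels are kept so parsing
#'   round-trips.
#' @param sep `"|"` (MetaPhlAn) or `"; "` (QIIME).
#' @param n_levels Number of levels to print (default: up to the deepest
#'   non-empty one, minimum 1).
#' @return A single lineage string.
#' @export
format_lineage <- function(levels, sep = "|", n_levels = NULL) {
  if (is.null(n_levels)) {
    nz <- which(nzchar(levels))
    n_levels <- if (length(nz)) max(nz) else 1L
  }
  paste0(RANK_PREFIXES[seq_len(n_levels)], levels[seq_len(n_levels)],
         collapse = sep)
}

#' Build a taxonomy map from lineage strings
#'
#' @param x Character vector of lineage strings; names (or the strings
#'   themselves) become feature ids.
#' @return A data frame with column `feature_id` plus one column per
#'   canonical rank (class `taxonomy_map`).
#' @export
taxonomy_from_strings <- function(x) {
  ids <- if (is.null(names(x))) x else names(x)
  lv <- t(vapply(x, parse_lineage, character(7L)))
  df <- data.frame(feature_id = ids, lv, stringsAsFactors = FALSE,
                   row.names = NULL, check.names = FALSE)
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read a taxonomy map from TSV
#'
#' Expects two tab-separated columns: feature id and lineage string (either
#' dialect, see [parse_lineage()]).
#'
#' @param path Path to the TSV.
#' @return A `taxonomy_map` data frame.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop("taxonomy file needs feature_id and lineage columns", call. = FALSE)
  tax <- taxonomy_from_strings(stats::setNames(as.character(df[[2]]),
                                               as.character(df[[1]])))
  tax
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `group`, `project`. Optional columns:
#' `phenotype`, `intervention`, `role` (`case`/`control`). Missing optional
#' columns are added as `NA`.
#'
#' @param path Path to the TSV.
#' @return A data frame of per-sample labels.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  required <- c("sample_id", "group", "project")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (opt in c("phenotype", "intervention", "role")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  df
}

#' Align a feature table with sample metadata
#'
#' Sample ids are matched case-sensitively. Table samples absent from the
#' metadata are dropped with a warning (mirroring tolerant subsetting);
#' metadata rows without a table column are ignored.
#'
#' @param ft A `feature_table`.
#' @param meta Metadata data frame from [read_sample_metadata()].
#' @return List with the aligned `table` and `meta` (same sample order).
#' @export
align_samples <- function(ft, meta) {
  shared <- intersect(sample_ids(ft), meta$sample_id)
  dropped <- setdiff(sample_ids(ft), shared)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " sample(s) absent from metadata: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  }
  if (!length(shared)) stop("no samples shared between table and metadata", call. = FALSE)
  list(table = subset_samples(ft, shared),
       meta = meta[match(shared, meta$sample_id), , drop = FALSE])
}

#' Collapse a feature table to a taxonomic rank
#'
#' Rows mapping to the same (case-sensitive) lineage value at `rank` are
#' summed; features with an empty or missing value at that rank are pooled
#' into `"Unclassified"`. Column totals are conserved exactly.
#'
#' @param ft A `feature_table`.
#' @param tax A `taxonomy_map` covering (at least) the table's features.
#' @param rank One of the seven canonical ranks
#'   (`r paste(CANONICAL_RANKS, collapse = ", ")`).
#' @return A `feature_table` at the requested rank, rows sorted
#'   alphabetically with `"Unclassified"` last.
#' @export
collapse_to_rank <- function(ft, tax, rank) {
  if (!rank %in% CANONICAL_RANKS) {
    stop("unknown rank '", rank, "'; expected one of ",
         paste(CANONICAL_RANKS, collapse = ", "), call. = FALSE)
  }
  labels <- tax[[rank]][match(feature_ids(ft), tax$feature_id)]
  labels[is.na(labels) | !nzchar(labels)] <- "Unclassified"
  collapsed <- rowsum(ft$values, group = labels, reorder = TRUE)
  ord <- order(rownames(collapsed) == "Unclassified", rownames(collapsed))
  collapsed <- collapsed[ord, , drop = FALSE]
  feature_table(collapsed, units = ft$units, rank = rank)
}

#' Enumerate case-vs-control comparisons across projects
#'
#' One comparison is defined per project whose metadata contains both the
#' case and the control group label. Projects with multiple relevant label
#' pairs (time points, dosages) yield one comparison per call with the
#' corresponding pair.
#'
#' @param meta Metadata data frame ([read_sample_metadata()]).
#' @param case_label Group label treated as case.
#' @param control_label Group label treated as control.
#' @return A data frame with one row per comparison: `comparison_id`,
#'   `project`, `case_group`, `control_group`, `phenotype`, `intervention`,
#'   ordered by project id. Empty (with a warning) when no project carries
#'   both labels.
#' @export
enumerate_comparisons <- function(meta, case_label, control_label) {
  if (identical(case_label, control_label)) {
    stop("case and control labels must differ", call. = FALSE)
  }
  out <- data.frame(comparison_id = character(), project = character(),
                    case_group = character(), control_group = character(),
                    phenotype = character(), intervention = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(meta)) return(out)
  for (proj in sort(unique(meta$project))) {
    sub <- meta[meta$project == proj, , drop = FALSE]
    if (case_label %in% sub$group && control_label %in% sub$group) {
      first <- function(col) {
        v <- sub[[col]][sub$group %in% c(case_label, control_label)]
        v <- v[!is.na(v)]
        if (length(v)) v[[1]] else NA_character_
      }
      out <- rbind(out, data.frame(
        comparison_id = paste(proj, case_label, "vs", control_label, sep = "."),
        project = proj, case_group = case_label,
        control_group = control_label,
        phenotype = first("phenotype"), intervention = first("intervention"),
        stringsAsFactors = FALSE))
    }
  }
  if (!nrow(out)) {
    warning("no project contains both '", case_label, "' and '",
            control_label, "'", call. = FALSE)
  }
  out
}
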
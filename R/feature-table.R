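#' Construct a feature table
#'
#' A feature table is the central data container: a non-negative numeric
#' matrix with features (taxa, OTUs, KOs, pathways) as rows and samples as
#' columns, plus a units flag saying whether the values are raw counts or
#' relative abundances, and an optional taxonomic rank label describing the
#' level the rows live at.
#'
#' @param values Numeric matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids). All entries must be
#'   finite and >= 0.
#' @param units Either `"counts"` or `"relative"`. For `"relative"` every
#'   column sum must be <= 1 + 1e-6.
#' @param rank Optional rank label (e.g. `"genus"`) recording the taxonomic
#'   level of the rows.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, units = c("counts", "relative"), rank = NULL) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (features) and colnames (samples)", call. = FALSE)
  }
  ft <- structure(
    list(values = values, units = units, rank = rank),
    class = "feature_table"
  )
  validate_feature_table(ft)
  ft
}

#' Validate feature-table invariants
#'
#' Checks non-negativity, finiteness, id uniqueness and (for relative
#' tables) that no column sums above 1.
#'
#' @param ft A `feature_table`.
#' @return `ft`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  v <- ft$values
  if (anyDuplicated(rownames(v))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(v))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(v))) stop("feature table contains non-finite values", call. = FALSE)
  if (any(v < 0)) stop("feature table contains negative values", call. = FALSE)
  if (ft$units == "relative") {
    cs <- colSums(v)
    bad <- cs > 1 + 1e-6
    if (any(bad)) {
      stop("relative-abundance columns sum above 1: ",
           paste(colnames(v)[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%s%s)\n",
              nrow(x$values), ncol(x$values), x$units,
              if (is.null(x$rank)) "" else paste0(", rank=", x$rank)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample identifiers of a feature table
#' @param ft A `feature_table`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(ft) rownames(ft$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(ft) colnames(ft$values)

#' Subset a feature table by samples
#'
#' @param ft A `feature_table`.
#' @param samples Character vector of sample ids to keep (order preserved).
#' @return A `feature_table` restricted to those samples.
#' @export
subset_samples <- function(ft, samples) {
  missing <- setdiff(samples, sample_ids(ft))
  if (length(missing)) {
    stop("samples not in table: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  feature_table(ft$values[, samples, drop = FALSE], units = ft$units, rank = ft$rank)
}
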
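#' Construct a samples-by-features abundance table
#'
#' The central container for species or pathway profiles: a non-negative
#' numeric matrix with unique sample ids as row names and unique feature ids
#' as column names, plus optional per-feature taxonomy (rank-prefixed,
#' pipe-separated clade strings) for species tables.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param feature_kind one of "species", "pathway", "stratified-pathway".
#' @param taxonomy optional named character vector of clade strings, one per
#'   feature (names must match colnames of `values`).
#' @param relative logical; if TRUE each row must sum to 1 (within 1e-6) or to
#'   100 (within 1e-4) for the percent dialect.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, feature_kind = c("species", "pathway", "stratified-pathway"),
                            taxonomy = NULL, relative = FALSE) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance_table: values must have sample (row) and feature (column) names")
  if (anyDuplicated(rownames(values))) stop("abundance_table: duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("abundance_table: duplicate feature ids")
  if (any(values < 0)) stop("abundance_table: negative abundances")
  if (relative) {
    rs <- rowSums(values)
    ok1 <- all(abs(rs - 1) <= 1e-6)
    ok100 <- all(abs(rs - 100) <= 1e-4)
    if (!ok1 && !ok100)
      stop("abundance_table: rows flagged relative must sum to 1 (or 100)")
  }
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) names(taxonomy) <- colnames(values)
    if (!all(colnames(values) %in% names(taxonomy)))
      stop("abundance_table: taxonomy must cover every feature")
    taxonomy <- taxonomy[colnames(values)]
  }
  structure(list(values = values, feature_kind = feature_kind,
                 taxonomy = taxonomy, relative = relative),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d %s features%s\n",
              nrow(x$values), ncol(x$values), x$feature_kind,
              if (x$relative) " (relative)" else ""))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)

# subset an abundance_table by features and/or samples, keeping taxonomy in step
at_subset <- function(x, samples = NULL, features = NULL) {
  v <- x$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  tax <- if (!is.null(x$taxonomy)) x$taxonomy[colnames(v)] else NULL
  abundance_table(v, x$feature_kind, taxonomy = tax, relative = FALSE)
}
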
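#' Read a MetaPhlAn-style merged abundance table
#'
#' Parses the merged-table dialect of the MetaPhlAn profiler: TSV with a
#' clade-string first column (`k__...|p__...|...|s__...`) and one column per
#' sample. Only species-level rows (containing `s__` and no strain-level
#' `t__`) are retained; coarser ranks are represented by their own rows and
#' dropped here (use [aggregate_to_rank()] to recover them). Values in the
#' percent dialect (row sums near 100 per sample) are rescaled to proportions;
#' the dialect is auto-detected from the median per-sample sum.
#'
#' @param path TSV file path.
#' @return an [abundance_table()] of species proportions with taxonomy.
#' @export
read_metaphlan_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0L) stop("read_metaphlan_table: empty file: ", path)
  clade <- as.character(raw[[1]])
  if (anyDuplicated(colnames(raw)[-1]))
    stop("read_metaphlan_table: duplicate sample column in ", path)
  bad <- !grepl("^k__", clade)
  if (any(bad)) {
    warning(sprintf("read_metaphlan_table: dropping %d malformed clade row(s)", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
    clade <- clade[!bad]
  }
  is_species <- grepl("\\|s__", clade) & !grepl("\\|t__", clade)
  raw <- raw[is_species, , drop = FALSE]
  clade <- clade[is_species]
  if (nrow(raw) == 0L) stop("read_metaphlan_table: no species-level rows in ", path)
  feats <- sub("^.*\\|s__", "", clade)
  if (anyDuplicated(feats)) stop("read_metaphlan_table: duplicate species ids")
  vals <- t(as.matrix(raw[, -1, drop = FALSE]))  # samples x features
  mode(vals) <- "numeric"
  colnames(vals) <- feats
  if (stats::median(rowSums(vals)) > 2) vals <- vals / 100
  abundance_table(vals, "species", taxonomy = stats::setNames(clade, feats))
}

#' Write a species table in the MetaPhlAn merged dialect
#'
#' @param table species [abundance_table()] with taxonomy.
#' @param path output TSV path.
#' @param percent write on the percent scale (rows summing to 100).
#' @return `path`, invisibly.
#' @export
write_metaphlan_table <- function(table, path, percent = TRUE) {
  stopifnot(inherits(table, "abundance_table"), !is.null(table$taxonomy))
  vals <- t(table$values)             # features x samples
  if (percent) vals <- vals * 100
  df <- data.frame(clade_name = unname(table$taxonomy[rownames(vals)]),
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a HUMAnN-style pathway abundance table
#'
#' Splits community-level rows (plain pathway id) from taxon-stratified rows
#' (`PWY|g__Genus.s__Species`). `UNMAPPED`/`UNINTEGRATED` rows are excluded by
#' default. Rows that are neither community nor parseable stratified entries
#' are skipped with a warning.
#'
#' @param path TSV file path; first column pathway id, remaining columns samples.
#' @param keep_unintegrated retain UNMAPPED/UNINTEGRATED rows as community features.
#' @return list with elements `community` and `stratified`
#'   ([abundance_table()]s); the stratified table carries attributes
#'   `pathway` and `taxon` giving the split feature ids.
#' @export
read_humann_pathways <- function(path, keep_unintegrated = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0L) stop("read_humann_pathways: empty file: ", path)
  ids <- as.character(raw[[1]])
  if (!keep_unintegrated) {
    drop <- grepl("^(UNMAPPED|UNINTEGRATED)", ids)
    raw <- raw[!drop, , drop = FALSE]; ids <- ids[!drop]
  }
  strat <- grepl("|", ids, fixed = TRUE)
  parse_ok <- !strat | grepl("^[^|]+\\|.+$", ids)
  if (any(!parse_ok)) {
    warning(sprintf("read_humann_pathways: skipping %d unparseable row(s)", sum(!parse_ok)))
    raw <- raw[parse_ok, , drop = FALSE]; ids <- ids[parse_ok]; strat <- strat[parse_ok]
  }
  vals <- as.matrix(raw[, -1, drop = FALSE]); mode(vals) <- "numeric"
  if (sum(!strat) == 0L) stop("read_humann_pathways: no community-level rows in ", path)
  comm <- t(vals[!strat, , drop = FALSE]); colnames(comm) <- ids[!strat]
  community <- abundance_table(comm, "pathway")
  stratified <- NULL
  if (any(strat)) {
    sv <- t(vals[strat, , drop = FALSE]); colnames(sv) <- ids[strat]
    stratified <- abundance_table(sv, "stratified-pathway")
    attr(stratified, "pathway") <- sub("\\|.*$", "", ids[strat])
    attr(stratified, "taxon") <- sub("^[^|]+\\|", "", ids[strat])
  }
  list(community = community, stratified = stratified)
}

#' Write a pathway table (optionally with stratified rows) in HUMAnN dialect
#'
#' @param community community-level [abundance_table()].
#' @param path output TSV path.
#' @param stratified optional stratified [abundance_table()].
#' @return `path`, invisibly.
#' @export
write_humann_pathways <- function(community, path, stratified = NULL) {
  blocks <- t(community$values)
  if (!is.null(stratified)) blocks <- rbind(blocks, t(stratified$values))
  df <- data.frame(`# Pathway` = rownames(blocks), blocks,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Align a cohort table with an abundance table on participant/sample ids
#'
#' Participants missing from either side are dropped (a message reports the
#' count); both outputs share the same id order.
#'
#' @param cohort data.frame with a `participant_id` column.
#' @param table an [abundance_table()].
#' @return list(cohort, table) with matched row order.
#' @export
align_tables <- function(cohort, table) {
  stopifnot(nrow(cohort) > 0, nrow(table$values) > 0)
  common <- intersect(cohort$participant_id, sample_ids(table))
  if (length(common) == 0L) stop("align_tables: no overlapping ids")
  dropped <- (nrow(cohort) - length(common)) + (nrow(table$values) - length(common))
  if (dropped > 0) message(sprintf("align_tables: dropped %d unmatched row(s)", dropped))
  cohort2 <- cohort[match(common, cohort$participant_id), , drop = FALSE]
  rownames(cohort2) <- NULL
  list(cohort = cohort2, table = at_subset(table, samples = common))
}

#' Aggregate a species table to a coarser taxonomic rank
#'
#' Sums species abundances within each clade at the requested rank; a linear,
#' per-sample-total-preserving map.
#'
#' @param table species [abundance_table()] with taxonomy.
#' @param rank one of "kingdom", "phylum", "class", "order", "family",
#'   "genus", "species".
#' @return an [abundance_table()] at the requested rank.
#' @export
aggregate_to_rank <- function(table, rank) {
  ranks <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
             family = "f__", genus = "g__", species = "s__")
  rank <- match.arg(rank, names(ranks))
  if (rank == "species") return(table)
  stopifnot(!is.null(table$taxonomy))
  pre <- ranks[[rank]]
  groups <- vapply(table$taxonomy[colnames(table$values)], function(cl) {
    parts <- strsplit(cl, "|", fixed = TRUE)[[1]]
    hit <- parts[startsWith(parts, pre)]
    if (length(hit) == 0L) NA_character_ else sub(pre, "", hit[1], fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(groups))
    stop("aggregate_to_rank: rank '", rank, "' absent from some clade strings")
  agg <- t(rowsum(t(table$values), group = groups))
  abundance_table(agg, "species")
}

#' Read a participant metadata table (CSV)
#'
#' Missing values must be encoded as empty cells or `NA`; they are kept as
#' explicit `NA`s, never silently zeroed.
#'
#' @param path CSV path with a `participant_id` column.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"participant_id" %in% names(df))
    stop("read_cohort_csv: no participant_id column in ", path)
  if (anyDuplicated(df$participant_id)) stop("read_cohort_csv: duplicate participant ids")
  df
}
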
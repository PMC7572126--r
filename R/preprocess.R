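#' Mean arterial pressure from brachial readings
#'
#' MAP = (SBP + 2 DBP) / 3, mmHg. Affine in both inputs and bounded between
#' DBP and SBP; a DBP exceeding its SBP indicates a measurement inconsistency
#' and is an error.
#'
#' @param sbp,dbp systolic/diastolic blood pressure, mmHg (vectorized).
#' @return MAP in mmHg.
#' @export
compute_map <- function(sbp, dbp) {
  ok <- !(is.na(sbp) | is.na(dbp))
  if (any(dbp[ok] > sbp[ok])) stop("compute_map: DBP exceeds SBP")
  if (any(dbp[ok] <= 0)) stop("compute_map: non-positive pressure")
  (sbp + 2 * dbp) / 3
}

#' Hypertension flag
#'
#' TRUE iff SBP > 140 and/or DBP > 90 (strict inequalities).
#'
#' @param sbp,dbp blood pressures, mmHg (vectorized).
#' @return logical vector.
#' @export
flag_hypertension <- function(sbp, dbp) sbp > 140 | dbp > 90

#' Exclude rare taxa from a relative-abundance table
#'
#' A taxon is excluded iff its detection prevalence (abundance > 0) is below
#' `prevalence` AND its mean relative abundance is below `abundance`
#' (`logic = "and"`, the default reading; `logic = "or"` excludes on either
#' clause alone). Remaining abundances are NOT renormalized: they stay as
#' observed fractions. The filter is idempotent.
#'
#' @param table relative-abundance [abundance_table()].
#' @param prevalence detection-prevalence threshold, fraction in (0, 1].
#' @param abundance mean-relative-abundance threshold, fraction in (0, 1].
#' @param logic "and" (default) or "or"; how the two exclusion clauses combine.
#' @return list(table = filtered table, report = per-feature audit data.frame
#'   with prevalence, mean abundance and the retained flag).
#' @export
filter_rare_taxa <- function(table, prevalence = 0.40, abundance = 0.01,
                             logic = c("and", "or")) {
  logic <- match.arg(logic)
  if (prevalence <= 0 || prevalence > 1 || abundance <= 0 || abundance > 1)
    stop("filter_rare_taxa: thresholds must lie in (0, 1]")
  v <- table$values
  prev <- colMeans(v > 0)
  meanab <- colMeans(v)
  low_prev <- prev < prevalence
  low_ab <- meanab < abundance
  excluded <- if (logic == "and") low_prev & low_ab else low_prev | low_ab
  report <- data.frame(feature = colnames(v), prevalence = unname(prev),
                       mean_abundance = unname(meanab),
                       retained = unname(!excluded),
                       stringsAsFactors = FALSE)
  attr(report, "rule") <- sprintf(
    "exclude iff prevalence < %g %s mean relative abundance < %g",
    prevalence, toupper(logic), abundance)
  list(table = at_subset(table, features = colnames(v)[!excluded]),
       report = report)
}

#' Natural-log transform of cohort variables
#'
#' Applies [log_offset()] (half-minimum offset for zeros) column-wise;
#' offsets used are recorded in the "log_offsets" attribute. Negative values
#' are an error.
#'
#' @param cohort data.frame.
#' @param variables character vector of column names to transform.
#' @return cohort with transformed columns.
#' @export
log_transform <- function(cohort, variables) {
  stopifnot(all(variables %in% names(cohort)))
  offs <- numeric(0)
  for (v in variables) {
    lx <- log_offset(cohort[[v]])
    offs[v] <- attr(lx, "offset")
    cohort[[v]] <- as.numeric(lx)
  }
  attr(cohort, "log_offsets") <- offs
  cohort
}
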
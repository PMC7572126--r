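#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_i = min over j >= rank(i) of m p_(j) / j, capped
#' at 1. This is the single BH implementation shared by every stage of the
#' pipeline (a thin wrapper over `p.adjust`).
#'
#' @param p vector of p-values in [0, 1] (NAs propagate).
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_fdr: p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Presence/absence matrix from an abundance table
#'
#' Presence = abundance strictly greater than `threshold` (default 0:
#' profiler detection equals presence).
#'
#' @param table [abundance_table()].
#' @param threshold detection threshold (default 0).
#' @return integer samples x features matrix of 0/1.
#' @export
presence_matrix <- function(table, threshold = 0) {
  v <- table$values
  out <- (v > threshold) + 0L
  dimnames(out) <- dimnames(v)
  out
}

#' Microbiome-wide moderation (interaction) scan
#'
#' Per eligible taxon fits Y = b0 + b1 group + b2 presence +
#' b3 (group x presence) + eta' covariates and Wald-tests b3. Taxa outside
#' the prevalence window, or with any of the four group x presence cell
#' counts below `cell_min`, are skipped (reason recorded) and do not enter
#' the Benjamini-Hochberg correction, which runs across tested taxa only.
#'
#' @param outcome numeric outcome vector (e.g. SBP, mmHg).
#' @param group binary grouping (factor or 0/1), e.g. island.
#' @param presence samples x taxa 0/1 matrix from [presence_matrix()].
#' @param covariates optional data.frame of adjustment covariates.
#' @param cell_min minimum count per group x presence cell (default 3).
#' @param prevalence_window presence-fraction eligibility window (default 0.1-0.9).
#' @return data.frame: taxon, beta_interaction, se, t, p, q, cell counts,
#'   skipped, skip_reason.
#' @export
interaction_scan <- function(outcome, group, presence, covariates = NULL,
                             cell_min = 3, prevalence_window = c(0.1, 0.9)) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("interaction_scan: group must be binary")
  g01 <- as.numeric(g) - 1
  n <- length(outcome)
  stopifnot(nrow(presence) == n, length(g01) == n)
  cmat <- if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    stats::model.matrix(~ ., as.data.frame(covariates))[, -1, drop = FALSE]
  else matrix(0, n, 0)
  if (ncol(cmat)) {
    keep <- qr(cbind(1, cmat))$rank == ncol(cmat) + 1
    if (!keep) {
      warning("interaction_scan: dropping collinear covariate column(s)")
      qq <- qr(cbind(1, cmat))
      idx <- qq$pivot[seq_len(qq$rank)]
      cmat <- cbind(1, cmat)[, idx, drop = FALSE][, -1, drop = FALSE]
    }
  }
  rows <- lapply(colnames(presence), function(tx) {
    pr <- presence[, tx]
    prev <- mean(pr)
    base <- data.frame(taxon = tx, beta_interaction = NA_real_, se = NA_real_,
                       t = NA_real_, p = NA_real_, q = NA_real_,
                       n_g0_absent = sum(g01 == 0 & pr == 0),
                       n_g0_present = sum(g01 == 0 & pr == 1),
                       n_g1_absent = sum(g01 == 1 & pr == 0),
                       n_g1_present = sum(g01 == 1 & pr == 1),
                       skipped = TRUE, skip_reason = "", stringsAsFactors = FALSE)
    if (prev <= 0 || prev >= 1) { base$skip_reason <- "degenerate presence"; return(base) }
    if (prev < prevalence_window[1] || prev > prevalence_window[2]) {
      base$skip_reason <- "outside prevalence window"; return(base)
    }
    cells <- c(base$n_g0_absent, base$n_g0_present, base$n_g1_absent, base$n_g1_present)
    if (any(cells < cell_min)) { base$skip_reason <- "cell below cell_min"; return(base) }
    xm <- cbind(`(Intercept)` = 1, group = g01, presence = pr,
                interaction = g01 * pr, cmat)
    xtx <- crossprod(xm)
    xtxi <- tryCatch(solve(xtx), error = function(e) NULL)
    if (is.null(xtxi)) { base$skip_reason <- "collinear"; return(base) }
    cf <- drop(xtxi %*% crossprod(xm, outcome))
    resid <- outcome - drop(xm %*% cf)
    dfres <- n - ncol(xm)
    rss <- sum(resid^2)
    se <- sqrt(rss / dfres * xtxi[4, 4])
    base$beta_interaction <- unname(cf[4])
    base$se <- se
    base$t <- base$beta_interaction / se
    base$p <- 2 * stats::pt(-abs(base$t), dfres)
    base$skipped <- FALSE
    base$skip_reason <- NA_character_
    base
  })
  out <- do.call(rbind, rows)
  tested <- !out$skipped
  out$q[tested] <- bh_fdr(out$p[tested])
  out
}

#' Moderation ladder for selected taxa
#'
#' Refits the interaction model for each taxon of interest under three
#' adjustment rungs (unadjusted, age-adjusted, multivariate: age, BMI,
#' gender, smoking, fruit, vegetables, takeaway, ssb, seafood, alcohol) and
#' reports the four group x presence cell means with pairwise Welch t-tests
#' (all pairs returned; the `significant` flag mirrors a p < 0.05 display
#' convention).
#'
#' @param data data.frame with outcome, group, and covariate columns.
#' @param outcome,group column names.
#' @param presence samples x taxa 0/1 matrix (rows aligned with `data`).
#' @param taxa taxa of interest (columns of `presence`).
#' @param multivariate_set covariate columns of the widest rung.
#' @return nested list: per taxon, per rung, list(scan_row, cell_means,
#'   pairwise).
#' @export
scan_ladder <- function(data, outcome, group, presence, taxa,
                        multivariate_set = c("age", "bmi", "gender", "smoking",
                                             "fruit", "vegetables", "takeaway",
                                             "ssb", "seafood", "alcohol")) {
  rungs <- list(unadjusted = character(), age = "age",
                multivariate = intersect(multivariate_set, names(data)))
  g <- as.factor(data[[group]])
  y <- data[[outcome]]
  out <- list()
  for (tx in taxa) {
    pr <- presence[, tx]
    cellid <- interaction(g, ifelse(pr == 1, "present", "absent"), sep = " & ")
    cm <- tapply(y, cellid, mean)
    counts <- as.vector(table(cellid))
    pairs <- utils::combn(levels(cellid), 2)
    pw <- apply(pairs, 2, function(pp) {
      y1 <- y[cellid == pp[1]]; y2 <- y[cellid == pp[2]]
      if (length(y1) < 2 || length(y2) < 2) return(NA_real_)
      stats::t.test(y1, y2)$p.value
    })
    pairwise <- data.frame(cell_a = pairs[1, ], cell_b = pairs[2, ],
                           p = pw, significant = !is.na(pw) & pw < 0.05,
                           stringsAsFactors = FALSE)
    res <- list()
    for (nm in names(rungs)) {
      cv <- rungs[[nm]]
      covdf <- if (length(cv)) data[, cv, drop = FALSE] else NULL
      sr <- interaction_scan(y, g, presence[, tx, drop = FALSE], covariates = covdf)
      res[[nm]] <- list(scan_row = sr,
                        cell_means = data.frame(cell = names(cm),
                                                mean = as.vector(cm),
                                                n = counts,
                                                stringsAsFactors = FALSE),
                        pairwise = pairwise)
    }
    out[[tx]] <- res
  }
  out
}
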
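#' Two-group comparisons with paired unadjusted/age-adjusted p-values
#'
#' Per variable: group medians with quartiles (always on the untransformed
#' scale), an unadjusted p from a one-way ANOVA (with two groups this equals
#' the pooled t-test), and an adjusted p from an ANCOVA (linear model
#' variable ~ group + covariate, Wald test on group). Variables listed in
#' `log_vars` are natural-log transformed (half-minimum offset for zeros)
#' before testing.
#'
#' @param cohort data.frame.
#' @param variables numeric columns to compare.
#' @param group binary grouping column name.
#' @param log_vars subset of `variables` to test on the log scale.
#' @param covariate adjustment covariate (default "age").
#' @return data.frame with medians, quartiles, p_unadjusted, p_adjusted,
#'   transformed flag and a note for degenerate variables.
#' @export
table1_compare <- function(cohort, variables, group, log_vars = character(),
                           covariate = "age") {
  g <- as.factor(cohort[[group]])
  stopifnot(nlevels(g) == 2)
  lv <- levels(g)
  rows <- lapply(variables, function(v) {
    y_raw <- cohort[[v]]
    ok <- !is.na(y_raw) & !is.na(g)
    med <- function(lev) {
      q <- stats::quantile(y_raw[ok & g == lev], c(0.25, 0.5, 0.75))
      c(q1 = unname(q[1]), median = unname(q[2]), q3 = unname(q[3]))
    }
    m1 <- med(lv[1]); m2 <- med(lv[2])
    y <- if (v %in% log_vars) as.numeric(log_offset(y_raw)) else y_raw
    note <- ""
    if (stats::var(y[ok]) == 0) {
      p_un <- 1; p_adj <- 1; note <- "constant variable"
    } else {
      p_un <- stats::anova(stats::lm(y ~ g, subset = ok))[["Pr(>F)"]][1]
      if (v == covariate) p_adj <- NA_real_   # cannot adjust a variable for itself
      else {
        cov <- cohort[[covariate]]
        ok2 <- ok & !is.na(cov)
        fit <- stats::lm(y ~ g + cov, subset = ok2)
        p_adj <- summary(fit)$coefficients[2, 4]
      }
    }
    data.frame(variable = v,
               group1 = lv[1], median1 = m1["median"], q1_1 = m1["q1"], q3_1 = m1["q3"],
               group2 = lv[2], median2 = m2["median"], q1_2 = m2["q1"], q3_2 = m2["q3"],
               p_unadjusted = p_un, p_adjusted = p_adj,
               transformed = v %in% log_vars, n_used = sum(ok), note = note,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Spearman correlation screen of biomarkers against microbiome features
#'
#' Tie-corrected Spearman rho for every biomarker x feature pair, asymptotic
#' t-approximation p-values for n > 10 and the exact null distribution below
#' (via `cor.test`), Benjamini-Hochberg adjustment across the full grid, and
#' the pass rule |rho| >= rho_min AND q <= alpha. Pairs with fewer than 4
#' complete observations or a constant vector are flagged, not tested.
#'
#' @param biomarkers data.frame or matrix (participants x biomarkers).
#' @param features data.frame or matrix (participants x features), same rows.
#' @param rho_min effect-size threshold (default 0.3).
#' @param alpha q-value threshold (default 0.05).
#' @return data.frame: biomarker, feature, rho, p, q, n, passed, note.
#' @export
spearman_screen <- function(biomarkers, features, rho_min = 0.3, alpha = 0.05) {
  bm <- as.matrix(biomarkers); ft <- as.matrix(features)
  stopifnot(nrow(bm) == nrow(ft))
  grid <- expand.grid(biomarker = colnames(bm), feature = colnames(ft),
                      stringsAsFactors = FALSE)
  res <- mapply(function(b, f) {
    x <- bm[, b]; y <- ft[, f]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4) return(c(NA, NA, sum(ok), 1))
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA, NA, sum(ok), 2))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = sum(ok) <= 10))
    c(unname(ct$estimate), ct$p.value, sum(ok), 0)
  }, grid$biomarker, grid$feature)
  out <- data.frame(grid, rho = res[1, ], p = res[2, ], q = NA_real_,
                    n = res[3, ],
                    note = c("", "too few pairs", "constant vector")[res[4, ] + 1],
                    stringsAsFactors = FALSE)
  tested <- !is.na(out$p)
  out$q[tested] <- bh_fdr(out$p[tested])
  out$passed <- tested & abs(out$rho) >= rho_min & out$q <= alpha
  out
}

#' Community-level pathway comparison between two groups
#'
#' Per pathway: tie-corrected Mann-Whitney U p-value, Benjamini-Hochberg q,
#' and an effect size (difference in group mean proportions) with a seeded
#' percentile bootstrap 95% CI. Pathways absent in every sample are skipped.
#'
#' @param community community-level [abundance_table()].
#' @param group two-level labels, one per sample.
#' @param n_boot bootstrap resamples for the effect CI (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame: pathway, p, q, effect, effect_lo, effect_hi, skipped.
#' @export
pathway_compare <- function(community, group, n_boot = 1000, seed = 1, conf = 0.95) {
  g <- as.factor(group)
  stopifnot(nlevels(g) == 2, length(g) == nrow(community$values))
  v <- community$values
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  al <- (1 - conf) / 2
  boot_idx <- with_substream(seed, "pathway-boot", {
    list(a = matrix(sample(i1, length(i1) * n_boot, replace = TRUE), ncol = n_boot),
         b = matrix(sample(i2, length(i2) * n_boot, replace = TRUE), ncol = n_boot))
  })
  rows <- lapply(colnames(v), function(pw) {
    x <- v[, pw]
    if (all(x == 0)) {
      return(data.frame(pathway = pw, p = NA_real_, q = NA_real_,
                        effect = NA_real_, effect_lo = NA_real_,
                        effect_hi = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(stats::wilcox.test(x[i2], x[i1])$p.value)
    eff <- mean(x[i2]) - mean(x[i1])
    es <- colMeans(matrix(x[boot_idx$b], ncol = n_boot)) -
      colMeans(matrix(x[boot_idx$a], ncol = n_boot))
    ci <- stats::quantile(es, c(al, 1 - al))
    data.frame(pathway = pw, p = p, q = NA_real_, effect = eff,
               effect_lo = unname(ci[1]), effect_hi = unname(ci[2]),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !out$skipped
  out$q[tested] <- bh_fdr(out$p[tested])
  out
}

#' Stratified (pathway, taxon) comparison with the 80%-presence filter
#'
#' Keeps (pathway, taxon) features detected (> 0) in at least
#' `presence_floor` of the samples of either group, then applies
#' Mann-Whitney + Benjamini-Hochberg on the survivors. Non-surviving and
#' non-significant features are reported as such rather than dropped.
#'
#' @param stratified stratified [abundance_table()] from
#'   [read_humann_pathways()].
#' @param group two-level labels.
#' @param presence_floor within-group detection fraction required (default 0.8).
#' @param alpha significance threshold for the reported flag (default 0.05).
#' @return data.frame: feature, pathway, taxon, prevalence per group,
#'   retained, p, q, significant.
#' @export
stratified_pathway_compare <- function(stratified, group, presence_floor = 0.8,
                                       alpha = 0.05) {
  g <- as.factor(group)
  stopifnot(nlevels(g) == 2, length(g) == nrow(stratified$values))
  v <- stratified$values
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  prev1 <- colMeans(v[i1, , drop = FALSE] > 0)
  prev2 <- colMeans(v[i2, , drop = FALSE] > 0)
  retained <- prev1 >= presence_floor | prev2 >= presence_floor
  pw <- attr(stratified, "pathway")
  tx <- attr(stratified, "taxon")
  out <- data.frame(feature = colnames(v),
                    pathway = if (is.null(pw)) NA_character_ else pw,
                    taxon = if (is.null(tx)) NA_character_ else tx,
                    prevalence_g1 = unname(prev1), prevalence_g2 = unname(prev2),
                    retained = unname(retained), p = NA_real_, q = NA_real_,
                    stringsAsFactors = FALSE)
  if (any(retained)) {
    out$p[retained] <- apply(v[, retained, drop = FALSE], 2, function(x)
      suppressWarnings(stats::wilcox.test(x[i2], x[i1])$p.value))
    out$q[retained] <- bh_fdr(out$p[retained])
  }
  out$significant <- !is.na(out$q) & out$q <= alpha
  out
}
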
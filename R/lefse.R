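#' Scale each sample's feature vector to sum to one million
#'
#' @param table non-negative [abundance_table()].
#' @return per-million [abundance_table()].
#' @export
normalize_per_million <- function(table) {
  v <- table$values
  rs <- rowSums(v)
  if (any(rs == 0)) stop("normalize_per_million: all-zero sample")
  abundance_table(v / rs * 1e6, table$feature_kind, taxonomy = table$taxonomy)
}

#' Kruskal-Wallis gate for differential abundance
#'
#' Per-feature tie-corrected Kruskal-Wallis test of abundance against the
#' class labels; retains features with p <= alpha. With exactly two classes
#' the statistic is the chi-square form of the Wilcoxon rank-sum statistic.
#' Constant features get p = 1.
#'
#' @param table [abundance_table()] (any scale; ranks are scale-free).
#' @param classes class labels, one per sample.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame(feature, kw_p, retained).
#' @export
kw_gate <- function(table, classes, alpha = 0.05) {
  classes <- as.factor(classes)
  stopifnot(length(classes) == nrow(table$values))
  if (any(table(classes) < 3)) stop("kw_gate: each class needs n >= 3")
  p <- apply(table$values, 2, function(x) {
    if (length(unique(x)) == 1L) return(1)
    stats::kruskal.test(x, classes)$p.value
  })
  data.frame(feature = colnames(table$values), kw_p = unname(p),
             retained = unname(p <= alpha), stringsAsFactors = FALSE)
}

# Regularized two-class LDA discriminant direction: covariance shrunk toward
# its diagonal with weight lambda, plus a small ridge for rank safety.
lda_direction <- function(x, cl, lambda = 0.1) {
  x0 <- x[cl == levels(cl)[1], , drop = FALSE]
  x1 <- x[cl == levels(cl)[2], , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1)
  sw <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) / (n0 + n1 - 2)
  sreg <- (1 - lambda) * sw + lambda * diag(diag(sw), ncol(x))
  diag(sreg) <- diag(sreg) + 1e-8 * mean(diag(sreg)) + 1e-12
  w <- solve(sreg, colMeans(x1) - colMeans(x0))
  nrm <- sqrt(sum(w^2))
  if (!is.finite(nrm) || nrm < 1e-300) w[] <- 0 else w <- w / nrm
  w
}

#' Bootstrap-averaged LDA effect size
#'
#' For each bootstrap round, each class is subsampled (with replacement, a
#' `boot_fraction` of its size) and a regularized two-class LDA is fitted on
#' the supplied features. A feature's raw effect in a round is
#' 0.5 (|class-mean difference| + |its discriminant-axis contribution|),
#' where the contribution is |w_j| times the between-class separation along
#' the unit discriminant axis. The final score is log10(1 + mean raw effect
#' over rounds). Scores are invariant to feature and sample order.
#'
#' @param table per-million [abundance_table()] restricted to KW-retained features.
#' @param classes two-level class labels.
#' @param n_boot bootstrap rounds (default 30).
#' @param boot_fraction per-class subsample fraction (default 2/3).
#' @param seed RNG seed.
#' @param lambda shrinkage weight toward the diagonal covariance (default 0.1).
#' @return data.frame(feature, lda_score, enriched_class).
#' @export
lda_effect_size <- function(table, classes, n_boot = 30, boot_fraction = 2/3,
                            seed = 1, lambda = 0.1) {
  cl <- as.factor(classes)
  if (nlevels(cl) != 2) stop("lda_effect_size: exactly two classes required")
  v <- table$values
  feats <- colnames(v)
  # order-invariance: work in a canonical feature order, restore at the end
  ord <- order(feats)
  v <- v[, ord, drop = FALSE]
  ord_s <- order(rownames(v))
  v <- v[ord_s, , drop = FALSE]
  cl <- cl[ord_s]
  idx0 <- which(cl == levels(cl)[1]); idx1 <- which(cl == levels(cl)[2])
  m0 <- max(2L, floor(boot_fraction * length(idx0)))
  m1 <- max(2L, floor(boot_fraction * length(idx1)))
  eff <- with_substream(seed, "lefse-lda", {
    rounds <- matrix(NA_real_, n_boot, ncol(v))
    failed <- 0L
    for (b in seq_len(n_boot)) {
      ok <- FALSE
      for (try in 1:5) {
        s0 <- sample(idx0, m0, replace = TRUE)
        s1 <- sample(idx1, m1, replace = TRUE)
        xs <- v[c(s0, s1), , drop = FALSE]
        cs <- droplevels(cl[c(s0, s1)])
        if (nlevels(cs) < 2) next
        w <- tryCatch(lda_direction(xs, cs, lambda), error = function(e) NULL)
        if (is.null(w)) next
        mu0 <- colMeans(xs[cs == levels(cs)[1], , drop = FALSE])
        mu1 <- colMeans(xs[cs == levels(cs)[2], , drop = FALSE])
        sep <- abs(sum(w * (mu1 - mu0)))
        rounds[b, ] <- 0.5 * (abs(mu1 - mu0) + abs(w) * sep)
        ok <- TRUE
        break
      }
      if (!ok) failed <- failed + 1L
    }
    if (failed > n_boot / 2) stop("lda_effect_size: more than half the bootstrap rounds failed")
    colMeans(rounds, na.rm = TRUE)
  })
  score <- log10(1 + eff)
  enriched <- ifelse(colMeans(v[idx1, , drop = FALSE]) >= colMeans(v[idx0, , drop = FALSE]),
                     levels(cl)[2], levels(cl)[1])
  out <- data.frame(feature = colnames(v), lda_score = unname(score),
                    enriched_class = unname(enriched), stringsAsFactors = FALSE)
  out[match(feats, out$feature), , drop = FALSE]
}

#' LEfSe-style differential abundance: KW gate + LDA effect size
#'
#' Normalizes to per-million, gates features by Kruskal-Wallis at `alpha`,
#' scores the retained features by bootstrap-averaged LDA effect size, and
#' flags features passing both gates (kw_p <= alpha AND lda_score >=
#' lda_threshold). Rows are sorted by score (descending) within enriched
#' class.
#'
#' @param table non-negative [abundance_table()] (relative or per-million).
#' @param classes two-level class labels.
#' @param alpha KW significance threshold (default 0.05).
#' @param lda_threshold log10 LDA score threshold (default 3).
#' @param n_boot,boot_fraction,lambda see [lda_effect_size()].
#' @param seed RNG seed.
#' @return data.frame(feature, kw_p, lda_score, enriched_class, passed).
#' @export
lefse <- function(table, classes, alpha = 0.05, lda_threshold = 3.0,
                  n_boot = 30, boot_fraction = 2/3, seed = 1, lambda = 0.1) {
  pm <- normalize_per_million(table)
  gate <- kw_gate(pm, classes, alpha)
  kept <- gate$feature[gate$retained]
  out <- data.frame(feature = gate$feature, kw_p = gate$kw_p,
                    lda_score = 0, enriched_class = NA_character_,
                    passed = FALSE, stringsAsFactors = FALSE)
  if (length(kept)) {
    sc <- lda_effect_size(at_subset(pm, features = kept), classes,
                          n_boot = n_boot, boot_fraction = boot_fraction,
                          seed = seed, lambda = lambda)
    i <- match(sc$feature, out$feature)
    out$lda_score[i] <- sc$lda_score
    out$enriched_class[i] <- sc$enriched_class
    out$passed <- out$kw_p <= alpha & out$lda_score >= lda_threshold &
      out$feature %in% kept
  }
  out[order(out$enriched_class, -out$lda_score), , drop = FALSE]
}
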
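#' Bias-corrected Chao1 richness
#'
#' S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with F1/F2 the singleton and
#' doubleton counts. Input must be (whole-number) counts; relative abundances
#' should first be scaled to counts per million (see [alpha_diversity()]).
#'
#' @param counts non-negative integer vector of per-species counts.
#' @return estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("chao1: negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("chao1: non-integer input; round per-million-scaled abundances first")
  counts <- round(counts)
  if (!any(counts > 0)) stop("chao1: all counts zero")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon-Wiener diversity (nats)
#'
#' H' = -sum p_i ln p_i over positive entries; the vector is renormalized
#' over its positive support.
#'
#' @param p non-negative abundance vector.
#' @return H' in nats.
#' @export
shannon <- function(p) {
  if (any(p < 0)) stop("shannon: negative abundances")
  q <- p[p > 0]
  if (!length(q)) stop("shannon: all-zero vector")
  q <- q / sum(q)
  -sum(q * log(q))
}

#' Shannon evenness E = H' / ln S
#'
#' S is the number of positive entries; a single-species community has E = 0
#' by convention. E lies in [0, 1].
#'
#' @param p non-negative abundance vector.
#' @return evenness in [0, 1].
#' @export
evenness <- function(p) {
  s <- sum(p > 0)
  if (s <= 1) return(0)
  shannon(p) / log(s)
}

#' Per-sample alpha diversity for an abundance table
#'
#' Chao1 is computed on abundances scaled to counts per million and rounded
#' to integers (the profiler emits proportions, not reads); Shannon and
#' evenness are computed on the proportions directly.
#'
#' @param table relative-abundance [abundance_table()].
#' @return data.frame with sample_id, S_obs, F1, F2, chao1, shannon, evenness.
#' @export
alpha_diversity <- function(table) {
  v <- table$values
  per_sample <- function(i) {
    p <- v[i, ]
    cts <- round(p / sum(p) * 1e6)
    c(S_obs = sum(cts > 0), F1 = sum(cts == 1), F2 = sum(cts == 2),
      chao1 = chao1(cts), shannon = shannon(p), evenness = evenness(p))
  }
  res <- t(vapply(seq_len(nrow(v)), per_sample, numeric(6)))
  data.frame(sample_id = rownames(v), res, stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed (by default) on
#' square-root-transformed abundances. A pair of all-zero samples gets
#' distance 0 with a warning. Values lie in [0, 1]; Bray-Curtis is a
#' semimetric (no triangle inequality).
#'
#' @param table [abundance_table()] (or a bare non-negative matrix).
#' @param sqrt_transform square-root-transform abundances first (default TRUE).
#' @return a `dist` object.
#' @export
bray_curtis <- function(table, sqrt_transform = TRUE) {
  v <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  if (any(v < 0)) stop("bray_curtis: negative abundances")
  if (sqrt_transform) v <- sqrt(v)
  d <- suppressWarnings(vegan::vegdist(v, method = "bray"))
  if (anyNA(d)) {
    warning("bray_curtis: all-zero sample pair(s); defining their distance as 0")
    d[is.na(d)] <- 0
  }
  d
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions squared distances between and within groups:
#' SS_total = (1/n) sum_{i<j} d_ij^2, SS_within = sum_g (1/n_g)
#' sum_{i<j in g} d_ij^2, pseudo-F = ((SS_total - SS_within)/(g-1)) /
#' (SS_within/(n-g)). Significance by label permutation with the +1
#' correction: p = (1 + #{F_perm >= F_obs}) / (1 + n_perm). For two groups,
#' when the number of distinct label assignments is at most `n_perm` the
#' permutation distribution is enumerated exhaustively and
#' p = #{F >= F_obs} / #assignments (the observed assignment included).
#'
#' @param d `dist` object or square symmetric matrix.
#' @param groups group labels (>= 2 groups, each with >= 2 members).
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @return list of class `permanova_result`: pseudo_F, p_perm, n_perm,
#'   exhaustive flag, df_between, df_within, SS_total, SS_within, SS_between.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("permanova: labels do not match matrix order")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("permanova: need at least two groups")
  if (any(sizes < 2)) stop("permanova: singleton group")
  g <- length(sizes)
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within_for <- function(lab) {
    s <- 0
    for (lev in levels(groups)) {
      idx <- which(lab == lev)
      s <- s + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    s
  }
  f_stat <- function(ssw) ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  ssw_obs <- ss_within_for(groups)
  f_obs <- f_stat(ssw_obs)

  n_distinct <- if (g == 2) choose(n, sizes[[1]]) else Inf
  eps <- 1e-12
  if (is.finite(n_distinct) && n_distinct <= n_perm) {
    combs <- utils::combn(n, sizes[[1]])
    levs <- levels(groups)
    f_all <- apply(combs, 2, function(idx) {
      lab <- rep(levs[2], n); lab[idx] <- levs[1]
      f_stat(ss_within_for(factor(lab, levels = levs)))
    })
    p <- mean(f_all >= f_obs - eps)
    exhaustive <- TRUE
    n_perm_used <- length(f_all)
  } else {
    f_perm <- with_substream(seed, "permanova", {
      vapply(seq_len(n_perm), function(i) {
        f_stat(ss_within_for(sample(groups)))
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - eps)) / (1 + n_perm)
    exhaustive <- FALSE
    n_perm_used <- n_perm
  }
  structure(list(pseudo_F = f_obs, p_perm = p, n_perm = n_perm_used,
                 exhaustive = exhaustive, df_between = g - 1, df_within = n - g,
                 SS_total = ss_total, SS_within = ssw_obs,
                 SS_between = ss_total - ssw_obs),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g (%s%d permutations)\n",
              x$pseudo_F, x$df_between, x$df_within, x$p_perm,
              if (x$exhaustive) "exhaustive, " else "", x$n_perm))
  invisible(x)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Minimizes Kruskal stress-1 via monotone regression of configuration
#' distances on dissimilarity ranks (vegan's engine), keeping the best of
#' `n_restarts` random starts. Coordinates are centered and principal-axis
#' rotated.
#'
#' @param d `dist` object.
#' @param k target dimensionality (default 2).
#' @param n_restarts random restarts (default 50).
#' @param max_iter iterations per start (default 500).
#' @param tol convergence tolerance on stress (default 1e-6).
#' @param seed RNG seed.
#' @return list of class `ordination_result`: coordinates (n x k), stress
#'   (Kruskal stress-1 as a fraction), n_restarts, converged.
#' @export
nmds <- function(d, k = 2, n_restarts = 50, max_iter = 500, tol = 1e-6, seed = 1) {
  stopifnot(inherits(d, "dist"))
  fit <- with_substream(seed, "nmds", {
    suppressWarnings(  # metaMDS warns on near-zero stress; we report it instead
      vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                     maxit = max_iter, sfgrmin = 1e-7, sratmax = 1 - tol,
                     trace = 0, autotransform = FALSE, wascores = FALSE,
                     parallel = 1))
  })
  coords <- vegan::scores(fit, display = "sites")
  coords <- scale(coords, center = TRUE, scale = FALSE)
  pc <- prcomp(coords, center = FALSE)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("NMDS", seq_len(k))
  conv <- isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0) ||
    fit$stress < 1e-3
  if (!conv) warning("nmds: no convergent solution; returning best configuration")
  structure(list(coordinates = coords, stress = fit$stress,
                 n_restarts = n_restarts, converged = conv),
            class = "ordination_result")
}
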
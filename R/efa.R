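#' Exploratory factor analysis by principal-axis factoring
#'
#' Standardizes columns, extracts `k` factors by principal-axis factoring
#' with iterated communalities (initialized at squared multiple
#' correlations), applies the requested rotation (varimax by default), and
#' fixes signs so each factor's largest-|loading| indicator loads
#' positively. Heywood cases (communalities above 1) are clamped with a
#' warning. Per standardized feature, communality + uniqueness = 1.
#'
#' @param x numeric matrix or data.frame, participants x features.
#' @param k number of factors (>= 1).
#' @param rotation "varimax" or "none".
#' @param max_iter communality-iteration cap (default 200).
#' @param tol convergence tolerance on communalities (default 1e-6).
#' @return object of class `factor_solution`: loadings (features x k),
#'   uniquenesses, rotation, scores (Thurstone regression scores),
#'   variance_explained, indicator_map (argmax-|loading| factor per
#'   feature), and the correlation matrix used.
#' @export
efa_fit <- function(x, k, rotation = c("varimax", "none"),
                    max_iter = 200, tol = 1e-6) {
  rotation <- match.arg(rotation)
  x <- as.matrix(x)
  if (!is.numeric(k) || k < 1) stop("efa_fit: k must be >= 1")
  k <- as.integer(k)
  p <- ncol(x)
  if (k >= p) stop("efa_fit: k must be smaller than the number of features")
  if (any(apply(x, 2, stats::sd) == 0)) stop("efa_fit: constant feature")
  r <- stats::cor(x)
  # squared multiple correlations as starting communalities
  rinv <- tryCatch(solve(r), error = function(e) solve(r + diag(1e-6, p)))
  h2 <- pmin(pmax(1 - 1 / diag(rinv), 0.05), 0.995)
  lam <- NULL
  for (it in seq_len(max_iter)) {
    rr <- r
    diag(rr) <- h2
    eig <- eigen(rr, symmetric = TRUE)
    ev <- pmax(eig$values[seq_len(k)], 0)
    lam <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
    h2_new <- rowSums(lam^2)
    if (any(h2_new > 1)) {
      warning("efa_fit: Heywood case; clamping communalities")
      h2_new <- pmin(h2_new, 0.995)
    }
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) break
    if (it == max_iter)
      stop(sprintf("efa_fit: communalities did not converge in %d iterations (last delta %.2e)",
                   max_iter, delta))
  }
  if (rotation == "varimax" && k >= 2) {
    lam <- stats::varimax(lam)$loadings[, , drop = FALSE]
    lam <- matrix(as.numeric(lam), nrow = p, ncol = k)
  }
  # sign convention: the largest-|loading| entry of each factor is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(lam[, j]))
    if (lam[i, j] < 0) lam[, j] <- -lam[, j]
  }
  rownames(lam) <- colnames(x)
  colnames(lam) <- paste0("Factor", seq_len(k))
  h2 <- rowSums(lam^2)
  sol <- structure(list(
    loadings = lam,
    uniquenesses = stats::setNames(1 - h2, colnames(x)),
    rotation = rotation,
    correlation = r,
    variance_explained = colSums(lam^2) / p,
    indicator_map = stats::setNames(apply(abs(lam), 1, which.max), colnames(x)),
    scores = NULL), class = "factor_solution")
  sol$scores <- regression_scores(sol, x)
  sol
}

#' Thurstone regression factor scores
#'
#' F = Z R^-1 Lambda with Z the standardized data and R the sample
#' correlation matrix stored in the solution. When R is singular or
#' near-singular (reciprocal condition number below 1e-8, as happens when
#' the feature count approaches the sample size), the model-implied
#' correlation Lambda Lambda' + Psi is inverted instead — it is bounded away
#' from singularity by the uniquenesses and coincides with R when the model
#' fits; a plainly singular R additionally gets a 1e-6 ridge. Score columns
#' have mean zero.
#'
#' @param solution a `factor_solution`.
#' @param x data on the same feature set the solution was fitted to.
#' @return participants x k matrix of scores.
#' @export
regression_scores <- function(solution, x) {
  x <- as.matrix(x)
  stopifnot(identical(colnames(x), rownames(solution$loadings)))
  z <- scale(x)
  r <- solution$correlation
  lam <- solution$loadings
  if (rcond(r) < 1e-8) {
    warning("regression_scores: near-singular correlation matrix; using the model-implied correlation")
    r <- tcrossprod(lam) + diag(pmax(solution$uniquenesses, 5e-3))
  }
  w <- tryCatch(solve(r, lam), error = function(e) {
    warning("regression_scores: singular correlation matrix; ridge-regularizing")
    solve(r + diag(1e-6, nrow(r)), lam)
  })
  s <- z %*% w
  colnames(s) <- colnames(lam)
  rownames(s) <- rownames(x)
  s
}

#' The fixed three-block cytokine indicator assignment
#'
#' Factor 1: TNFa, IL4, IL12p70; Factor 2: CRP, IL18, MCP1; Factor 3: IL15,
#' IL33, IFNg, IL1b. Blocks are disjoint.
#'
#' @return named list of three character vectors.
#' @export
paper_biomarker_blocks <- function() {
  list(Factor1 = c("TNFa", "IL4", "IL12p70"),
       Factor2 = c("CRP", "IL18", "MCP1"),
       Factor3 = c("IL15", "IL33", "IFNg", "IL1b"))
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d features, %d factors (%s), variance explained %.1f%%\n",
              nrow(x$loadings), ncol(x$loadings), x$rotation,
              100 * sum(x$variance_explained)))
  invisible(x)
}
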
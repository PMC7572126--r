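# fast OLS coefficient via .lm.fit; design matrices are prebuilt once per call
ols_coef <- function(xm, y) .lm.fit(xm, y)$coefficients

#' Causal mediation analysis with nonparametric bootstrap
#'
#' Fits the two linear models M = a0 + a X + g'C + e1 and
#' Y = b0 + c' X + b M + d'C + e2 on complete cases, decomposes the
#' exposure effect as ACME = a b, ADE = c', Total = a b + c', and obtains
#' inference by resampling participants with replacement and refitting both
#' models. Intervals are percentile (2.5, 97.5 for `conf` = 0.95); the
#' bootstrap p-value is the symmetric two-sided tail
#' p = 2 min(mean(draws <= 0), mean(draws >= 0)), reported as < 2/n_boot
#' when a tail is empty. The proportion mediated is ACME*/Total* per draw
#' with its point estimate the median over draws; draws with Total* = 0 are
#' excluded and counted. In this linear no-interaction model
#' ACME + ADE = Total holds exactly in every draw.
#'
#' The mediator is used as supplied; for relative abundances, transform with
#' [log_offset()] first (compositional skew), or pass raw abundance to keep
#' the original scale.
#'
#' @param data data.frame.
#' @param exposure,mediator,outcome column names (numeric; binaries coded 0/1).
#' @param covariates character vector of adjustment covariates (factors allowed).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `mediation_result`.
#' @export
mediate <- function(data, exposure, mediator, outcome, covariates = character(),
                    n_boot = 1000, seed = 1, conf = 0.95) {
  cols <- c(exposure, mediator, outcome, covariates)
  stopifnot(all(cols %in% names(data)))
  dd <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(dd)
  if (n < 10 + length(covariates))
    stop("mediate: too few complete cases for the requested adjustment set")
  x <- dd[[exposure]]; m <- dd[[mediator]]; y <- dd[[outcome]]
  if (stats::var(x) == 0 || stats::var(m) == 0)
    stop("mediate: zero variance in exposure or mediator")
  cmat <- if (length(covariates))
    stats::model.matrix(~ ., dd[, covariates, drop = FALSE])[, -1, drop = FALSE]
  else matrix(0, n, 0)
  xm_m <- cbind(1, x, cmat)                 # mediator model design
  xm_y <- cbind(1, x, m, cmat)              # outcome model design

  point <- function(idx) {
    a <- ols_coef(xm_m[idx, , drop = FALSE], m[idx])[2]
    cf <- ols_coef(xm_y[idx, , drop = FALSE], y[idx])
    c(a = a, b = cf[3], cprime = cf[2])
  }
  est <- point(seq_len(n))
  acme0 <- est["a"] * est["b"]; ade0 <- est["cprime"]; tot0 <- acme0 + ade0

  draws <- with_substream(seed, "mediate", {
    vapply(seq_len(n_boot), function(i) {
      point(sample.int(n, n, replace = TRUE))
    }, numeric(3))
  })
  acme_s <- draws[1, ] * draws[2, ]
  ade_s <- draws[3, ]
  tot_s <- acme_s + ade_s
  nz <- abs(tot_s) > 1e-12
  prop_s <- acme_s[nz] / tot_s[nz]

  al <- (1 - conf) / 2
  summ <- function(pt, s) {
    p_lo <- mean(s <= 0); p_hi <- mean(s >= 0)
    pv <- 2 * min(p_lo, p_hi)
    list(point = unname(pt), lo = unname(stats::quantile(s, al)),
         hi = unname(stats::quantile(s, 1 - al)),
         p = if (pv == 0) 2 / n_boot else pv,
         p_is_bound = pv == 0)
  }
  structure(list(
    acme = summ(acme0, acme_s), ade = summ(ade0, ade_s),
    total = summ(tot0, tot_s),
    prop_mediated = {
      pm <- summ(stats::median(prop_s), prop_s)
      pm$n_excluded <- sum(!nz)
      pm
    },
    a_hat = unname(est["a"]), b_hat = unname(est["b"]),
    c_prime_hat = unname(est["cprime"]),
    draws = rbind(acme = acme_s, ade = ade_s, total = tot_s),
    n_boot = n_boot, seed = seed, conf = conf,
    adjustment_set = covariates, n_used = n), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(lbl, s) sprintf("  %-14s %8.4f [%8.4f, %8.4f]  p %s%.4g",
                                  lbl, s$point, s$lo, s$hi,
                                  if (isTRUE(s$p_is_bound)) "< " else "", s$p)
  cat(sprintf("Mediation (n = %d, %d bootstrap draws, adjusted for: %s)\n",
              x$n_used, x$n_boot,
              if (length(x$adjustment_set)) paste(x$adjustment_set, collapse = ", ")
              else "nothing"))
  cat(fmt("ACME", x$acme), "\n")
  cat(fmt("ADE", x$ade), "\n")
  cat(fmt("Total", x$total), "\n")
  cat(fmt("Prop. mediated", x$prop_mediated), "\n")
  invisible(x)
}

#' Mediation under the standard adjustment-set ladder
#'
#' Runs [mediate()] under four adjustment sets sharing one seed: unadjusted,
#' age-adjusted, age + island, and the multivariate set (age, BMI, gender,
#' smoking, fruit, vegetables, takeaway, seafood, alcohol). Rungs whose
#' covariates are missing from the data are skipped with a message.
#'
#' @param data data.frame.
#' @param exposure,mediator,outcome column names.
#' @param n_boot,seed,conf passed to [mediate()].
#' @param multivariate_set covariates of the widest rung.
#' @return named list of `mediation_result` (unadjusted, age, age_island,
#'   multivariate).
#' @export
mediation_ladder <- function(data, exposure, mediator, outcome,
                             n_boot = 1000, seed = 1, conf = 0.95,
                             multivariate_set = c("age", "bmi", "gender",
                                                  "smoking", "fruit", "vegetables",
                                                  "takeaway", "seafood", "alcohol")) {
  rungs <- list(unadjusted = character(),
                age = "age",
                age_island = c("age", "island"),
                multivariate = multivariate_set)
  out <- list()
  for (nm in names(rungs)) {
    cv <- rungs[[nm]]
    if (!all(cv %in% names(data))) {
      message(sprintf("mediation_ladder: skipping '%s' rung (missing: %s)", nm,
                      paste(setdiff(cv, names(data)), collapse = ", ")))
      next
    }
    out[[nm]] <- mediate(data, exposure, mediator, outcome, covariates = cv,
                         n_boot = n_boot, seed = seed, conf = conf)
  }
  out
}
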
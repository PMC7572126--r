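make_table <- function(v) {
  dimnames(v) <- list(sprintf("s%02d", seq_len(nrow(v))),
                      sprintf("f%02d", seq_len(ncol(v))))
  abundance_table(v, "species")
}

test_that("per-million normalization scales rows and rejects empty samples", {
  at <- make_table(rbind(c(0.2, 0.8), c(0.5, 0.5)))
  pm <- normalize_per_million(at)
  expect_equal(unname(pm$values[1, ]), c(2e5, 8e5))
  expect_true(all(abs(rowSums(pm$values) - 1e6) < 1e-3))
  expect_identical(normalize_per_million(pm)$values, pm$values)
  expect_error(normalize_per_million(make_table(rbind(c(0, 0), c(1, 1)))),
               "all-zero sample")
})

test_that("two-class KW gate agrees with the rank-sum test and handles constants", {
  set.seed(21)
  cl <- rep(c("a", "b"), each = 10)
  v <- cbind(matrix(rgamma(20 * 19, 2), 20), const = 1)
  at <- make_table(v)
  gate <- kw_gate(at, cl)
  for (j in 1:19) {
    p_wil <- kruskal.test(v[, j], factor(cl))$p.value
    expect_equal(gate$kw_p[j], p_wil, tolerance = 1e-12)
    # rank-sum equivalence: KW chi-square p == normal-approx Wilcoxon p
    w <- suppressWarnings(wilcox.test(v[1:10, j], v[11:20, j],
                                      exact = FALSE, correct = FALSE))
    expect_equal(gate$kw_p[j], w$p.value, tolerance = 1e-9)
  }
  expect_equal(gate$kw_p[20], 1)
  expect_false(gate$retained[20])
})

test_that("a planted 10-fold shift is decisively gated in", {
  set.seed(22)
  cl <- rep(c("a", "b"), each = 50)
  x <- c(rlnorm(50, log(10)), rlnorm(50, log(1)))
  at <- make_table(cbind(x, rlnorm(100)))
  gate <- kw_gate(at, cl)
  expect_lt(gate$kw_p[1], 1e-6)
})

test_that("single-feature LDA effect size matches the closed form", {
  # one feature: the unit discriminant is +-1, so the raw effect per round is
  # |mean difference| and the score is log10(1 + mean |diff| over rounds).
  set.seed(23)
  cl <- factor(rep(c("a", "b"), each = 12))
  x <- c(rnorm(12, 1000, 10), rnorm(12, 3000, 10))
  at <- make_table(matrix(x, ncol = 1))
  res <- lda_effect_size(at, cl, n_boot = 50, seed = 9)
  # independent closed-form oracle replaying the same subsampling scheme
  oracle <- withr::with_seed(miomed::substream_seed(9, "lefse-lda"), {
    idx0 <- 1:12; idx1 <- 13:24
    m <- max(2L, floor(2 / 3 * 12))
    effs <- replicate(50, {
      s0 <- sample(idx0, m, replace = TRUE)
      s1 <- sample(idx1, m, replace = TRUE)
      abs(mean(x[s1]) - mean(x[s0]))
    })
    log10(1 + mean(effs))
  })
  expect_equal(res$lda_score, oracle, tolerance = 1e-10)
  expect_equal(res$enriched_class, "b")
})

test_that("identical class distributions score zero; planted shift scores >= 3", {
  cl <- rep(c("a", "b"), each = 20)
  same <- rep(5e5, 40)      # identical (degenerate) distribution in both classes
  set.seed(24)
  planted <- c(rnorm(20, 5e5, 2e4), rnorm(20, 5e4, 5e3))
  filler <- rep(2e5, 40)
  at <- make_table(cbind(same, planted, filler))
  res <- lda_effect_size(at, cl, n_boot = 30, seed = 2)
  expect_equal(res$lda_score[res$feature == "f01"], 0)
  expect_gte(res$lda_score[res$feature == "f02"], 3)
})

test_that("lefse composes the gates, sorts by score, and is seed-deterministic", {
  set.seed(25)
  cl <- rep(c("a", "b"), each = 25)
  v <- matrix(rlnorm(50 * 10, log(0.05), 0.3), 50, 10)
  v[1:25, 1] <- v[1:25, 1] * 12     # enriched in class a
  v <- v / rowSums(v)
  at <- make_table(v)
  r1 <- lefse(at, cl, seed = 5)
  r2 <- lefse(at, cl, seed = 5)
  expect_identical(r1, r2)
  expect_true(r1$passed[r1$feature == "f01"])
  expect_identical(r1$enriched_class[r1$feature == "f01"], "a")
  # passed requires both gates
  expect_true(all(r1$kw_p[r1$passed] <= 0.05))
  expect_true(all(r1$lda_score[r1$passed] >= 3))
  # sorted by score descending within class
  for (cls in unique(stats::na.omit(r1$enriched_class))) {
    s <- r1$lda_score[!is.na(r1$enriched_class) & r1$enriched_class == cls]
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("scores are invariant to feature and sample order", {
  set.seed(26)
  cl <- rep(c("a", "b"), each = 15)
  v <- matrix(rlnorm(30 * 6, log(1e5), 0.4), 30, 6)
  at <- make_table(v)
  r1 <- lda_effect_size(at, cl, n_boot = 20, seed = 3)
  perm_f <- sample(6); perm_s <- sample(30)
  at2 <- abundance_table(at$values[perm_s, perm_f, drop = FALSE], "species")
  r2 <- lda_effect_size(at2, cl[perm_s], n_boot = 20, seed = 3)
  m <- match(r1$feature, r2$feature)
  expect_equal(r1$lda_score, r2$lda_score[m], tolerance = 1e-12)
})

test_that("scaling a planted difference upward never decreases the score", {
  cl <- rep(c("a", "b"), each = 15)
  base <- rep(1e5, 30)
  scores <- vapply(c(0, 1e3, 1e4, 1e5, 4e5), function(delta) {
    x <- base; x[16:30] <- x[16:30] + delta
    at <- make_table(cbind(x, rep(2e5, 30)))
    lda_effect_size(at, cl, n_boot = 10, seed = 7)$lda_score[1]
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
})
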
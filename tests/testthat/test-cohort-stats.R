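test_that("two-group ANOVA F equals the squared t statistic", {
  set.seed(71)
  df <- data.frame(participant_id = 1:40, g = rep(c("a", "b"), 20),
                   age = rnorm(40, 45, 10), y = rnorm(40))
  out <- table1_compare(df, "y", group = "g")
  tt <- t.test(y ~ g, df, var.equal = TRUE)
  av <- anova(lm(y ~ g, df))
  expect_equal(av$F[1], tt$statistic[[1]]^2, tolerance = 1e-10)
  expect_equal(out$p_unadjusted, av[["Pr(>F)"]][1], tolerance = 1e-12)
  expect_equal(out$p_unadjusted, tt$p.value, tolerance = 1e-12)
})

test_that("a group shift fully explained by age vanishes under ANCOVA", {
  set.seed(72)
  n <- 2000
  g <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 40, 10) + ifelse(g == "b", 10, 0)
  y <- 0.5 * age + rnorm(n)          # group shift = 0.5 * delta-age
  df <- data.frame(participant_id = seq_len(n), g = g, age = age, y = y)
  out <- table1_compare(df, "y", group = "g")
  expect_lt(out$p_unadjusted, 1e-10)
  expect_gt(out$p_adjusted, 0.05)
  # medians are reported on the untransformed scale even when testing logs
  df$z <- exp(y / 20)
  out2 <- table1_compare(df, "z", group = "g", log_vars = "z")
  expect_equal(out2$median1, median(df$z[df$g == "a"]), tolerance = 1e-12)
  expect_true(out2$transformed)
  # constant variables are flagged with p = 1
  df$k <- 5
  out3 <- table1_compare(df, "k", group = "g")
  expect_equal(out3$p_unadjusted, 1)
  expect_match(out3$note, "constant")
})

test_that("spearman screen: monotone transform, thresholds, rank oracle", {
  set.seed(73)
  n <- 60
  x <- rnorm(n)
  bm <- cbind(b1 = x^3, b2 = rnorm(n))              # b1 monotone in x
  ft <- cbind(f1 = x + rnorm(n, 0, 0.2), f2 = rnorm(n))
  out <- spearman_screen(bm, ft)
  r11 <- out[out$biomarker == "b1" & out$feature == "f1", ]
  expect_gt(r11$rho, 0.9)
  expect_true(r11$passed)
  # exact rho = 1 for y = x^3 against x itself
  out2 <- spearman_screen(cbind(b = x^3), cbind(f = x))
  expect_equal(out2$rho, 1)
  # rho below 0.3 never passes, whatever its q
  expect_true(all(!out$passed[abs(out$rho) < 0.3]))
  # tie-free rho equals Pearson on ranks
  r_oracle <- cor(rank(bm[, "b1"]), rank(ft[, "f2"]))
  expect_equal(out$rho[out$biomarker == "b1" & out$feature == "f2"],
               r_oracle, tolerance = 1e-10)
  # constant vector flagged, not tested
  out3 <- spearman_screen(cbind(b = rep(1, n)), cbind(f = x))
  expect_true(is.na(out3$rho))
  expect_match(out3$note, "constant")
})

test_that("pathway comparison: null CI straddles 0, planted shift found, U oracle", {
  set.seed(74)
  n <- 100
  g <- rep(c("w", "m"), each = n / 2)
  v <- matrix(rlnorm(n * 12, log(0.08), 0.3), n, 12)
  v[g == "m", 1] <- v[g == "m", 1] * 2           # planted 2x pathway
  v <- v / rowSums(v)
  dimnames(v) <- list(paste0("s", 1:n), sprintf("PWY-%02d", 1:12))
  at <- abundance_table(v, "pathway")
  res <- pathway_compare(at, g, n_boot = 500, seed = 4)
  expect_lt(res$q[1], 0.05)
  # genuinely identical group distributions: effect CIs straddle 0
  v0 <- matrix(rlnorm(n * 12, log(0.08), 0.3), n, 12)
  v0 <- v0 / rowSums(v0)
  dimnames(v0) <- dimnames(v)
  res0 <- pathway_compare(abundance_table(v0, "pathway"), g,
                          n_boot = 500, seed = 5)
  expect_gt(mean(res0$effect_lo <= 0 & res0$effect_hi >= 0), 0.7)
  # Mann-Whitney U equals brute-force pair counting at small n
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  y <- c(2.0, 4.4, 3.9, 1.1)
  u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(wilcox.test(x, y)$statistic), u_brute)
})

test_that("stratified comparison applies the either-group 80% presence rule", {
  set.seed(75)
  n <- 40
  g <- rep(c("w", "m"), each = n / 2)
  mk <- function(p1, p2) {
    x <- numeric(n)
    x[1:20] <- rbinom(20, 1, p1) * rlnorm(20)
    x[21:40] <- rbinom(20, 1, p2) * rlnorm(20)
    x
  }
  # deterministic prevalence grid via exact counts
  col <- function(k1, k2) c(rep(1, k1), rep(0, 20 - k1), rep(1, k2), rep(0, 20 - k2)) * rlnorm(n)
  v <- cbind(hi_w = col(18, 2), hi_m = col(2, 17), lo_both = col(14, 14),
             hi_both = col(20, 19))
  rownames(v) <- paste0("s", 1:n)
  at <- abundance_table(v, "stratified-pathway")
  attr(at, "pathway") <- rep("PWY-1", 4); attr(at, "taxon") <- colnames(v)
  res <- stratified_pathway_compare(at, g, presence_floor = 0.8)
  expect_true(res$retained[res$feature == "hi_w"])    # 90% in one group
  expect_true(res$retained[res$feature == "hi_m"])    # 85% in the other
  expect_false(res$retained[res$feature == "lo_both"])# 70% in both
  expect_true(res$retained[res$feature == "hi_both"])
  expect_true(all(is.na(res$p[!res$retained])))
  # survivor set equals the brute-force rule
  brute <- apply(v > 0, 2, function(z) mean(z[1:20]) >= 0.8 || mean(z[21:40]) >= 0.8)
  expect_identical(res$retained, unname(brute))
})

test_that("bootstrap effect CI attains near-nominal coverage", {
  set.seed(76)
  true_diff <- 0.02
  covered <- replicate(60, {
    g <- rep(c("a", "b"), each = 50)   # effect = mean(b) - mean(a)
    x <- c(rnorm(50, 0.10, 0.03), rnorm(50, 0.10 + true_diff, 0.03))
    at <- abundance_table(matrix(pmax(x, 1e-6), ncol = 1,
                                 dimnames = list(paste0("s", 1:100), "PWY-1")),
                          "pathway")
    r <- pathway_compare(at, g, n_boot = 300, seed = sample.int(1e6, 1))
    r$effect_lo <= true_diff && r$effect_hi >= true_diff
  })
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 1.0)
})
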
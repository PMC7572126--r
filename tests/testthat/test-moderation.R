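test_that("bh_fdr matches the hand example and the brute-force definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  set.seed(61)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  # q >= p always
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p - 1e-15))
})

test_that("presence matrix thresholds strictly", {
  m <- matrix(c(0, 1e-6, 5e-5, 2e-4), 2, 2,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  at <- abundance_table(m, "species")
  p0 <- presence_matrix(at)
  expect_equal(as.vector(p0), c(0L, 1L, 1L, 1L))
  p4 <- presence_matrix(at, threshold = 1e-4)
  expect_equal(as.vector(p4), c(0L, 0L, 0L, 1L))
})

test_that("interaction coefficient equals the 2x2 cell-means contrast exactly", {
  # hand-built cell means: mu00=100, mu01=105, mu10=110, mu11=103
  cells <- expand.grid(g = c(0, 1), pr = c(0, 1))
  mu <- c(`0.0` = 100, `1.0` = 110, `0.1` = 105, `1.1` = 103)
  d <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(g = cells$g[i], pr = cells$pr[i],
               y = mu[paste(cells$g[i], cells$pr[i], sep = ".")] + c(-1, 0, 1, 2))
  }))
  pres <- matrix(d$pr, ncol = 1, dimnames = list(NULL, "tax1"))
  scan <- interaction_scan(d$y, d$g, pres, cell_min = 2)
  beta_expected <- (mu["1.1"] - mu["1.0"]) - (mu["0.1"] - mu["0.0"])  # -12
  expect_equal(scan$beta_interaction, unname(beta_expected), tolerance = 1e-10)
  # invariance up to sign under group-label swap
  scan2 <- interaction_scan(d$y, 1 - d$g, pres, cell_min = 2)
  expect_equal(scan2$beta_interaction, -scan$beta_interaction, tolerance = 1e-10)
})

test_that("degenerate and window-violating taxa are skipped without estimates", {
  set.seed(62)
  n <- 60
  g <- rep(0:1, each = 30)
  pres <- cbind(all_present = rep(1L, n),
                rare = c(rep(1L, 3), rep(0L, n - 3)),
                tiny_cell = c(rep(1L, 2), rep(0L, 28), rep(1L, 15), rep(0L, 15)),
                good = rbinom(n, 1, 0.5))
  y <- rnorm(n, 120, 10)
  scan <- interaction_scan(y, g, pres)
  expect_true(scan$skipped[scan$taxon == "all_present"])
  expect_match(scan$skip_reason[scan$taxon == "all_present"], "degenerate")
  expect_true(scan$skipped[scan$taxon == "rare"])
  expect_false(scan$skipped[scan$taxon == "good"])
  expect_true(is.na(scan$beta_interaction[scan$taxon == "rare"]))
  # skipping does not alter tested estimates, and BH runs over tested only
  scan_good_only <- interaction_scan(y, g, pres[, "good", drop = FALSE])
  expect_equal(scan$beta_interaction[scan$taxon == "good"],
               scan_good_only$beta_interaction, tolerance = 1e-12)
  expect_equal(scan$q[scan$taxon == "good"], scan$p[scan$taxon == "good"])
})

test_that("a planted interaction is detected among nulls at n = 500", {
  set.seed(63)
  n <- 500
  g <- rep(0:1, each = n / 2)
  n_taxa <- 70
  pres <- matrix(rbinom(n * n_taxa, 1, 0.6), n, n_taxa,
                 dimnames = list(NULL, paste0("t", seq_len(n_taxa))))
  y <- 120 + 3 * g + 8 * g * (1 - pres[, 1]) + rnorm(n, 0, 10)
  scan <- interaction_scan(y, g, pres)
  expect_lt(scan$q[1], 0.05)
  expect_gte(mean(scan$q[-1] >= 0.05, na.rm = TRUE), 0.95)
})

test_that("under a global null few taxa reach q < 0.05", {
  set.seed(64)
  rates <- replicate(10, {
    n <- 200
    g <- rep(0:1, each = n / 2)
    pres <- matrix(rbinom(n * 40, 1, 0.5), n, 40,
                   dimnames = list(NULL, paste0("t", 1:40)))
    y <- rnorm(n, 120, 10)
    scan <- interaction_scan(y, g, pres)
    mean(scan$q < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(rates), 0.05)
})

test_that("the moderation ladder shares cell counts across rungs", {
  st <- small_study()
  cohort <- st$cohort
  pres <- presence_matrix(st$microbiome)
  lad <- scan_ladder(cohort, "sbp", "island", pres,
                     taxa = st$params$moderator)
  rungs <- lad[[st$params$moderator]]
  expect_setequal(names(rungs), c("unadjusted", "age", "multivariate"))
  counts <- lapply(rungs, function(r) r$cell_means$n)
  expect_identical(counts$unadjusted, counts$age)
  expect_identical(counts$unadjusted, counts$multivariate)
  expect_equal(sum(rungs$unadjusted$cell_means$n), nrow(cohort))
})
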
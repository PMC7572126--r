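test_that("chao1 matches its closed form and conventions", {
  expect_equal(chao1(c(5, 3, 2, 1, 1)), 5.5)
  expect_equal(chao1(c(5, 3, 2)), 3)              # no singletons -> S_obs
  expect_equal(chao1(c(5, 3, 2, 1, 1, 0)), 5.5)   # zero-count species inert
  expect_error(chao1(c(1.5, 2)), "non-integer")
  expect_gte(chao1(c(1, 1, 1)), 3)                # never below S_obs
})

test_that("shannon and evenness match closed forms", {
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(evenness(rep(0.25, 4)), 1)
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(evenness(c(1, 0, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "all-zero")
  # E in [0,1] on random compositions
  set.seed(1)
  for (i in 1:20) {
    p <- rgamma(10, 1); p <- p / sum(p)
    expect_true(evenness(p) >= 0 && evenness(p) <= 1)
  }
})

test_that("bray-curtis matches hand values and vegan, stays in [0,1]", {
  m <- rbind(a = c(1, 0), b = c(0.5, 0.5))
  d <- bray_curtis(m, sqrt_transform = FALSE)
  expect_equal(as.numeric(d), 0.5)
  m2 <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  d2 <- as.matrix(bray_curtis(m2, sqrt_transform = FALSE))
  expect_equal(d2["a", "b"], 1)   # disjoint supports
  expect_equal(d2["a", "c"], 0)   # identical samples
  st <- small_study()
  d3 <- bray_curtis(st$microbiome)
  expect_true(all(d3 >= 0 & d3 <= 1))
  # cross-check the sqrt-transform path against vegan directly
  expect_equal(as.numeric(d3),
               as.numeric(vegan::vegdist(sqrt(st$microbiome$values), "bray")))
  expect_warning(bray_curtis(rbind(a = c(0, 0), b = c(0, 0)),
                             sqrt_transform = FALSE), "all-zero")
})

test_that("permanova equals exhaustive enumeration and matches vegan's pseudo-F", {
  set.seed(7)
  pts <- matrix(rnorm(16), 8, 2)
  rownames(pts) <- paste0("s", 1:8)
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 4)
  res <- permanova(d, g, n_perm = 9999, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$p_perm, permanova_brute_p(d, g))
  # pseudo-F cross-check against the independent vegan implementation
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$df_between + res$df_within, 7)
  # clearly separated groups attain the minimal p
  pts2 <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  res2 <- permanova(dist(pts2), g, n_perm = 9999, seed = 1)
  expect_equal(res2$p_perm, 2 / 70)  # observed split and its mirror
  expect_error(permanova(d, c("a", rep("b", 7)), 99), "singleton")
})

test_that("permanova p is uniform under an exchangeable null", {
  set.seed(11)
  ps <- replicate(200, {
    pts <- matrix(rnorm(30), 15, 2)
    g <- sample(rep(c("a", "b"), c(7, 8)))
    permanova(dist(pts), g, n_perm = 199, seed = sample.int(1e6, 1))$p_perm
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("permanova invariant under consistent relabeling/permutation", {
  set.seed(3)
  pts <- matrix(rnorm(24), 12, 2)
  g <- rep(c("a", "b"), each = 6)
  d <- dist(pts)
  perm <- sample(12)
  d2 <- as.matrix(d)[perm, perm]
  r1 <- permanova(d, g, n_perm = 99, seed = 1)
  r2 <- permanova(as.dist(d2), g[perm], n_perm = 99, seed = 1)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-12)
})

test_that("nmds recovers known geometry and stress decreases in k", {
  # 4 points at the corners of a unit square
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rownames(sq) <- paste0("p", 1:4)
  d <- dist(sq)
  res <- nmds(d, k = 2, n_restarts = 20, seed = 4)
  expect_lt(res$stress, 1e-3)
  pro <- vegan::procrustes(sq, res$coordinates, scale = TRUE)
  expect_lt(pro$ss / sum(scale(sq, scale = FALSE)^2), 1e-2)
  # larger example: stress(k=3) <= stress(k=2)
  set.seed(5)
  pts <- matrix(rnorm(60), 20, 3)
  d2 <- dist(pts)
  s2 <- nmds(d2, k = 2, n_restarts = 10, seed = 1)$stress
  s3 <- nmds(d2, k = 3, n_restarts = 10, seed = 1)$stress
  expect_lte(s3, s2 + 1e-6)
})
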
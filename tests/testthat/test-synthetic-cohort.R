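test_that("cohort generation is deterministic in the seed and refuses tiny n", {
  a <- generate_cohort(100, seed = 1)
  b <- generate_cohort(100, seed = 1)
  expect_identical(a, b)
  c2 <- generate_cohort(100, seed = 2)
  expect_false(identical(a$ssb, c2$ssb))
  expect_error(generate_cohort(10, seed = 1), "n must be >= 20")
})

test_that("planted island age shift is recovered at large n", {
  ch <- generate_cohort(6000, seed = 7)
  gt <- ground_truth_default()
  # oracle: ages are normals truncated at 15, so the expected island
  # difference is the truncated-normal mean difference, not the raw shift
  tmean <- function(mu, sd, lo = 15) {
    a <- (lo - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a))
  }
  expected <- tmean(gt$age_mean_waiben + gt$age_shift_mer, gt$age_sd) -
    tmean(gt$age_mean_waiben, gt$age_sd)
  observed <- mean(ch$age[ch$island == "Mer"]) - mean(ch$age[ch$island == "Waiben"])
  expect_lt(abs(observed - expected), 1)
  expect_true(all(ch$age >= 15))
  expect_equal(unname(table(ch$island)), c(3000, 3000), ignore_attr = TRUE)
})

test_that("microbiome rows are compositions and structural zeros behave", {
  st <- small_study()
  v <- st$microbiome$values
  expect_true(all(abs(rowSums(v) - 1) < 1e-9))
  expect_true(all(v >= 0))
  gt <- st$params
  pres <- attr(st$microbiome, "moderator_present")
  expect_true(all(v[pres == 0, gt$moderator] == 0))
  expect_true(all(v[, gt$mediator] > 0))
})

test_that("planted exposure->mediator path is recovered by OLS at n = 2000", {
  gt <- ground_truth_default()
  ch <- generate_cohort(2000, seed = 11)
  mb <- generate_microbiome(ch, seed = 11, params = gt)
  lm_fit <- lm(log(mb$values[, gt$mediator]) ~ ch$ssb)
  expect_lt(abs(coef(lm_fit)[2] - gt$a_path), 0.05)
})

test_that("a_path = 0 leaves exposure and mediator uncorrelated", {
  gt <- ground_truth_default()
  gt$a_path <- 0
  ch <- generate_cohort(2000, seed = 5)
  mb <- generate_microbiome(ch, seed = 5, params = gt)
  rho <- cor(ch$ssb, log(mb$values[, gt$mediator]), method = "spearman")
  expect_lt(abs(rho), 0.06)
})

test_that("biomarker blocks correlate within more than across and are positive", {
  gt <- ground_truth_default()
  ch <- generate_cohort(2000, seed = 13)
  mb <- generate_microbiome(ch, seed = 13, params = gt)
  ch <- generate_biomarkers(ch, mb, seed = 13, params = gt)
  blocks <- gt$biomarker_blocks
  bm <- log(as.matrix(ch[, unlist(blocks)]))
  r <- cor(bm)
  within <- unlist(lapply(blocks, function(b) {
    rr <- r[b, b]; rr[upper.tri(rr)]
  }))
  across <- c(r[blocks[[1]], blocks[[2]]], r[blocks[[1]], blocks[[3]]])
  expect_gt(mean(within), mean(across) + 0.2)
  expect_true(all(as.matrix(ch[, unlist(blocks)]) > 0))
})

test_that("b_path = 0 removes the mediator-IL15 partial association", {
  gt <- ground_truth_default()
  gt$b_path <- 0; gt$c_prime <- 0
  ch <- generate_cohort(1500, seed = 17)
  mb <- generate_microbiome(ch, seed = 17, params = gt)
  ch <- generate_biomarkers(ch, mb, seed = 17, params = gt)
  r <- cor(log(ch$IL15), log(mb$values[, gt$mediator]))
  expect_lt(abs(r), 0.08)
})

test_that("planted moderation contrast matches theta and MAP follows its formula", {
  gt <- ground_truth_default()
  ch <- generate_cohort(500, seed = 23)
  mb <- generate_microbiome(ch, seed = 23, params = gt)
  ch <- generate_biomarkers(ch, mb, seed = 23, params = gt)
  ch <- generate_outcomes(ch, mb, seed = 23, params = gt)
  expect_equal(ch$map, (ch$sbp + 2 * ch$dbp) / 3, tolerance = 1e-12)
  expect_true(all(ch$sbp >= ch$dbp))
  pres <- attr(mb, "moderator_present")
  mer <- ch$island == "Mer"
  # age differs between islands, so contrast on the age-detrended scale
  sbp_res <- ch$sbp - 0.45 * ch$age
  contrast <- mean(sbp_res[mer & pres == 0]) - mean(sbp_res[mer & pres == 1])
  expect_lt(abs(contrast - gt$theta_interaction), 1.5)
})

test_that("fixture set round-trips through the dialect readers", {
  st <- small_study()
  outdir <- withr::local_tempdir()
  paths <- write_fixture_set(st, outdir)
  expect_true(all(file.exists(paths)))
  sp <- read_metaphlan_table(paths[["species"]])
  expect_equal(sp$values, st$microbiome$values, tolerance = 1e-12)
  expect_identical(unname(sp$taxonomy), unname(st$microbiome$taxonomy))
  meta <- read_cohort_csv(paths[["metadata"]])
  expect_equal(meta$sbp, st$cohort$sbp)
  pw <- read_humann_pathways(paths[["pathways"]])
  expect_equal(pw$community$values, st$pathways$community$values, tolerance = 1e-12)
  man <- jsonlite::read_json(paths[["manifest"]])
  for (fld in c("a_path", "b_path", "c_prime", "theta_interaction", "p_present"))
    expect_equal(man[[fld]], st$params[[fld]])
})
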
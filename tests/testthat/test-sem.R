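gen_chain <- function(n, beta = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- beta * x + rnorm(n)
  y <- beta * m + rnorm(n)
  data.frame(x = x, m = m, y = y)
}

chain_model <- path_model(c("x", "m", "y"),
                          data.frame(from = c("x", "m"), to = c("m", "y")),
                          exogenous = "x")
saturated_model <- path_model(c("x", "m", "y"),
                              data.frame(from = c("x", "x", "m"),
                                         to = c("m", "y", "y")),
                              exogenous = "x")

test_that("path_model validates its graph", {
  expect_error(path_model(c("a", "b"), data.frame(from = "a", to = "a")),
               "self-loop")
  expect_error(path_model(c("a", "b"), data.frame(from = "a", to = "c")),
               "not in variables")
  expect_error(path_model(c("a", "b"), data.frame(from = "b", to = "a"),
                          exogenous = "a"), "incoming edge")
})

test_that("saturated model fits perfectly: T ~ 0, df = 0, CFI 1, SRMR ~ 0", {
  d <- gen_chain(400, seed = 41)
  f <- suppressWarnings(sem_fit(d, saturated_model))
  expect_lt(abs(f$T), 1e-6)
  expect_equal(f$df, 0)
  expect_equal(unname(f$CFI), 1)
  expect_lt(unname(f$SRMR), 1e-6)
  expect_equal(unname(f$RMSEA), 0)
  expect_true(f$converged)
})

test_that("chain-model parameters are recovered at n = 5000 with adequate fit", {
  d <- gen_chain(5000, beta = 0.5, seed = 42)
  f <- sem_fit(d, chain_model)
  expect_true(all(abs(f$estimates$beta - 0.5) < 0.05))
  expect_gt(f$p_chi2, 0.05)
  expect_gt(unname(f$CFI), 0.8)
  expect_lt(unname(f$SRMR), 0.08)
  expect_lt(unname(f$RMSEA), 0.05)
})

test_that("sandwich SEs agree with nonparametric-bootstrap SEs within 15%", {
  d <- gen_chain(1000, seed = 43)
  f <- sem_fit(d, chain_model)
  set.seed(99)
  boots <- replicate(200, {
    idx <- sample.int(nrow(d), replace = TRUE)
    sem_fit(d[idx, ], chain_model)$estimates$beta
  })
  se_boot <- apply(boots, 1, sd)
  expect_true(all(abs(f$estimates$se_robust - se_boot) / se_boot < 0.15))
})

test_that("SRMR and CFI formulas match hand-worked values", {
  s <- matrix(c(1, 0.5, 0.5, 1), 2)
  # model-implied identity: the only nonzero standardized residual is 0.5
  fi <- fit_indices(10, 1, 50, 1, 100, s, diag(2))
  expect_equal(unname(fi["SRMR"]), sqrt(0.25 / 3), tolerance = 1e-6)
  # Sigma = S exactly
  fi2 <- fit_indices(0, 1, 50, 1, 100, s, s)
  expect_equal(unname(fi2["CFI"]), 1)
  expect_equal(unname(fi2["SRMR"]), 0)
  expect_equal(unname(fi2["RMSEA"]), 0)
  # the independence model evaluated as itself has CFI 0
  fi3 <- fit_indices(50, 1, 50, 1, 100, s, diag(2))
  expect_equal(unname(fi3["CFI"]), 0)
})

test_that("nested models never fit better: T_nested >= T_fuller", {
  d <- gen_chain(300, seed = 44)
  f_full <- suppressWarnings(sem_fit(d, saturated_model))
  f_nest <- sem_fit(d, chain_model)
  expect_gte(f_nest$T, f_full$T - 1e-8)
})

test_that("standardized coefficients are invariant to rescaling a variable", {
  d <- gen_chain(500, seed = 45)
  f1 <- sem_fit(d, chain_model)
  d2 <- d; d2$m <- d2$m * 37.5
  f2 <- sem_fit(d2, chain_model)
  expect_equal(f1$estimates$beta_std, f2$estimates$beta_std, tolerance = 1e-6)
})

test_that("framework comparison recovers the generating framework and is order-invariant", {
  gen_fw1 <- function(n, seed) {
    set.seed(seed)
    e <- rnorm(n)
    m1 <- 0.5 * e + rnorm(n); m2 <- -0.4 * e + rnorm(n)
    b1 <- 0.5 * m1 + 0.3 * e + rnorm(n); b2 <- 0.4 * m2 + rnorm(n)
    data.frame(E = e, M1 = m1, M2 = m2, B1 = b1, B2 = b2)
  }
  d <- gen_fw1(500, 46)
  cmp <- compare_frameworks(d, "E", c("M1", "M2"), c("B1", "B2"))
  expect_equal(cmp$best, 1)
  expect_true(all(cmp$report$converged))
  # ranking invariant to column order of the data
  d2 <- d[, c("B2", "M1", "E", "B1", "M2")]
  cmp2 <- compare_frameworks(d2, "E", c("M1", "M2"), c("B1", "B2"))
  expect_equal(cmp$report$AIC[order(cmp$report$framework)],
               cmp2$report$AIC[order(cmp2$report$framework)], tolerance = 1e-6)
  # pure noise: all structural paths near zero
  set.seed(47)
  dn <- as.data.frame(matrix(rnorm(500 * 5), 500, 5))
  names(dn) <- c("E", "M1", "M2", "B1", "B2")
  cmpn <- compare_frameworks(dn, "E", c("M1", "M2"), c("B1", "B2"))
  f1 <- cmpn$fits[[1]]
  expect_true(all(abs(f1$estimates$beta) < 0.15))
})
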
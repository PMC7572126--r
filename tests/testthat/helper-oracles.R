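# Shared fixtures and independent oracles for the test suite.

# simple linear mediation generator: X -> M -> Y with direct path
gen_mediation_data <- function(n, a = 0.5, b = 0.4, cprime = 0.3, sd = 1,
                               seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, sd)
  y <- cprime * x + b * m + rnorm(n, 0, sd)
  data.frame(x = x, m = m, y = y)
}

# cytokine panel with the fixed three-block indicator structure
gen_block_panel <- function(n, loading = 0.7, seed = 1,
                            blocks = miomed::paper_biomarker_blocks()) {
  set.seed(seed)
  g <- matrix(rnorm(n * length(blocks)), n, length(blocks))
  cols <- list()
  for (j in seq_along(blocks)) for (bm in blocks[[j]])
    cols[[bm]] <- loading * g[, j] + sqrt(1 - loading^2) * rnorm(n)
  list(x = do.call(cbind, cols), g = g)
}

# brute-force BH step-up definition
bh_brute <- function(p) {
  m <- length(p)
  ps <- sort(p)
  ranks <- seq_len(m)
  vapply(p, function(pi) {
    idx <- which(ps >= pi - 1e-15)
    min(1, min(m * ps[idx] / ranks[idx]))
  }, numeric(1))
}

# brute-force two-group PERMANOVA p by full enumeration of group-1 index sets
permanova_brute_p <- function(d, groups) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  g <- as.factor(groups)
  n1 <- sum(g == levels(g)[1])
  ss_total <- sum(dm[upper.tri(dm)]) / n
  fstat <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    ssw <- sum(dm[idx1, idx1][upper.tri(diag(length(idx1)))]) / length(idx1) +
      sum(dm[idx2, idx2][upper.tri(diag(length(idx2)))]) / length(idx2)
    ((ss_total - ssw) / 1) / (ssw / (n - 2))
  }
  f_obs <- fstat(which(g == levels(g)[1]))
  combs <- utils::combn(n, n1)
  f_all <- apply(combs, 2, fstat)
  mean(f_all >= f_obs - 1e-12)
}

# tiny MetaPhlAn-dialect file content
write_tiny_metaphlan <- function(path) {
  lines <- c(
    "clade_name\tS1\tS2\tS3",
    "k__Bacteria\t100\t100\t100",
    "k__Bacteria|p__Firmicutes\t60\t50\t40",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae|g__Roseburia|s__Roseburia_hominis\t40\t30\t20",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae|g__Roseburia|s__Roseburia_hominis|t__GCF_000225345\t40\t30\t20",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae|g__Blautia|s__Blautia_obeum\t20\t20\t20",
    "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides|s__Bacteroides_ovatus\t40\t50\t60")
  writeLines(lines, path)
  path
}

write_tiny_humann <- function(path) {
  lines <- c(
    "# Pathway\tS1\tS2",
    "UNMAPPED\t100\t120",
    "PWY-5484\t10\t12",
    "PWY-5484|g__Escherichia.s__Escherichia_coli\t7\t8",
    "PWY-5484|g__Roseburia.s__Roseburia_hominis\t3\t4",
    "ARO-PWY\t5\t6")
  writeLines(lines, path)
  path
}

# small deterministic study used by several test files
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- miomed::simulate_study(n = 60, seed = 101)
    cache
  }
})
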
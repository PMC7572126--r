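#' Default ground truth for the synthetic two-island cohort
#'
#' Bundles every planted coefficient and distributional choice of the
#' generator: the exposure -> mediator-taxon path `a_path` (log-abundance
#' units per serve/day of sugar-sweetened beverages), the mediator -> outcome
#' paths (`b_path` onto log IL-15, `b_path_map` in mmHg per log-unit onto
#' both blood pressures, hence onto MAP), the direct exposure paths
#' (`c_prime`, `c_prime_map`), the island x taxon-absence interaction
#' `theta_interaction` on SBP (mmHg), the species factor loadings, the
#' three-block cytokine indicator structure, presence probability of the
#' moderator taxon, and per-channel noise SDs. All entries are echoed
#' verbatim into the fixture manifest. The default sizes mirror a
#' two-community study: n = 100 (2 x 50), ~70 species retained after the
#' rare-taxon filter.
#'
#' @param n_species total species count, core + rare (default 100).
#' @param n_rare how many of them are rare/low-prevalence (default 30).
#' @param k latent species factors (default 6).
#' @return list of class `ground_truth`.
#' @export
ground_truth_default <- function(n_species = 100, n_rare = 30, k = 6) {
  stopifnot(n_species > n_rare + 2, k >= 1)
  tax <- default_taxonomy(n_species)
  # species factor loadings are fixed constants of the design (own substream)
  loadings <- with_substream(20201019, "species-loadings", {
    l <- matrix(stats::rnorm(n_species * k, 0, 0.5), n_species, k)
    # give each factor a block of strong indicators among the core species
    n_core <- n_species - n_rare
    block <- split(seq_len(n_core), rep(seq_len(k), length.out = n_core))
    for (j in seq_len(k)) l[block[[j]], j] <- l[block[[j]], j] + 0.8
    rownames(l) <- names(tax)
    colnames(l) <- paste0("SpeciesFactor", seq_len(k))
    l
  })
  mu <- with_substream(20201019, "species-mu", {
    n_core <- n_species - n_rare
    m <- c(stats::rnorm(n_core, 0, 1.2), stats::rnorm(n_rare, -7, 1))
    stats::setNames(m, names(tax))
  })
  mediator <- "Lachnospiraceae_bacterium_8_1_57FAA"
  moderator <- "Alistipes_onderdonkii"
  mu[mediator] <- 0    # typical-share core taxon carrying the mediation path
  # the mediator loads only on factor 2, so the exposure -> factor-1 path
  # never leaks into the mediator: its planted a_path stays cleanly recoverable
  loadings[mediator, ] <- 0
  if (k >= 2) loadings[mediator, 2] <- 0.5
  # island-differential taxa: a block of core species shifted on Mer
  island_taxa <- grep("synthetic_sp", names(tax), value = TRUE)[1:8]
  island_shift <- stats::setNames(rep(c(1.5, -1.5), 4), island_taxa)
  structure(list(
    island_shift = island_shift,
    ssb_factor_effect = 0.3,
    factor_biomarker_effect = 0.4,
    a_path = 0.5,
    b_path = 0.4,
    b_path_map = 1.5,
    c_prime = 0.3,
    c_prime_map = 0,
    theta_interaction = 8,
    island_sbp_shift = 3,
    mediator = mediator,
    moderator = moderator,
    p_present = 0.6,
    detection_limit = 1e-4,
    species_mu = mu,
    species_loadings = loadings,
    taxonomy = tax,
    biomarker_blocks = paper_biomarker_blocks(),
    biomarker_loading = 0.7,
    extra_biomarkers = c("IL13", "IL12p40", "IL2", "IL6"),
    age_mean_waiben = 42, age_shift_mer = 10, age_sd = 14,
    noise_sds = c(species = 1, biomarker = 0.5, sbp = 10, dbp = 8)
  ), class = "ground_truth")
}

# small synthetic taxonomy: clade strings across five phyla; the mediator and
# moderator keep their canonical lineages, the rest are synthetic placeholders
default_taxonomy <- function(n_species) {
  lineages <- list(
    c("k__Bacteria", "p__Firmicutes", "c__Clostridia", "o__Clostridiales",
      "f__Lachnospiraceae", "g__Blautia"),
    c("k__Bacteria", "p__Firmicutes", "c__Clostridia", "o__Clostridiales",
      "f__Ruminococcaceae", "g__Faecalibacterium"),
    c("k__Bacteria", "p__Bacteroidetes", "c__Bacteroidia", "o__Bacteroidales",
      "f__Bacteroidaceae", "g__Bacteroides"),
    c("k__Bacteria", "p__Proteobacteria", "c__Gammaproteobacteria",
      "o__Enterobacteriales", "f__Enterobacteriaceae", "g__Escherichia"),
    c("k__Bacteria", "p__Actinobacteria", "c__Actinobacteria",
      "o__Bifidobacteriales", "f__Bifidobacteriaceae", "g__Bifidobacterium"),
    c("k__Archaea", "p__Euryarchaeota", "c__Methanobacteria",
      "o__Methanobacteriales", "f__Methanobacteriaceae", "g__Methanobrevibacter"))
  fixed <- c(
    Lachnospiraceae_bacterium_8_1_57FAA = paste(
      c("k__Bacteria", "p__Firmicutes", "c__Clostridia", "o__Clostridiales",
        "f__Lachnospiraceae", "g__Lachnospiraceae_noname",
        "s__Lachnospiraceae_bacterium_8_1_57FAA"), collapse = "|"),
    Alistipes_onderdonkii = paste(
      c("k__Bacteria", "p__Bacteroidetes", "c__Bacteroidia", "o__Bacteroidales",
        "f__Rikenellaceae", "g__Alistipes", "s__Alistipes_onderdonkii"),
      collapse = "|"))
  n_extra <- n_species - length(fixed)
  extra <- vapply(seq_len(n_extra), function(i) {
    lin <- lineages[[(i - 1) %% length(lineages) + 1]]
    genus <- sub("^g__", "", lin[6])
    sp <- sprintf("%s_synthetic_sp_%03d", genus, i)
    paste(c(lin, paste0("s__", sp)), collapse = "|")
  }, character(1))
  names(extra) <- sub("^.*\\|s__", "", extra)
  c(fixed, extra)
}

#' Generate the participant exposure/demographic table
#'
#' Two balanced island communities; age is a site-shifted truncated normal
#' (>= 15 y), smoking a zero-inflated count, dietary exposures count-like
#' (serves/day or serves/week), alcohol a zero-inflated gamma, physical
#' activity gamma-distributed minutes/week, BMI truncated normal. Exposure
#' scales are assumptions of the generator (the source design reports only
#' medians), documented in the methods vignette.
#'
#' @param n participants (>= 20; balanced across islands, so even).
#' @param seed integer seed.
#' @param params a `ground_truth` list.
#' @return data.frame cohort table.
#' @export
generate_cohort <- function(n, seed = 1, params = ground_truth_default()) {
  if (n < 20) stop("generate_cohort: n must be >= 20 (models unidentifiable below)")
  if (n %% 2 != 0) stop("generate_cohort: n must be even for balanced islands")
  with_substream(seed, "cohort", {
    island <- rep(c("Waiben", "Mer"), each = n / 2)
    age_mu <- ifelse(island == "Mer",
                     params$age_mean_waiben + params$age_shift_mer,
                     params$age_mean_waiben)
    age <- stats::rnorm(n, age_mu, params$age_sd)
    while (any(age < 15)) age[age < 15] <- stats::rnorm(sum(age < 15),
                                                        age_mu[age < 15],
                                                        params$age_sd)
    smoker <- stats::rbinom(n, 1, 0.33)
    data.frame(
      participant_id = sprintf("P%04d", seq_len(n)),
      island = island,
      age = round(age, 1),
      gender = sample(c("female", "male"), n, replace = TRUE),
      smoking = smoker * stats::rpois(n, 6),
      ssb = stats::rpois(n, 1.0),
      fruit = stats::rpois(n, 2),
      vegetables = stats::rpois(n, 3.5),
      takeaway = stats::rpois(n, ifelse(island == "Mer", 0.6, 1.2)),
      seafood = stats::rpois(n, ifelse(island == "Mer", 3, 2)),
      alcohol = round(stats::rbinom(n, 1, 0.6) *
                        stats::rgamma(n, shape = 1.2, scale = 0.8), 2),
      activity = round(stats::rgamma(n, shape = 4, scale = 50)),
      bmi = round(pmin(pmax(stats::rnorm(n, 32, 6), 16), 60), 1),
      stringsAsFactors = FALSE)
  })
}

#' Generate the species relative-abundance table
#'
#' Log-latent abundances are mu + Lambda f + a_path ssb (mediator taxon
#' only) + noise, mapped to compositions by exponentiation and per-sample
#' normalization (softmax link, preserving linear planted paths on the log
#' scale). Entries below the detection limit become exact zeros; the
#' moderator taxon is additionally gated by a Bernoulli(p_present) structural
#' zero (detect/non-detect, not rounding). Rows sum to 1 within 1e-9.
#'
#' @param cohort table from [generate_cohort()].
#' @param seed integer seed.
#' @param params a `ground_truth` list.
#' @return species [abundance_table()]; the latent factor scores and the
#'   moderator presence gate are attached as attributes `latent_factors`,
#'   `moderator_present`.
#' @export
generate_microbiome <- function(cohort, seed = 1, params = ground_truth_default()) {
  n <- nrow(cohort)
  lam <- params$species_loadings
  k <- ncol(lam)
  n_sp <- nrow(lam)
  if (k > n_sp) stop("generate_microbiome: loading rank exceeds species count")
  with_substream(seed, "microbiome", {
    f <- matrix(stats::rnorm(n * k), n, k, dimnames = list(cohort$participant_id,
                                                           colnames(lam)))
    # exposure -> species-factor path (factor 1; the mediator does not load on it)
    f[, 1] <- f[, 1] + params$ssb_factor_effect *
      (cohort$ssb - mean(cohort$ssb)) / max(stats::sd(cohort$ssb), 1e-8)
    eps <- matrix(stats::rnorm(n * n_sp, 0, params$noise_sds[["species"]]), n, n_sp)
    loglat <- matrix(params$species_mu, n, n_sp, byrow = TRUE) +
      f %*% t(lam) + eps
    # island-differential block
    mer <- as.numeric(cohort$island == "Mer")
    ii <- match(names(params$island_shift), rownames(lam))
    loglat[, ii] <- loglat[, ii] + outer(mer, params$island_shift)
    med_i <- match(params$mediator, rownames(lam))
    loglat[, med_i] <- loglat[, med_i] + params$a_path * cohort$ssb
    v <- exp(loglat)
    v <- v / rowSums(v)
    present <- stats::rbinom(n, 1, params$p_present)
    mod_i <- match(params$moderator, rownames(lam))
    v[present == 0, mod_i] <- 0
    v[v < params$detection_limit] <- 0
    v[, med_i] <- pmax(v[, med_i], params$detection_limit)  # mediator always detected
    v <- v / rowSums(v)
    dimnames(v) <- list(cohort$participant_id, rownames(lam))
    out <- abundance_table(v, "species", taxonomy = params$taxonomy)
    attr(out, "latent_factors") <- f
    attr(out, "moderator_present") <- stats::setNames(present, cohort$participant_id)
    out
  })
}

#' Generate the cytokine panel from the three-block factor structure
#'
#' Twelve-plus biomarker concentrations are drawn from three latent factors
#' with the fixed indicator blocks (Factor 1: TNFa, IL-4, IL-12p70;
#' Factor 2: CRP, IL-18, MCP1; Factor 3: IL-15, IL-33, IFNg, IL-1b) through
#' a lognormal link, so concentrations are strictly positive. IL-15
#' additionally receives b_path times the mediator's (centered) log relative
#' abundance — the planted mediation path onto inflammation.
#'
#' @param cohort table from [generate_cohort()].
#' @param microbiome table from [generate_microbiome()].
#' @param seed integer seed.
#' @param params a `ground_truth` list.
#' @return cohort augmented with biomarker columns (pg/mL-scale).
#' @export
generate_biomarkers <- function(cohort, microbiome, seed = 1,
                                params = ground_truth_default()) {
  blocks <- params$biomarker_blocks
  all_bm <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_bm)) stop("generate_biomarkers: duplicate biomarker in blocks")
  if (!params$mediator %in% colnames(microbiome$values))
    stop("generate_biomarkers: mediator taxon column missing")
  n <- nrow(cohort)
  logm <- log(microbiome$values[cohort$participant_id, params$mediator])
  logm_c <- logm - mean(logm)
  lv <- params$biomarker_loading
  f <- attr(microbiome, "latent_factors")
  with_substream(seed, "biomarkers", {
    g <- matrix(stats::rnorm(n * length(blocks)), n, length(blocks))
    # inflammation factor 3 partially driven by species factor 1 (a
    # framework-1-like latent path), when the factors are available
    if (!is.null(f)) {
      rho <- params$factor_biomarker_effect
      g[, 3] <- rho * scale(f[, 1])[, 1] + sqrt(1 - rho^2) * g[, 3]
    }
    base_mu <- c(TNFa = -1, IL4 = 1.7, IL12p70 = -0.5, CRP = -0.3, IL18 = 2.5,
                 MCP1 = 4.3, IL15 = 2, IL33 = 0.5, IFNg = -0.2, IL1b = -1)
    for (j in seq_along(blocks)) for (bm in blocks[[j]]) {
      logc <- base_mu[[bm]] + lv * g[, j] +
        stats::rnorm(n, 0, params$noise_sds[["biomarker"]])
      if (bm == "IL15") logc <- logc + params$b_path * logm_c +
          params$c_prime * (cohort$ssb - mean(cohort$ssb))
      cohort[[bm]] <- round(exp(logc), 4)
    }
    for (bm in params$extra_biomarkers)
      cohort[[bm]] <- round(exp(stats::rnorm(n, 0.5, 0.6)), 4)
    cohort
  })
}

#' Generate blood-pressure outcomes with the planted moderation effect
#'
#' SBP = b0 + b_age age + delta island + theta (island x moderator-absence)
#' + b_path_map (centered log mediator abundance) + noise; DBP analogously
#' without the island or interaction terms. DBP is capped at SBP - 5 mmHg
#' (measurement consistency). MAP = (SBP + 2 DBP)/3; because the mediator
#' path enters both pressures with the same coefficient, MAP carries it too.
#' Also adds glucose and waist circumference as auxiliary clinical columns.
#'
#' @param cohort table (from [generate_biomarkers()] or [generate_cohort()]).
#' @param microbiome table from [generate_microbiome()].
#' @param seed integer seed.
#' @param params a `ground_truth` list.
#' @return cohort augmented with sbp, dbp, map, hypertension, glucose, waist.
#' @export
generate_outcomes <- function(cohort, microbiome, seed = 1,
                              params = ground_truth_default()) {
  n <- nrow(cohort)
  pres <- attr(microbiome, "moderator_present")
  if (is.null(pres))
    pres <- as.integer(microbiome$values[cohort$participant_id, params$moderator] > 0)
  logm <- log(microbiome$values[cohort$participant_id, params$mediator])
  logm_c <- logm - mean(logm)
  mer <- as.numeric(cohort$island == "Mer")
  absent <- 1 - pres
  with_substream(seed, "outcomes", {
    sbp <- 103 + 0.45 * cohort$age + params$island_sbp_shift * mer +
      params$theta_interaction * mer * absent +
      params$b_path_map * logm_c +
      params$c_prime_map * cohort$ssb +
      stats::rnorm(n, 0, params$noise_sds[["sbp"]])
    dbp <- 58 + 0.25 * cohort$age +
      params$b_path_map * logm_c +
      stats::rnorm(n, 0, params$noise_sds[["dbp"]])
    dbp <- pmin(dbp, sbp - 5)
    cohort$sbp <- round(sbp, 1)
    cohort$dbp <- round(dbp, 1)
    cohort$map <- compute_map(cohort$sbp, cohort$dbp)
    cohort$hypertension <- flag_hypertension(cohort$sbp, cohort$dbp)
    cohort$glucose <- round(exp(stats::rnorm(n, log(5.6), 0.15)), 1)
    cohort$waist <- round(2.3 * cohort$bmi + 30 + stats::rnorm(n, 0, 6))
    cohort
  })
}

#' Generate a community + stratified pathway table (HUMAnN-style fixture)
#'
#' Pathway relative abundances are drawn directly from a low-rank factor
#' model (softmax link) with an island shift planted in a handful of
#' pathways; a few pathways are additionally split into 2-3 taxon-stratified
#' rows by fixed Dirichlet-like weights. Pathway inference from reads is
#' deliberately not simulated.
#'
#' @param cohort table from [generate_cohort()].
#' @param seed integer seed.
#' @param params a `ground_truth` list.
#' @param n_pathways community pathways (default 40).
#' @param n_shifted pathways carrying an island shift (default 5).
#' @return list(community, stratified) of [abundance_table()]s (per-million scale).
#' @export
generate_pathways <- function(cohort, seed = 1, params = ground_truth_default(),
                              n_pathways = 40, n_shifted = 5) {
  n <- nrow(cohort)
  mer <- as.numeric(cohort$island == "Mer")
  with_substream(seed, "pathways", {
    ids <- sprintf("PWY-%04d", seq_len(n_pathways) + 1000)
    k <- 3
    lam <- matrix(stats::rnorm(n_pathways * k, 0, 0.4), n_pathways, k)
    mu <- stats::rnorm(n_pathways, 0, 0.8)
    f <- matrix(stats::rnorm(n * k), n, k)
    loglat <- matrix(mu, n, n_pathways, byrow = TRUE) + f %*% t(lam) +
      matrix(stats::rnorm(n * n_pathways, 0, 0.5), n, n_pathways)
    shift_idx <- seq_len(n_shifted)
    loglat[, shift_idx] <- loglat[, shift_idx] + outer(mer, rep(0.8, n_shifted))
    v <- exp(loglat)
    v <- v / rowSums(v) * 1e6
    dimnames(v) <- list(cohort$participant_id, ids)
    community <- abundance_table(v, "pathway")
    # stratify the first 6 pathways across 2 contributing taxa each
    taxa <- c("g__Escherichia.s__Escherichia_coli",
              "g__Roseburia.s__Roseburia_synthetic_sp_004",
              "g__Bacteroides.s__Bacteroides_synthetic_sp_003")
    strat_cols <- list(); strat_ids <- character(0)
    for (i in 1:6) {
      w <- stats::runif(1, 0.3, 0.7)
      t1 <- taxa[(i - 1) %% 3 + 1]; t2 <- taxa[i %% 3 + 1]
      strat_cols[[length(strat_cols) + 1]] <- v[, i] * w
      strat_ids <- c(strat_ids, paste0(ids[i], "|", t1))
      strat_cols[[length(strat_cols) + 1]] <- v[, i] * (1 - w)
      strat_ids <- c(strat_ids, paste0(ids[i], "|", t2))
    }
    sv <- do.call(cbind, strat_cols)
    dimnames(sv) <- list(cohort$participant_id, strat_ids)
    stratified <- abundance_table(sv, "stratified-pathway")
    attr(stratified, "pathway") <- sub("\\|.*$", "", strat_ids)
    attr(stratified, "taxon") <- sub("^[^|]+\\|", "", strat_ids)
    list(community = community, stratified = stratified)
  })
}

#' Generate the full synthetic study (cohort + microbiome + biomarkers +
#' outcomes + pathways)
#'
#' @param n participants (default 100).
#' @param seed integer seed.
#' @param params a `ground_truth` list.
#' @return list(cohort, microbiome, pathways, params, seed).
#' @export
simulate_study <- function(n = 100, seed = 1, params = ground_truth_default()) {
  cohort <- generate_cohort(n, seed, params)
  microbiome <- generate_microbiome(cohort, seed, params)
  cohort <- generate_biomarkers(cohort, microbiome, seed, params)
  cohort <- generate_outcomes(cohort, microbiome, seed, params)
  pathways <- generate_pathways(cohort, seed, params)
  list(cohort = cohort, microbiome = microbiome, pathways = pathways,
       params = params, seed = seed)
}

#' Write a fixture set (metadata CSV, species TSV, pathway TSV, manifest)
#'
#' Emits the four files a real study would provide: participant metadata
#' (CSV), a species table in the MetaPhlAn merged dialect (percent scale), a
#' pathway table in the HUMAnN dialect (community + stratified rows), and a
#' JSON manifest echoing every planted coefficient. A round-trip read of the
#' emitted files reproduces the in-memory tables.
#'
#' @param study list from [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture_set <- function(study, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("write_fixture_set: cannot write to ", outdir)
  paths <- c(metadata = file.path(outdir, "metadata.csv"),
             species = file.path(outdir, "species_metaphlan.tsv"),
             pathways = file.path(outdir, "pathways_humann.tsv"),
             manifest = file.path(outdir, "manifest.json"))
  utils::write.csv(study$cohort, paths[["metadata"]], row.names = FALSE,
                   quote = FALSE, eol = "\n")
  write_metaphlan_table(study$microbiome, paths[["species"]])
  write_humann_pathways(study$pathways$community, paths[["pathways"]],
                        stratified = study$pathways$stratified)
  gt <- study$params
  manifest <- list(
    seed = study$seed, n = nrow(study$cohort),
    a_path = gt$a_path, b_path = gt$b_path, b_path_map = gt$b_path_map,
    c_prime = gt$c_prime, c_prime_map = gt$c_prime_map,
    theta_interaction = gt$theta_interaction,
    island_sbp_shift = gt$island_sbp_shift,
    island_shift = as.list(gt$island_shift),
    ssb_factor_effect = gt$ssb_factor_effect,
    factor_biomarker_effect = gt$factor_biomarker_effect,
    mediator = gt$mediator, moderator = gt$moderator,
    p_present = gt$p_present, detection_limit = gt$detection_limit,
    biomarker_blocks = gt$biomarker_blocks,
    biomarker_loading = gt$biomarker_loading,
    age_mean_waiben = gt$age_mean_waiben, age_shift_mer = gt$age_shift_mer,
    age_sd = gt$age_sd,
    noise_sds = as.list(gt$noise_sds),
    species_loadings = unname(apply(gt$species_loadings, 1, function(r)
      as.list(unname(r)), simplify = FALSE)),
    species_mu = as.list(gt$species_mu))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
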
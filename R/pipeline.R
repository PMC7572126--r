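#' Default pipeline configuration
#'
#' All thresholds of the analysis in one place: rare-taxon prevalence 0.40
#' and abundance 0.01, LDA score gate 3.0, alpha 0.05, Spearman rho 0.3,
#' presence threshold 0, stratified-pathway floor 0.8; resampling sizes
#' (mediation bootstrap 1000, PERMANOVA permutations 9999, LDA bootstrap
#' 30); the global seed; and the variable roles.
#'
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    paths = list(species = NULL, pathways = NULL, metadata = NULL,
                 outdir = "results"),
    n_participants = 100,
    seed = 42,
    thresholds = list(prevalence = 0.40, abundance = 0.01, lda = 3.0,
                      alpha = 0.05, rho = 0.3, presence = 0,
                      pathway_floor = 0.8),
    resampling = list(n_boot = 1000, n_perm = 9999, lefse_boot = 30,
                      nmds_restarts = 50),
    factors = list(species_k = 6, biomarker_k = 3),
    roles = list(
      exposure = "ssb",
      mediator = "Lachnospiraceae_bacterium_8_1_57FAA",
      moderator_outcome = "sbp",
      mediation_outcomes = c("IL15", "map"),
      group = "island",
      sem_exposures = c("ssb", "age"),
      log_vars = c("glucose", "TNFa", "IL4", "IL12p70", "CRP", "IL18", "MCP1",
                   "IL15", "IL33", "IFNg", "IL1b", "IL13", "IL12p40", "IL2", "IL6"),
      table1_vars = c("age", "ssb", "fruit", "vegetables", "takeaway", "seafood",
                      "alcohol", "smoking", "activity", "glucose", "sbp", "map",
                      "bmi", "waist", "TNFa", "IL4", "IL12p70", "CRP", "IL18",
                      "MCP1", "IL15", "IL33", "IFNg", "IL1b"))
  ), class = "pipeline_config")
}

check_range <- function(val, nm, lo, hi) {
  if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < lo || val > hi)
    stop(sprintf("validate_config: field '%s' out of range [%g, %g]", nm, lo, hi))
  val
}

#' Validate (and default) a pipeline configuration
#'
#' Accepts a YAML file path or a list. Unknown keys are an error (no silent
#' ignoring); missing keys take their documented defaults; every threshold
#' is range-checked. An empty file yields all defaults.
#'
#' @param config YAML path, list, or NULL for pure defaults.
#' @return a validated `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  base <- default_config()
  user <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop("validate_config: no such file: ", config)
    y <- yaml::read_yaml(config)
    if (!is.list(y)) list() else y     # empty/blank files give all defaults
  } else as.list(config)
  merge_into <- function(base, user, path = "") {
    for (nm in names(user)) {
      full <- if (path == "") nm else paste0(path, ".", nm)
      if (!nm %in% names(base)) stop("validate_config: unknown key '", full, "'")
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge_into(base[[nm]], as.list(user[[nm]]), full)
      } else base[nm] <- list(user[[nm]])   # keeps explicit NULLs in place
    }
    base
  }
  cfg <- merge_into(unclass(base), user)
  th <- cfg$thresholds
  check_range(th$prevalence, "prevalence", 1e-9, 1)
  check_range(th$abundance, "abundance", 1e-9, 1)
  check_range(th$lda, "lda", 0, 10)
  check_range(th$alpha, "alpha", 0, 1)
  check_range(th$rho, "rho", 0, 1)
  check_range(th$presence, "presence", 0, 1)
  check_range(th$pathway_floor, "pathway_floor", 0, 1)
  check_range(cfg$resampling$n_boot, "n_boot", 10, 1e6)
  check_range(cfg$resampling$n_perm, "n_perm", 10, 1e7)
  check_range(cfg$resampling$lefse_boot, "lefse_boot", 1, 1e4)
  check_range(cfg$seed, "seed", 0, 2^31 - 1)
  check_range(cfg$n_participants, "n_participants", 20, 1e6)
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing (alignment, MAP/hypertension, rare-taxon
#' filter), diversity (alpha, Bray-Curtis, PERMANOVA, NMDS), the LEfSe-style
#' differential-abundance stage, pathway comparisons, EFA of species and
#' biomarkers, the four-framework SEM comparison, the mediation ladder, the
#' microbiome-wide moderation scan, and cohort statistics (group
#' comparisons, Spearman screen). If the config names input files they are
#' read; otherwise a synthetic study is generated at `config$n_participants` under
#' `config$seed`. Writes per-stage TSV/JSON outputs plus a manifest into
#' `outdir` (deterministic byte-for-byte for a fixed config; the manifest
#' carries no timestamps).
#'
#' @param config a `pipeline_config`, YAML path, or NULL for defaults.
#' @param outdir output directory (overrides config$paths$outdir if given).
#' @return the result bundle (named list), invisibly.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  cfg <- validate_config(config)
  if (is.null(outdir)) outdir <- cfg$paths$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- cfg$seed
  th <- cfg$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("run_pipeline: stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- inputs -----------------------------------------------------------
  inp <- stage("input", {
    if (!is.null(cfg$paths$species)) {
      sp <- read_metaphlan_table(cfg$paths$species)
      meta <- read_cohort_csv(cfg$paths$metadata)
      pw <- if (!is.null(cfg$paths$pathways))
        read_humann_pathways(cfg$paths$pathways) else NULL
      list(cohort = meta, microbiome = sp, pathways = pw, manifest_gt = NULL)
    } else {
      st <- simulate_study(n = cfg$n_participants, seed = seed)
      list(cohort = st$cohort, microbiome = st$microbiome,
           pathways = st$pathways, manifest_gt = st$params)
    }
  })

  # --- preprocess -------------------------------------------------------
  pre <- stage("preprocess", {
    al <- align_tables(inp$cohort, inp$microbiome)
    cohort <- al$cohort
    if (!"map" %in% names(cohort))
      cohort$map <- compute_map(cohort$sbp, cohort$dbp)
    if (!"hypertension" %in% names(cohort))
      cohort$hypertension <- flag_hypertension(cohort$sbp, cohort$dbp)
    filt <- filter_rare_taxa(al$table, th$prevalence, th$abundance)
    write_tsv(filt$report, file.path(outdir, "filter_report.tsv"))
    list(cohort = cohort, species = filt$table, report = filt$report)
  })
  n_used <- nrow(pre$cohort)

  # --- diversity --------------------------------------------------------
  div <- stage("diversity", {
    alpha <- alpha_diversity(pre$species)
    d <- bray_curtis(pre$species, sqrt_transform = TRUE)
    perma <- permanova(d, pre$cohort[[cfg$roles$group]],
                       n_perm = cfg$resampling$n_perm,
                       seed = substream_seed(seed, "stage-permanova"))
    ord <- nmds(d, k = 2, n_restarts = cfg$resampling$nmds_restarts,
                seed = substream_seed(seed, "stage-nmds"))
    write_tsv(alpha, file.path(outdir, "alpha_diversity.tsv"))
    dm <- as.matrix(d)
    write_tsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
              file.path(outdir, "bray_curtis.tsv"))
    write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates, check.names = FALSE),
              file.path(outdir, "nmds_coordinates.tsv"))
    list(alpha = alpha, dist = d, permanova = perma, nmds = ord)
  })

  # --- differential abundance ------------------------------------------
  da <- stage("lefse", {
    res <- lefse(pre$species, pre$cohort[[cfg$roles$group]],
                 alpha = th$alpha, lda_threshold = th$lda,
                 n_boot = cfg$resampling$lefse_boot,
                 seed = substream_seed(seed, "stage-lefse"))
    write_tsv(res, file.path(outdir, "lefse.tsv"))
    res
  })

  # --- pathways ---------------------------------------------------------
  pw <- stage("pathways", {
    if (is.null(inp$pathways)) return(NULL)
    ids <- pre$cohort$participant_id
    comm <- at_subset(inp$pathways$community, samples = ids)
    res_c <- pathway_compare(comm, pre$cohort[[cfg$roles$group]],
                             n_boot = cfg$resampling$n_boot,
                             seed = substream_seed(seed, "stage-pathways"))
    res_s <- NULL
    if (!is.null(inp$pathways$stratified)) {
      strat <- inp$pathways$stratified
      keep <- match(ids, sample_ids(strat))
      sv <- strat$values[keep, , drop = FALSE]
      strat2 <- abundance_table(sv, "stratified-pathway")
      attr(strat2, "pathway") <- attr(strat, "pathway")
      attr(strat2, "taxon") <- attr(strat, "taxon")
      res_s <- stratified_pathway_compare(strat2, pre$cohort[[cfg$roles$group]],
                                          presence_floor = th$pathway_floor,
                                          alpha = th$alpha)
      write_tsv(res_s, file.path(outdir, "pathways_stratified.tsv"))
    }
    write_tsv(res_c, file.path(outdir, "pathways_community.tsv"))
    list(community = res_c, stratified = res_s)
  })

  # --- latent factors ---------------------------------------------------
  efa <- stage("efa", {
    sp_efa <- efa_fit(pre$species$values, k = cfg$factors$species_k)
    bm_cols <- unlist(paper_biomarker_blocks(), use.names = FALSE)
    bm_cols <- intersect(bm_cols, names(pre$cohort))
    bm_mat <- log(as.matrix(pre$cohort[, bm_cols]))  # lognormal panel
    bm_efa <- efa_fit(bm_mat, k = cfg$factors$biomarker_k)
    ldf <- data.frame(feature = rownames(sp_efa$loadings), sp_efa$loadings,
                      uniqueness = sp_efa$uniquenesses, check.names = FALSE)
    write_tsv(ldf, file.path(outdir, "efa_species_loadings.tsv"))
    ldf2 <- data.frame(feature = rownames(bm_efa$loadings), bm_efa$loadings,
                       uniqueness = bm_efa$uniquenesses, check.names = FALSE)
    write_tsv(ldf2, file.path(outdir, "efa_biomarker_loadings.tsv"))
    list(species = sp_efa, biomarkers = bm_efa)
  })

  # --- SEM framework comparison ----------------------------------------
  sem <- stage("sem", {
    sp_sc <- efa$species$scores
    colnames(sp_sc) <- paste0("SpeciesFactor", seq_len(ncol(sp_sc)))
    bm_sc <- efa$biomarkers$scores
    colnames(bm_sc) <- paste0("BiomarkerFactor", seq_len(ncol(bm_sc)))
    dat <- cbind(pre$cohort[, cfg$roles$sem_exposures, drop = FALSE],
                 as.data.frame(sp_sc), as.data.frame(bm_sc))
    cmp <- compare_frameworks(dat, cfg$roles$sem_exposures,
                              colnames(sp_sc), colnames(bm_sc))
    write_tsv(cmp$report, file.path(outdir, "sem_frameworks.tsv"))
    cmp
  })

  # --- mediation ladder -------------------------------------------------
  med <- stage("mediation", {
    dat <- pre$cohort
    dat$mediator_log <- as.numeric(log_offset(
      pre$species$values[dat$participant_id, cfg$roles$mediator]))
    out <- list()
    for (oc in cfg$roles$mediation_outcomes) {
      yv <- if (oc %in% cfg$roles$log_vars)
        as.numeric(log_offset(dat[[oc]])) else dat[[oc]]
      dd <- dat; dd$.outcome <- yv
      out[[oc]] <- mediation_ladder(dd, cfg$roles$exposure, "mediator_log",
                                    ".outcome", n_boot = cfg$resampling$n_boot,
                                    seed = substream_seed(seed, paste0("stage-mediate-", oc)))
    }
    summ <- do.call(rbind, lapply(names(out), function(oc) {
      do.call(rbind, lapply(names(out[[oc]]), function(rung) {
        m <- out[[oc]][[rung]]
        data.frame(outcome = oc, rung = rung, acme = m$acme$point,
                   acme_lo = m$acme$lo, acme_hi = m$acme$hi, acme_p = m$acme$p,
                   ade = m$ade$point, total = m$total$point,
                   total_lo = m$total$lo, total_hi = m$total$hi,
                   prop_mediated = m$prop_mediated$point,
                   prop_lo = m$prop_mediated$lo, prop_hi = m$prop_mediated$hi,
                   n = m$n_used, stringsAsFactors = FALSE)
      }))
    }))
    write_tsv(summ, file.path(outdir, "mediation.tsv"))
    list(results = out, summary = summ)
  })

  # --- moderation scan --------------------------------------------------
  mod <- stage("moderation", {
    pres <- presence_matrix(pre$species, threshold = th$presence)
    scan <- interaction_scan(pre$cohort[[cfg$roles$moderator_outcome]],
                             pre$cohort[[cfg$roles$group]], pres)
    write_tsv(scan, file.path(outdir, "moderation_scan.tsv"))
    tested <- scan[!scan$skipped, ]
    top <- tested$taxon[which.min(tested$q)]
    ladder <- scan_ladder(pre$cohort, cfg$roles$moderator_outcome,
                          cfg$roles$group, pres, top)
    list(scan = scan, top_taxon = top, ladder = ladder)
  })

  # --- cohort statistics ------------------------------------------------
  stats_ <- stage("cohort_stats", {
    t1 <- table1_compare(pre$cohort,
                         intersect(cfg$roles$table1_vars, names(pre$cohort)),
                         group = cfg$roles$group,
                         log_vars = cfg$roles$log_vars)
    bm_cols <- intersect(unlist(paper_biomarker_blocks(), use.names = FALSE),
                         names(pre$cohort))
    screen <- spearman_screen(pre$cohort[, bm_cols],
                              pre$species$values[pre$cohort$participant_id, ],
                              rho_min = th$rho, alpha = th$alpha)
    write_tsv(t1, file.path(outdir, "table1.tsv"))
    write_tsv(screen, file.path(outdir, "spearman_screen.tsv"))
    list(table1 = t1, screen = screen)
  })

  # --- manifest ---------------------------------------------------------
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  manifest <- list(
    package_version = as.character(utils::packageVersion("miomed")),
    seed = seed, config_hash = string_hash(cfg_yaml),
    config = unclass(cfg),
    n_participants = n_used,
    n_species_in = ncol(inp$microbiome$values),
    n_species_retained = ncol(pre$species$values),
    stage_seeds = lapply(c("stage-permanova", "stage-nmds", "stage-lefse",
                           "stage-pathways"), function(s) substream_seed(seed, s)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = cfg, input = inp, preprocess = pre, diversity = div,
                 lefse = da, pathways = pw, efa = efa, sem = sem,
                 mediation = med, moderation = mod, cohort_stats = stats_,
                 manifest = manifest))
}
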
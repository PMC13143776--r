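#' Default run configuration
#'
#' Every tunable threshold the analysis modules expose, with its
#' documented default.  `simulate = TRUE` makes the pipeline generate
#' its own synthetic inputs; otherwise `counts_path`/`samples_path` (and
#' optionally `clinical_path`) must point at real inputs.
#'
#' @param outdir output directory
#' @param seed master seed; per-stage seeds are derived from it
#' @return named list (class `run_config`)
#' @export
default_config <- function(outdir = tempfile("nelfayap_run_"), seed = 1) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    simulate = TRUE,
    counts_path = NULL, samples_path = NULL, clinical_path = NULL,
    # synthetic design
    n_genes = 1200, n_planted_per_category = 50, effect_log2fc = 2,
    reps = 3, dispersion = 0.05,
    n_track_genes = 60, bound_fraction = 0.8, loss_fraction = 0.5,
    peak_enrichment = 4, output_fold = 1.3,
    cohort_n = 100, censor_months = 60,
    # analysis thresholds
    alpha = 0.05,
    gsea_weight = 1, gsea_n_perm = 500, gsea_min_size = 5,
    gsea_max_size = 500,
    pausing_eps = 1e-3, retention_threshold = 0.5, min_fold = 1,
    loss_drop = 1.5
  ), class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Values in the file override the defaults of [default_config()].
#' @param path YAML (`.yml`/`.yaml`) or JSON config file
#' @return a `run_config`
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(vals)] <- vals
  cfg
}

.stage_seed <- function(cfg, offset) (cfg$seed * 101L + offset) %% 2147483647L

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load) counts,
#' differential expression, co-regulation classification and overlaps,
#' enrichment, track simulation and pausing calls, cohort simulation
#' (or load) and clinical stratification/survival — writing each stage's
#' tables under `cfg$outdir` plus a JSON run manifest with the config
#' hash, seeds and per-stage row counts.  Reruns with the same config
#' reproduce all outputs (all randomness flows from `cfg$seed`).
#' Stages whose outputs already exist are recomputed unless
#' `resume = TRUE`, in which case their files are reused.
#'
#' @param cfg a `run_config` from [default_config()] or [read_config()]
#' @param resume reuse existing stage outputs instead of recomputing
#' @return the manifest, invisibly (also written to
#'   `outdir/manifest.json`)
#' @export
run_pipeline <- function(cfg = default_config(), resume = FALSE) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(cfg$outdir, ...)
  counts_n <- 0L
  manifest <- list(seed = cfg$seed, stages = list())
  cfg_json <- pth("config.json")
  jsonlite::write_json(cfg[order(names(cfg))], cfg_json, auto_unbox = TRUE,
                       null = "null", digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_json))
  manifest$versions <- list(
    package = as.character(utils::packageVersion("nelfayap")),
    r = paste(R.version$major, R.version$minor, sep = "."))

  done <- function(stage, rows) {
    manifest$stages[[stage]] <<- list(rows = rows)
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  ## stage: counts --------------------------------------------------------
  stage <- "counts"
  tryCatch({
    if (resume && file.exists(pth("counts.tsv"))) {
      cm <- read_counts(pth("counts.tsv"), pth("samples.csv"))
      truth_counts <- read.delim(pth("truth_counts.tsv"))
    } else if (isTRUE(cfg$simulate)) {
      sim <- simulate_counts(cfg$n_genes, cfg$n_planted_per_category,
                             cfg$effect_log2fc, cfg$reps, cfg$dispersion,
                             seed = .stage_seed(cfg, 1L))
      cm <- sim$counts; truth_counts <- sim$truth
      write_counts(cm, pth("counts.tsv"), pth("samples.csv"))
      write.table(truth_counts, pth("truth_counts.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    } else {
      if (is.null(cfg$counts_path) || is.null(cfg$samples_path))
        stop("missing input: counts_path/samples_path (and simulate = FALSE)")
      cm <- read_counts(cfg$counts_path, cfg$samples_path)
      truth_counts <- NULL
    }
    done(stage, nrow(cm$counts))
  }, error = function(e) fail(stage, e))

  ## stage: differential expression --------------------------------------
  stage <- "de"
  tab <- tryCatch({
    tab <- contrast_table(cm)
    write_contrast_table(tab, pth("contrasts.tsv"))
    for (cc in CONTRASTS) {
      rl <- tryCatch(make_ranked_list(tab, cc, cfg$alpha),
                     error = function(e) NULL)
      if (!is.null(rl)) write_rnk(rl, pth(paste0("ranked_", cc, ".rnk")))
    }
    done(stage, length(unique(tab$gene_id)))
    tab
  }, error = function(e) fail(stage, e))

  ## stage: classification and overlaps -----------------------------------
  stage <- "classify"
  calls <- tryCatch({
    calls <- classify_all(tab, cfg$alpha)
    write_category_calls(calls, pth("category_calls.tsv"))
    sets <- lapply(CONTRASTS, function(cc)
      significant_genes(tab, cc, cfg$alpha))
    names(sets) <- CONTRASTS
    ov <- overlap_counts(sets)
    write_overlaps_json(ov, pth("overlaps.json"))
    done(stage, nrow(calls))
    calls
  }, error = function(e) fail(stage, e))

  ## stage: enrichment -----------------------------------------------------
  stage <- "enrich"
  tryCatch({
    ranked <- make_ranked_list(tab, "siNELFA", cfg$alpha)
    universe <- unique(tab$gene_id)
    # gene sets: the planted categories (when simulated) act as signatures
    coll <- if (!is.null(truth_counts)) {
      split(truth_counts$gene_id, truth_counts$category)[COREG_CATEGORIES[1:4]]
    } else {
      split(calls$gene_id, calls$category)[COREG_CATEGORIES[1:4]]
    }
    coll <- Filter(function(s) length(s) >= cfg$gsea_min_size, coll)
    gsea <- run_gsea(ranked, coll, cfg$gsea_weight, cfg$gsea_n_perm,
                     cfg$gsea_min_size, cfg$gsea_max_size,
                     seed = .stage_seed(cfg, 2L))
    write.table(gsea, pth("gsea.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    fo <- run_fisher_overlap(significant_genes(tab, "siNELFA", cfg$alpha),
                             coll, universe)
    write.table(fo, pth("fisher_overlap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    done(stage, nrow(gsea))
  }, error = function(e) fail(stage, e))

  ## stage: pausing --------------------------------------------------------
  stage <- "pausing"
  tryCatch({
    tx <- toy_transcripts(cfg$n_track_genes)
    sim <- simulate_tracks(tx, cfg$bound_fraction, cfg$loss_fraction,
                           cfg$peak_enrichment, cfg$output_fold,
                           seed = .stage_seed(cfg, 3L))
    quant <- quantify_pausing(
      sim$transcripts,
      sim$tracks$chip_baseline, sim$tracks$chip_perturbed,
      sim$tracks$input,
      sim$tracks$nascent_plus_baseline, sim$tracks$nascent_minus_baseline,
      sim$tracks$nascent_plus_perturbed, sim$tracks$nascent_minus_perturbed,
      eps = cfg$pausing_eps,
      retention_threshold = cfg$retention_threshold,
      min_fold = cfg$min_fold, loss_drop = cfg$loss_drop)
    write.table(quant, pth("pausing_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$truth, pth("truth_tracks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    done(stage, nrow(quant))
  }, error = function(e) fail(stage, e))

  ## stage: clinical -------------------------------------------------------
  stage <- "clinical"
  tryCatch({
    if (!is.null(cfg$clinical_path)) {
      records <- read_clinical(cfg$clinical_path)
      truth_cohort <- NULL
    } else {
      sim <- simulate_cohort(cfg$cohort_n, censor_months = cfg$censor_months,
                             seed = .stage_seed(cfg, 4L))
      records <- sim$records; truth_cohort <- sim$truth
      write_clinical(records, pth("cohort.csv"))
      write.table(truth_cohort, pth("truth_cohort.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    yap_score <- composite_score(records$yap_percent, records$yap_intensity)
    nelfa_score <- composite_score(records$nelfa_percent,
                                   records$nelfa_intensity)
    cut_yap <- roc_cutoff(yap_score, records$dfs_event)$cutoff
    cut_nelfa <- roc_cutoff(nelfa_score, records$dfs_event)$cutoff
    strat <- stratify(records, "joint",
                      cutoffs = list(yap = cut_yap, nelfa = cut_nelfa))
    lr_os <- logrank_test(strat$os_months, strat$os_event, strat$group)
    lr_dfs <- logrank_test(strat$dfs_months, strat$dfs_event, strat$group)
    ct <- chi2_contingency(table(strat$group, strat$subtype))
    res <- list(
      cutoffs = list(yap = cut_yap, nelfa = cut_nelfa),
      group_sizes = as.list(table(strat$group)),
      logrank_os = lr_os, logrank_dfs = lr_dfs,
      subtype_contingency = list(statistic = ct$statistic, df = ct$df,
                                 p = ct$p))
    jsonlite::write_json(res, pth("clinical.json"), auto_unbox = TRUE,
                         digits = NA)
    write.table(strat, pth("cohort_stratified.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    done(stage, nrow(records))
  }, error = function(e) fail(stage, e))

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
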
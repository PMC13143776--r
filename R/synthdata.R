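#' @importFrom stats rnbinom runif rexp rbinom
NULL

#' Simulate a four-condition knockdown count matrix with planted genes
#'
#' Baseline means are drawn log-uniform in `[20, 2000]`; counts are
#' negative-binomial with variance `mu + dispersion * mu^2` (constant
#' dispersion across genes).  `n_planted_per_category` genes per
#' co-regulation category receive condition-specific mean multipliers
#' implementing that category's sign pattern:
#' NELFA-suppressed/YAP-activated genes go up `2^effect` in siNELFA,
#' down `2^-effect` in siYAP and are unchanged in the double knockdown;
#' the NELFA-activated/YAP-suppressed pattern is the mirror image;
#' co-suppressed (resp. co-activated) genes move `2^effect` (resp.
#' `2^-effect`) in both singles and 1.6x further in the same direction
#' in the double knockdown, placing the double-knockdown fold change a
#' clear margin beyond both singles relative to the estimation noise at
#' typical replicate counts.  Remaining genes are null (identical means
#' in all conditions).
#'
#' @param n_genes total genes (>= 4 x `n_planted_per_category`)
#' @param n_planted_per_category planted genes per category, default 50
#' @param effect_log2fc planted single-knockdown |log2FC|, default 2; a
#'   value below 1 cannot satisfy the category thresholds and triggers a
#'   warning
#' @param reps replicates per condition (>= 2), default 3
#' @param dispersion NB dispersion, default 0.05
#' @param seed integer seed; identical seed gives an identical matrix
#' @return list: `counts` (a [count_matrix()]) and `truth` (data.frame
#'   `gene_id`, `category`, `true_lfc_n`, `true_lfc_y`, `true_lfc_d`)
#' @export
simulate_counts <- function(n_genes, n_planted_per_category = 50,
                            effect_log2fc = 2, reps = 3,
                            dispersion = 0.05, seed = 1) {
  stopifnot(n_genes >= 4 * n_planted_per_category, reps >= 2,
            dispersion > 0, effect_log2fc > 0)
  if (effect_log2fc < 1)
    warning("effect_log2fc < 1 cannot satisfy the category thresholds")
  withr::with_seed(seed, {
    npc <- n_planted_per_category
    category <- rep(c(COREG_CATEGORIES[1:4], "none"),
                    c(rep(npc, 4), n_genes - 4 * npc))
    up <- 2^effect_log2fc; dn <- 2^-effect_log2fc
    double_margin <- 1.6
    mult <- matrix(1, n_genes, 4,
                   dimnames = list(NULL, KNOCKDOWN_CONDITIONS))
    i1 <- category == COREG_CATEGORIES[1]
    i2 <- category == COREG_CATEGORIES[2]
    i3 <- category == COREG_CATEGORIES[3]
    i4 <- category == COREG_CATEGORIES[4]
    mult[i1, c("siNELFA", "siYAP", "siNELFA_siYAP")] <- rep(c(up, dn, 1), each = npc)
    mult[i2, c("siNELFA", "siYAP", "siNELFA_siYAP")] <- rep(c(dn, up, 1), each = npc)
    mult[i3, c("siNELFA", "siYAP", "siNELFA_siYAP")] <-
      rep(c(up, up, double_margin * up), each = npc)
    mult[i4, c("siNELFA", "siYAP", "siNELFA_siYAP")] <-
      rep(c(dn, dn, dn / double_margin), each = npc)
    mu0 <- exp(runif(n_genes, log(20), log(2000)))
    samples <- data.frame(
      sample_id = paste0("S", seq_len(4 * reps)),
      condition = rep(KNOCKDOWN_CONDITIONS, each = reps),
      replicate = rep(seq_len(reps), 4))
    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                     samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- mu0 * mult[, samples$condition[j]]
      counts[, j] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    truth <- data.frame(
      gene_id = rownames(counts), category = category,
      true_lfc_n = log2(mult[, "siNELFA"]),
      true_lfc_y = log2(mult[, "siYAP"]),
      true_lfc_d = log2(mult[, "siNELFA_siYAP"]))
    list(counts = count_matrix(counts, samples), truth = truth)
  })
}

#' Toy transcript annotation for track simulation
#'
#' One chromosome, transcripts tiled at a fixed spacing with alternating
#' strands, sized so the promoter and gene-body windows always fit.
#'
#' @param n_genes number of transcripts
#' @param spacing tile spacing in bp, default 10000
#' @param length transcript length in bp, default 5000
#' @param chrom chromosome name
#' @return a [transcript_models()] data.frame
#' @export
toy_transcripts <- function(n_genes, spacing = 10000, length = 5000,
                            chrom = "chrS") {
  start <- spacing * seq_len(n_genes)
  transcript_models(chrom = chrom, start = start, end = start + length,
                    strand = rep(c("+", "-"), length.out = n_genes),
                    gene_id = sprintf("g%04d", seq_len(n_genes)),
                    transcript_id = sprintf("t%04d", seq_len(n_genes)))
}

#' Simulate ChIP/input/nascent tracks with planted occupancy loss
#'
#' Builds noiseless piecewise-constant tracks for a baseline and a
#' perturbed (factor-degraded) state.  The input track is flat at 1.0;
#' the baseline ChIP track equals the input times `peak_enrichment` over
#' the promoter window of each bound gene and equals the input
#' elsewhere; in the perturbed state the peak is removed for loss-flagged
#' genes.  Nascent signal is uniform over each gene body on the
#' transcript's strand and is multiplied by `output_fold` (increase) or
#' its inverse (decrease) in the perturbed state according to the gene's
#' planted output direction.
#'
#' @param transcripts non-overlapping [transcript_models()] (e.g.
#'   [toy_transcripts()]); transcripts too short for the gene-body
#'   window are skipped with a warning
#' @param bound_fraction fraction of genes with a promoter peak, in (0,1]
#' @param loss_fraction fraction of bound genes losing the peak when
#'   perturbed
#' @param peak_enrichment ChIP/input ratio at bound promoters (> 0)
#' @param output_fold output fold change for planted increase/decrease
#'   genes (> 0)
#' @param seed integer seed
#' @return list: `tracks` (named list of [signal_track()]s:
#'   `chip_baseline`, `chip_perturbed`, `input`, `nascent_plus_baseline`,
#'   `nascent_minus_baseline`, `nascent_plus_perturbed`,
#'   `nascent_minus_perturbed`), `truth` (data.frame `gene_id`, `bound`,
#'   `loss`, `output_dir`), and `transcripts` (the rows simulated)
#' @export
simulate_tracks <- function(transcripts, bound_fraction = 0.8,
                            loss_fraction = 0.5, peak_enrichment = 4,
                            output_fold = 1.3, seed = 1) {
  stopifnot(bound_fraction > 0, bound_fraction <= 1,
            loss_fraction >= 0, loss_fraction <= 1,
            peak_enrichment > 0, output_fold > 0)
  tx <- select_longest_transcript(transcripts)
  ok <- tx$length >= 2250 & tx$start >= 2250
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " transcript(s) too short for the gene-body window")
    tx <- tx[ok, , drop = FALSE]
  }
  w <- make_windows(tx)
  chromlen <- max(tx$end) + 10000
  chrom <- tx$chrom[1]
  withr::with_seed(seed, {
    n <- nrow(tx)
    bound <- runif(n) < bound_fraction
    loss <- bound & runif(n) < loss_fraction
    output_dir <- sample(c("up", "down", "none"), n, replace = TRUE,
                         prob = c(0.4, 0.3, 0.3))
    body_value <- runif(n, 0.5, 2)

    flat <- function(value) signal_track(chrom, 0, chromlen, value)
    peaks_track <- function(which_peak) {
      # background 1.0 everywhere, peak_enrichment over selected promoters
      ps <- sort(w$promoter_start[which_peak])
      pe <- sort(w$promoter_end[which_peak])
      if (!length(ps)) return(flat(1))
      starts <- c(0, pe); ends <- c(ps, chromlen)
      keep <- starts < ends
      signal_track(chrom,
                   c(starts[keep], ps), c(ends[keep], pe),
                   c(rep(1, sum(keep)), rep(peak_enrichment, length(ps))))
    }
    nascent_track <- function(strand, state) {
      i <- which(tx$strand == strand)
      if (!length(i)) return(flat(0))
      val <- body_value[i]
      if (state == "perturbed") {
        val <- val * ifelse(output_dir[i] == "up", output_fold,
                            ifelse(output_dir[i] == "down", 1 / output_fold, 1))
      }
      signal_track(chrom, w$body_start[i], w$body_end[i], val)
    }
    tracks <- list(
      chip_baseline = peaks_track(bound),
      chip_perturbed = peaks_track(bound & !loss),
      input = flat(1),
      nascent_plus_baseline = nascent_track("+", "baseline"),
      nascent_minus_baseline = nascent_track("-", "baseline"),
      nascent_plus_perturbed = nascent_track("+", "perturbed"),
      nascent_minus_perturbed = nascent_track("-", "perturbed"))
    truth <- data.frame(gene_id = tx$gene_id, bound = bound, loss = loss,
                        output_dir = output_dir)
    list(tracks = tracks, truth = truth, transcripts = tx)
  })
}

#' Simulate a clinical cohort with group-specific hazards
#'
#' Each patient is assigned a YAP-high and a NELFA-high flag (fair
#' coins), defining the four joint marker groups.  Marker percents come
#' from a two-component mixture (low: uniform 0-10; high: uniform
#' 40-100) and intensities from {1,2} (low) or {2,3} (high), so the
#' composite score separates the planted groups.  Survival times are
#' exponential with the patient's group hazard (per month); censoring is
#' administrative at `censor_months` combined with uniform dropout.
#' Disease-free survival is drawn the same way at 1.2x the hazard.
#'
#' @param n cohort size (>= 20)
#' @param subtype_props length-3 proportions (ER+, HER2+, TNBC) summing
#'   to 1; zero entries allowed
#' @param group_hazards named monthly hazards for
#'   `HighYAP_HighNELFA`, `HighYAP_LowNELFA`, `LowYAP_HighNELFA`,
#'   `LowYAP_LowNELFA` (all > 0); equal hazards give a null cohort
#' @param censor_months administrative censoring horizon
#' @param seed integer seed
#' @return list: `records` (a [clinical_table()]) and `truth`
#'   (data.frame `patient_id`, `group`, `hazard`)
#' @export
simulate_cohort <- function(n, subtype_props = c(0.41, 0.27, 0.32),
                            group_hazards = c(HighYAP_HighNELFA = 0.030,
                                              HighYAP_LowNELFA = 0.020,
                                              LowYAP_HighNELFA = 0.012,
                                              LowYAP_LowNELFA = 0.008),
                            censor_months = 60, seed = 1) {
  stopifnot(n >= 20, all(group_hazards > 0), censor_months >= 0,
            abs(sum(subtype_props) - 1) < 1e-8)
  groups <- c("HighYAP_HighNELFA", "HighYAP_LowNELFA",
              "LowYAP_HighNELFA", "LowYAP_LowNELFA")
  if (!all(groups %in% names(group_hazards)))
    stop("group_hazards must name all four YAP x NELFA groups")
  withr::with_seed(seed, {
    yap_high <- runif(n) < 0.5
    nelfa_high <- runif(n) < 0.5
    group <- ifelse(yap_high & nelfa_high, groups[1],
             ifelse(yap_high, groups[2],
             ifelse(nelfa_high, groups[3], groups[4])))
    draw_pct <- function(high)
      ifelse(high, runif(n, 40, 100), runif(n, 0, 10))
    draw_int <- function(high)
      ifelse(high, sample(2:3, n, replace = TRUE),
             sample(1:2, n, replace = TRUE))
    hz <- group_hazards[group]
    sim_endpoint <- function(hazard) {
      t_event <- rexp(n, rate = hazard)
      t_cens <- pmin(censor_months, runif(n, 0, 2 * max(censor_months, 1e-9)))
      if (censor_months == 0) t_cens <- rep(0, n)
      time <- pmin(t_event, t_cens)
      list(time = time, event = as.integer(t_event <= t_cens & censor_months > 0))
    }
    os <- sim_endpoint(hz)
    dfs <- sim_endpoint(hz * 1.2)
    records <- clinical_table(data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      subtype = sample(.BREAST_SUBTYPES, n, replace = TRUE,
                       prob = subtype_props),
      yap_percent = round(draw_pct(yap_high), 1),
      nelfa_percent = round(draw_pct(nelfa_high), 1),
      yap_intensity = draw_int(yap_high),
      nelfa_intensity = draw_int(nelfa_high),
      os_months = os$time, os_event = os$event,
      dfs_months = dfs$time, dfs_event = dfs$event))
    truth <- data.frame(patient_id = records$patient_id, group = group,
                        hazard = unname(hz))
    list(records = records, truth = truth)
  })
}
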
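# Small in-code fixtures shared across test files.

# 3 genes x 12 samples, 4 conditions x 3 replicates, written to disk
write_counts_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  samples <- data.frame(
    sample_id = paste0("S", 1:12),
    condition = rep(KNOCKDOWN_CONDITIONS, each = 3),
    replicate = rep(1:3, 4))
  counts <- matrix(seq_len(36) * 3L, nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), samples$sample_id))
  m <- count_matrix(counts, samples)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.csv"))
  write_counts(m, paths$counts, paths$samples)
  list(m = m, paths = paths, dir = dir)
}

write_bedgraph <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "track.bedGraph")
  writeLines(lines, path)
  path
}

# independent running-sum oracle for the GSEA statistic: explicit loop,
# no shared code with gsea_es()
gsea_es_oracle <- function(gene_id, score, set, weight = 1) {
  N <- length(gene_id)
  hit <- gene_id %in% set
  nh <- sum(hit)
  nr <- sum(abs(score[hit])^weight)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) run <- run + abs(score[i])^weight / nr
    else run <- run - 1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# truth-derived expected pausing call, restating the caller's contract
expected_pausing_call <- function(truth) {
  ifelse(!truth$bound, "not_retained",
  ifelse(truth$loss & truth$output_dir == "up", "coordinated_loss_up",
  ifelse(truth$output_dir == "down", "output_down", "unchanged")))
}

# simple cohort for clinical tests
tiny_cohort <- function(n = 8) {
  clinical_table(data.frame(
    patient_id = paste0("P", seq_len(n)),
    subtype = rep(c("ER+", "HER2+", "TNBC", "ER+"), length.out = n),
    yap_percent = rep(c(80, 5), length.out = n),
    nelfa_percent = rep(c(60, 2), length.out = n),
    yap_intensity = rep(c(3, 1), length.out = n),
    nelfa_intensity = rep(c(2, 1), length.out = n),
    os_months = seq_len(n) * 5,
    dfs_months = seq_len(n) * 4,
    os_event = rep(c(1, 0), length.out = n),
    dfs_event = rep(c(0, 1), length.out = n)))
}
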
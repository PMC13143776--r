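test_that("count matrix round-trips through TSV + sample sheet", {
  fx <- write_counts_fixture()
  m2 <- read_counts(fx$paths$counts, fx$paths$samples)
  expect_identical(dim(m2$counts), c(3L, 12L))
  expect_equal(m2$counts, fx$m$counts)
  expect_equal(m2$samples$condition, fx$m$samples$condition)
})

test_that("count matrix validation catches bad sheets and counts", {
  fx <- write_counts_fixture()
  sheet <- read.csv(fx$paths$samples)
  sheet$sample_id[12] <- "S13"
  bad_sheet <- file.path(fx$dir, "bad.csv")
  write.csv(sheet, bad_sheet, row.names = FALSE)
  expect_error(read_counts(fx$paths$counts, bad_sheet), "sample missing")

  counts <- fx$m$counts
  counts[1, 1] <- -2
  expect_error(count_matrix(counts, fx$m$samples), "negative count")
  counts[1, 1] <- 1.5
  expect_error(count_matrix(counts, fx$m$samples), "non-integer")
  sheet2 <- fx$m$samples
  sheet2$condition[1] <- "siFOO"
  expect_error(count_matrix(fx$m$counts, sheet2), "unknown condition")
})

test_that("GTF transcripts convert to 0-based half-open; BED6 is native", {
  dir <- withr::local_tempdir()
  gtf <- file.path(dir, "x.gtf")
  writeLines(paste0("chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "t1";'), gtf)
  ts <- read_transcripts(gtf)
  expect_equal(ts$start, 100)
  expect_equal(ts$end, 200)
  expect_equal(ts$length, 100)

  bed <- file.path(dir, "x.bed")
  writeLines("chr1\t100\t200\tg1|t1\t0\t-", bed)
  tb <- read_transcripts(bed)
  expect_equal(tb$start, 100)
  expect_equal(tb$end, 200)
  expect_equal(tb$strand, "-")

  # round trip through BED preserves the internal convention exactly
  bed2 <- file.path(dir, "rt.bed")
  write_transcripts_bed(ts, bed2)
  ts2 <- read_transcripts(bed2)
  expect_equal(ts2[c("chrom", "start", "end", "strand")],
               ts[c("chrom", "start", "end", "strand")])

  bad <- file.path(dir, "bad.gtf")
  writeLines(paste0("chr1\tsrc\ttranscript\t300\t200\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "t1";'), bad)
  expect_error(read_transcripts(bad))
  writeLines("chr1\t100\t200\tg1|t1\t0\t?", bed)
  expect_error(read_transcripts(bed), "strand")
})

test_that("signal tracks: window means, empty-region zeros, overlap rejection", {
  path <- write_bedgraph("chr1\t0\t100\t2.0")
  tr <- read_track(path)
  expect_equal(track_mean(tr, "chr1", 0, 100), 2.0)
  # uncovered bases count as 0 and stay in the denominator
  expect_equal(track_mean(tr, "chr1", 150, 250), 0)
  expect_equal(track_mean(tr, "chr1", 50, 150), 1.0)
  expect_equal(track_mean(tr, "chr1", 0, 100, summary = "sum"), 200)

  expect_error(signal_track(c("chr1", "chr1"), c(0, 25), c(50, 75), c(1, 3)),
               "overlapping intervals")
  # unsorted but disjoint input is sorted internally, not rejected
  tr2 <- signal_track(c("chr1", "chr1"), c(50, 0), c(100, 50), c(3, 1))
  expect_equal(track_mean(tr2, "chr1", 0, 100), 2.0)
})

test_that("signal tracks round-trip through bedGraph within 1e-9", {
  dir <- withr::local_tempdir()
  tr <- signal_track("chr1", c(0, 100, 500), c(100, 300, 600),
                     c(1.25, 0.333333333, 7))
  path <- file.path(dir, "rt.bedGraph")
  write_track(tr, path)
  tr2 <- read_track(path)
  for (w in list(c(0, 100), c(50, 250), c(400, 600)))
    expect_equal(track_mean(tr2, "chr1", w[1], w[2]),
                 track_mean(tr, "chr1", w[1], w[2]), tolerance = 1e-9)
})

test_that("GMT collections: dedup, duplicate names, round trip", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("S1\tdesc\tg1\tg2\tg2", "S2\tdesc\tg3"), gmt)
  sets <- read_gene_sets(gmt)
  expect_equal(sets$S1, c("g1", "g2"))

  writeLines(c("S1\td\tg1", "S1\td\tg2"), gmt)
  expect_error(read_gene_sets(gmt), "duplicate set name")
  writeLines("S1\td", gmt)
  expect_error(read_gene_sets(gmt), "0 members")

  # a 56-member curated signature round-trips with its size intact
  sig <- list(YAP_signature = paste0("y", 1:56))
  write_gene_sets(sig, gmt)
  back <- read_gene_sets(gmt)
  expect_length(back$YAP_signature, 56)
})

test_that("clinical table validation enforces ranges and binary events", {
  df <- tiny_cohort()
  expect_s3_class(df, "clinical_table")
  bad <- df; bad$yap_intensity[1] <- 4
  expect_error(clinical_table(bad), "0..3")
  bad <- df; bad$dfs_event[1] <- NA
  expect_error(clinical_table(bad), "event required")
  bad <- df; bad$nelfa_percent[1] <- 150
  expect_error(clinical_table(bad), "\\[0,100\\]")
  bad <- df; bad$os_months[1] <- -1
  expect_error(clinical_table(bad), "non-negative")

  dir <- withr::local_tempdir()
  path <- file.path(dir, "cohort.csv")
  write_clinical(df, path)
  df2 <- read_clinical(path)
  expect_equal(df2$patient_id, df$patient_id)
  expect_equal(df2$yap_percent, df$yap_percent)
})
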
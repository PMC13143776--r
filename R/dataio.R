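#' @importFrom utils read.delim read.csv write.csv write.table read.table
#' @importFrom stats median setNames
NULL

#' Conditions of the four-arm knockdown design
#'
#' Sample labels for the siRNA experiment: non-targeting control, NELFA
#' knockdown, YAP knockdown, and the double knockdown.
#' @export
KNOCKDOWN_CONDITIONS <- c("siControl", "siNELFA", "siYAP", "siNELFA_siYAP")

#' Construct a validated count matrix
#'
#' Bundles a genes x samples matrix of raw counts with its sample sheet
#' (condition and replicate per sample).  All counts must be non-negative
#' integers, gene identifiers unique, and every sample assigned one of the
#' four knockdown conditions.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `replicate`; one row per column of `counts`, in display order.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("gene ids must be present and unique")
  if (is.null(colnames(counts))) stop("sample ids missing from count matrix")
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns sample_id, condition, replicate")
  missing <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing))
    stop("sample missing from count matrix: ", paste(missing, collapse = ", "))
  counts <- counts[, as.character(samples$sample_id), drop = FALSE]
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and complete")
  if (any(counts < 0)) stop("negative count")
  if (any(counts != round(counts))) stop("non-integer count")
  bad <- setdiff(unique(samples$condition), KNOCKDOWN_CONDITIONS)
  if (length(bad))
    stop("unknown condition label: ", paste(bad, collapse = ", "))
  if (any(samples$replicate < 1) || any(samples$replicate != round(samples$replicate)))
    stop("replicate must be a positive integer")
  structure(list(counts = counts, samples = as.data.frame(samples)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(table(x$samples$condition))
  invisible(x)
}

#' Read a count matrix and its sample sheet
#'
#' @param counts_path TSV with a header row of sample ids and gene ids in
#'   the first column.
#' @param samples_path CSV sample sheet with columns `sample_id`,
#'   `condition`, `replicate`.  The returned sample order follows the sheet.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  sheet <- read.csv(samples_path, check.names = FALSE)
  count_matrix(counts, sheet)
}

#' Write a count matrix and sample sheet
#'
#' Inverse of [read_counts()]; round trips exactly.
#' @param m a `count_matrix`
#' @param counts_path,samples_path output paths
#' @export
write_counts <- function(m, counts_path, samples_path) {
  out <- data.frame(gene_id = rownames(m$counts), m$counts,
                    check.names = FALSE)
  write.table(out, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(m$samples, samples_path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

## ---- transcript models -----------------------------------------------------

#' Construct transcript models (0-based half-open)
#'
#' One record per transcript.  All genomic intervals in this package use a
#' single convention: 0-based, half-open `[start, end)`.
#'
#' @param chrom,start,end,strand,gene_id,transcript_id parallel vectors.
#' @return data.frame of class `transcript_models` with a `length` column.
#' @export
transcript_models <- function(chrom, start, end, strand, gene_id, transcript_id) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   gene_id = as.character(gene_id),
                   transcript_id = as.character(transcript_id),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("incomplete transcript record")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("invalid interval: need 0 <= start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("unknown strand character")
  if (anyDuplicated(df$transcript_id)) stop("duplicate transcript_id")
  df$length <- df$end - df$start
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Read transcript annotations from GTF or BED6
#'
#' GTF records of feature type `transcript` (1-based closed coordinates,
#' `gene_id`/`transcript_id` attributes) or BED6 with the name field
#' `gene_id|transcript_id` (already 0-based half-open).  Everything is
#' converted to the internal 0-based half-open convention on read.
#'
#' @param path annotation file; format chosen by extension
#'   (`.gtf`/`.gff` vs `.bed`).
#' @return a [transcript_models()] data.frame.
#' @export
read_transcripts <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff")) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "transcript"]
    if (!length(gr)) stop("no transcript records in GTF")
    if (anyNA(gr$gene_id) || anyNA(gr$transcript_id))
      stop("malformed attribute string: gene_id/transcript_id required")
    strand <- as.character(GenomicRanges::strand(gr))
    transcript_models(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = strand,
      gene_id = gr$gene_id, transcript_id = gr$transcript_id)
  } else if (ext == "bed") {
    bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(bed) < 6) stop("BED6 requires 6 columns")
    ids <- strsplit(bed[[4]], "|", fixed = TRUE)
    if (any(lengths(ids) != 2))
      stop("BED name must be gene_id|transcript_id")
    transcript_models(
      chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
      strand = bed[[6]],
      gene_id = vapply(ids, `[`, "", 1L),
      transcript_id = vapply(ids, `[`, "", 2L))
  } else stop("unsupported annotation format: ", ext)
}

#' Write transcript models as BED6
#'
#' @param ts a `transcript_models` data.frame
#' @param path output path
#' @export
write_transcripts_bed <- function(ts, path) {
  out <- data.frame(ts$chrom, ts$start, ts$end,
                    paste(ts$gene_id, ts$transcript_id, sep = "|"),
                    0L, ts$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

## ---- signal tracks ---------------------------------------------------------

#' Construct a piecewise-constant signal track
#'
#' Intervals are 0-based half-open and must not overlap within a
#' chromosome; uncovered bases count as signal 0 in window means.
#'
#' @param chrom,start,end,value parallel vectors describing constant-value
#'   intervals.
#' @return A `signal_track` object (wrapped `GRanges` with a `score`).
#' @export
signal_track <- function(chrom, start, end, value) {
  value <- as.numeric(value)
  if (anyNA(value) || any(!is.finite(value))) stop("non-numeric value in track")
  if (any(start < 0) || any(start >= end)) stop("invalid track interval")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    score = value)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  if (length(hits) > length(gr)) stop("overlapping intervals")
  gr <- sort(gr)
  structure(list(gr = gr), class = "signal_track")
}

#' Read a signal track (bedGraph, optionally BigWig)
#'
#' bedGraph is the required, bit-exact plain-text surface; BigWig files
#' (`.bw`/`.bigwig`) are accepted behind the same contract where the
#' binary format is available.
#'
#' @param path bedGraph (4 columns, 0-based half-open) or BigWig file
#' @return a [signal_track()]
#' @export
read_track <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("bw", "bigwig")) "BigWig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  signal_track(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               gr$score)
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`
#' @param path output path
#' @export
write_track <- function(track, path) {
  gr <- track$gr
  out <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr),
                    gr$score)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Mean signal over a genomic window
#'
#' Bases not covered by any interval contribute 0 and are included in the
#' denominator, matching coverage-track semantics.
#'
#' @param track a `signal_track`
#' @param chrom chromosome name
#' @param start,end window, 0-based half-open
#' @param summary `"mean"` (default) or `"sum"` of per-base signal
#' @return numeric scalar
#' @export
track_mean <- function(track, chrom, start, end, summary = c("mean", "sum")) {
  summary <- match.arg(summary)
  if (start >= end) stop("empty window")
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(win, track$gr)
  total <- 0
  if (length(hits)) {
    seg <- GenomicRanges::pintersect(
      track$gr[S4Vectors::subjectHits(hits)],
      rep(win, length(hits)))
    total <- sum(GenomicRanges::width(seg) * seg$score)
  }
  if (summary == "sum") total else total / (end - start)
}

## ---- gene sets (GMT) -------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then members.  Duplicate
#' members within a set are collapsed; duplicate set names and empty sets
#' are rejected.
#'
#' @param path GMT file
#' @return named list of character vectors with a `description` attribute
#'   (class `gene_set_collection`)
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("set with 0 members")
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate set name")
  desc <- vapply(fields, `[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(sets) == 0)) stop("set with 0 members")
  names(sets) <- nm
  attr(sets, "description") <- setNames(desc, nm)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute)
#' @param path output path
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(n)
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(NULL)
}

## ---- clinical records ------------------------------------------------------

.BREAST_SUBTYPES <- c("ER+", "HER2+", "TNBC")

#' Validate a clinical cohort table
#'
#' @param df data.frame with columns `patient_id`, `subtype`,
#'   `yap_percent`, `nelfa_percent`, `yap_intensity`, `nelfa_intensity`,
#'   `os_months`, `dfs_months`, `os_event`, `dfs_event`; further covariate
#'   columns (grade, cT, cN, NACT, pCR...) are carried through and may
#'   contain missing values (excluded per-test downstream).
#' @return the validated data.frame, class `clinical_table`
#' @export
clinical_table <- function(df) {
  req <- c("patient_id", "subtype", "yap_percent", "nelfa_percent",
           "yap_intensity", "nelfa_intensity",
           "os_months", "dfs_months", "os_event", "dfs_event")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing clinical columns: ", paste(miss, collapse = ", "))
  if (!all(df$subtype %in% .BREAST_SUBTYPES))
    stop("subtype must be one of ", paste(.BREAST_SUBTYPES, collapse = ", "))
  for (col in c("yap_percent", "nelfa_percent")) {
    v <- df[[col]]
    if (anyNA(v) || any(v < 0 | v > 100)) stop(col, " must lie in [0,100]")
  }
  for (col in c("yap_intensity", "nelfa_intensity")) {
    v <- df[[col]]
    if (anyNA(v) || !all(v %in% 0:3)) stop(col, " must be an integer in 0..3")
  }
  for (col in c("os_months", "dfs_months")) {
    v <- df[[col]]
    if (anyNA(v) || any(v < 0)) stop(col, " must be non-negative")
  }
  for (col in c("os_event", "dfs_event")) {
    v <- df[[col]]
    if (anyNA(v)) stop("event required: ", col)
    if (!all(v %in% c(0, 1))) stop(col, " must be 0/1")
  }
  df <- as.data.frame(df)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical cohort CSV
#' @param path CSV with the [clinical_table()] columns; row order preserved
#' @return a `clinical_table`
#' @export
read_clinical <- function(path) {
  clinical_table(read.csv(path, check.names = FALSE))
}

#' Write a clinical cohort CSV
#' @param df a `clinical_table`
#' @param path output path
#' @export
write_clinical <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
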
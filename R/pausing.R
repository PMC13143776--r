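#' Pick the longest transcript per gene
#'
#' Per gene, the transcript maximizing `end - start`; ties go to the
#' lexicographically smallest transcript id.
#'
#' @param ts a [transcript_models()] data.frame
#' @return `transcript_models` with one row per gene
#' @export
select_longest_transcript <- function(ts) {
  o <- order(ts$gene_id, -ts$length, ts$transcript_id, method = "radix")
  ts <- ts[o, , drop = FALSE]
  out <- ts[!duplicated(ts$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter and gene-body windows around the TSS
#'
#' The TSS is the transcript start for + strand and `end - 1` for -
#' strand (0-based).  The promoter window is TSS +/- 150 bp, symmetric in
#' genomic coordinates (width 300, half-open).  The gene-body window is
#' strand-directional, 250 to 2250 bp downstream of the TSS along the
#' direction of transcription (width 2000).  Windows extending below
#' coordinate 0 are an error.
#'
#' @param ts a [transcript_models()] data.frame (typically one row per
#'   gene from [select_longest_transcript()])
#' @param promoter_half,body_from,body_to window geometry in bp; defaults
#'   150, 250, 2250
#' @return data.frame: `gene_id`, `chrom`, `strand`, `tss`,
#'   `promoter_start`, `promoter_end`, `body_start`, `body_end`
#' @export
make_windows <- function(ts, promoter_half = 150, body_from = 250,
                         body_to = 2250) {
  tss <- ifelse(ts$strand == "+", ts$start, ts$end - 1L)
  prom_s <- tss - promoter_half
  prom_e <- tss + promoter_half
  body_s <- ifelse(ts$strand == "+", tss + body_from, tss - body_to + 1L)
  body_e <- ifelse(ts$strand == "+", tss + body_to, tss - body_from + 1L)
  if (any(prom_s < 0) || any(body_s < 0)) stop("window out of bounds")
  data.frame(gene_id = ts$gene_id, chrom = ts$chrom, strand = ts$strand,
             tss = tss,
             promoter_start = prom_s, promoter_end = prom_e,
             body_start = body_s, body_end = body_e,
             row.names = NULL)
}

#' Promoter enrichment: log2(ChIP/Input) over a window
#'
#' Window means of the ChIP and matched input tracks, each stabilized
#' with a small epsilon so the ratio is always finite.
#'
#' @param chip,input [signal_track()]s
#' @param chrom,start,end the promoter window (0-based half-open)
#' @param eps stabilizer added to both means, default 1e-3
#' @param summary window summary passed to [track_mean()]
#' @return log2 ratio
#' @export
promoter_enrichment <- function(chip, input, chrom, start, end,
                                eps = 1e-3, summary = "mean") {
  log2((track_mean(chip, chrom, start, end, summary) + eps) /
       (track_mean(input, chrom, start, end, summary) + eps))
}

#' Gene-body nascent-transcription output
#'
#' Strand-specific nascent signal is extracted from the plus and minus
#' tracks over the gene-body window and summed (strands combined, not
#' averaged) to give total output.
#'
#' @param plus,minus [signal_track()]s for the two strands
#' @param chrom,start,end the gene-body window (0-based half-open)
#' @param summary window summary passed to [track_mean()]
#' @return combined mean signal
#' @export
genebody_output <- function(plus, minus, chrom, start, end,
                            summary = "mean") {
  track_mean(plus, chrom, start, end, summary) +
    track_mean(minus, chrom, start, end, summary)
}

#' Call retention and coordinated pausing changes
#'
#' A promoter is retained when its baseline enrichment exceeds
#' `retention_threshold` (log2 ChIP/Input > 0.5, about 1.4-fold over
#' input).  Occupancy loss at a retained promoter is called when the
#' perturbed enrichment either drops below the retention threshold or
#' falls by at least `loss_drop` log2 units from baseline — degron
#' datasets report complete loss at strong promoters that still retain
#' up to ~2-fold residual enrichment, which an absolute threshold alone
#' would miss.  Among retained genes: `coordinated_loss_up` when
#' occupancy is lost and gene-body output increases; `output_down` when
#' output decreases; otherwise `unchanged`.  `min_fold` optionally
#' requires a minimum fold change in output (default 1: any
#' increase/decrease counts, matching the small output shifts seen in
#' degron data).
#'
#' @param quant data.frame with columns `gene_id`,
#'   `promoter_enrichment_baseline`, `promoter_enrichment_perturbed`,
#'   `genebody_output_baseline`, `genebody_output_perturbed`
#' @param retention_threshold log2 enrichment cutoff, default 0.5
#' @param min_fold minimum output fold change, default 1
#' @param loss_drop minimum log2 occupancy drop also counted as loss,
#'   default 1.5 (at most ~35% of baseline occupancy remains)
#' @return the input with `retained_baseline` and `call` columns
#' @export
call_pausing <- function(quant, retention_threshold = 0.5, min_fold = 1,
                         loss_drop = 1.5) {
  req <- c("gene_id", "promoter_enrichment_baseline",
           "promoter_enrichment_perturbed",
           "genebody_output_baseline", "genebody_output_perturbed")
  miss <- setdiff(req, names(quant))
  if (length(miss)) stop("missing quantification columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(quant[req])) stop("gene present in only one state")
  retained <- quant$promoter_enrichment_baseline > retention_threshold
  up <- quant$genebody_output_perturbed >
    quant$genebody_output_baseline * min_fold
  down <- quant$genebody_output_perturbed * min_fold <
    quant$genebody_output_baseline
  lost <- quant$promoter_enrichment_perturbed < retention_threshold |
    (quant$promoter_enrichment_baseline -
       quant$promoter_enrichment_perturbed) >= loss_drop
  call <- rep("unchanged", nrow(quant))
  call[down] <- "output_down"
  call[lost & up] <- "coordinated_loss_up"
  call[!retained] <- "not_retained"
  quant$retained_baseline <- retained
  quant$call <- factor(call, levels = c("coordinated_loss_up", "output_down",
                                        "unchanged", "not_retained"))
  quant
}

#' Quantify pausing from annotation and tracks, then call changes
#'
#' Convenience wrapper: longest transcript per gene, window construction,
#' promoter enrichment and gene-body output in both states, then
#' [call_pausing()].
#'
#' @param ts a [transcript_models()] data.frame
#' @param chip_baseline,chip_perturbed,input ChIP and input
#'   [signal_track()]s
#' @param plus_baseline,minus_baseline,plus_perturbed,minus_perturbed
#'   strand-specific nascent-transcription tracks in both states
#' @param eps,retention_threshold,min_fold,loss_drop,summary tuning
#'   knobs, see [promoter_enrichment()] and [call_pausing()]
#' @return a called quantification data.frame (one row per gene)
#' @export
quantify_pausing <- function(ts, chip_baseline, chip_perturbed, input,
                             plus_baseline, minus_baseline,
                             plus_perturbed, minus_perturbed,
                             eps = 1e-3, retention_threshold = 0.5,
                             min_fold = 1, loss_drop = 1.5,
                             summary = "mean") {
  w <- make_windows(select_longest_transcript(ts))
  quant <- data.frame(
    gene_id = w$gene_id,
    promoter_enrichment_baseline = vapply(seq_len(nrow(w)), function(i)
      promoter_enrichment(chip_baseline, input, w$chrom[i],
                          w$promoter_start[i], w$promoter_end[i],
                          eps, summary), numeric(1)),
    promoter_enrichment_perturbed = vapply(seq_len(nrow(w)), function(i)
      promoter_enrichment(chip_perturbed, input, w$chrom[i],
                          w$promoter_start[i], w$promoter_end[i],
                          eps, summary), numeric(1)),
    genebody_output_baseline = vapply(seq_len(nrow(w)), function(i)
      genebody_output(plus_baseline, minus_baseline, w$chrom[i],
                      w$body_start[i], w$body_end[i], summary), numeric(1)),
    genebody_output_perturbed = vapply(seq_len(nrow(w)), function(i)
      genebody_output(plus_perturbed, minus_perturbed, w$chrom[i],
                      w$body_start[i], w$body_end[i], summary), numeric(1)))
  call_pausing(quant, retention_threshold, min_fold, loss_drop)
}
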
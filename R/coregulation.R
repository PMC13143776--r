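#' Co-regulation categories
#'
#' The four mutually exclusive modes of joint regulation by NELFA and
#' YAP, read off the three knockdown log2 fold changes, plus `none`.
#' @export
COREG_CATEGORIES <- c("NELFA_suppressed_YAP_activated",
                      "NELFA_activated_YAP_suppressed",
                      "co_suppressed", "co_activated", "none")

#' Classify a gene from its three knockdown log2 fold changes
#'
#' Category conditions on (`fc_n`, `fc_y`, `fc_d`) = log2FC in the
#' NELFA, YAP and double knockdowns versus control:
#' \itemize{
#'   \item NELFA-suppressed / YAP-activated: `fc_n >= +1`, `fc_y <= -1`,
#'     and the double knockdown unchanged (`-1 < fc_d < +1`);
#'   \item NELFA-activated / YAP-suppressed: the mirror image;
#'   \item co-suppressed: `fc_n >= +1`, `fc_y >= +1`, and the double
#'     knockdown at least as elevated as either single
#'     (`fc_d >= max(fc_n, fc_y)`);
#'   \item co-activated: the mirror image (`fc_d <= min(fc_n, fc_y)`).
#' }
#' Boundary values use the non-strict thresholds (`>= +1`, `<= -1`) with
#' a strict interior for the "unchanged" double-knockdown band.  Any
#' other pattern is `none`.  Vectorized.
#'
#' @param fc_n,fc_y,fc_d finite log2 fold changes
#' @return factor with levels [COREG_CATEGORIES]
#' @export
classify_gene <- function(fc_n, fc_y, fc_d) {
  if (any(!is.finite(fc_n) | !is.finite(fc_y) | !is.finite(fc_d)))
    stop("non-finite log2 fold change")
  cat1 <- fc_n >= 1 & fc_y <= -1 & fc_d > -1 & fc_d < 1
  cat2 <- fc_n <= -1 & fc_y >= 1 & fc_d > -1 & fc_d < 1
  cat3 <- fc_n >= 1 & fc_y >= 1 & fc_d >= pmax(fc_n, fc_y)
  cat4 <- fc_n <= -1 & fc_y <= -1 & fc_d <= pmin(fc_n, fc_y)
  out <- rep("none", length(fc_n))
  out[cat1] <- COREG_CATEGORIES[1]
  out[cat2] <- COREG_CATEGORIES[2]
  out[cat3] <- COREG_CATEGORIES[3]
  out[cat4] <- COREG_CATEGORIES[4]
  factor(out, levels = COREG_CATEGORIES)
}

#' Classify every gene of a contrast table
#'
#' A gene enters the classifier only if it is significant (`p < alpha`)
#' in both single-knockdown contrasts — the weakest gate under which all
#' four categories are defined; gated-out genes are `none`.
#'
#' @param tab a [contrast_table()] with all three contrasts
#' @param alpha significance gate, default 0.05
#' @return data.frame: `gene_id`, `category`, `fc_n`, `fc_y`, `fc_d`,
#'   `gated` (TRUE if the gene passed the significance gate)
#' @export
classify_all <- function(tab, alpha = 0.05) {
  if (!nrow(tab))
    return(data.frame(gene_id = character(), category = character(),
                      fc_n = numeric(), fc_y = numeric(), fc_d = numeric(),
                      gated = logical()))
  for (cc in CONTRASTS)
    if (!cc %in% tab$contrast) stop("missing contrast: ", cc)
  n <- .contrast_slice(tab, "siNELFA")
  y <- .contrast_slice(tab, "siYAP")
  d <- .contrast_slice(tab, "siNELFA_siYAP")
  genes <- n$gene_id
  iy <- match(genes, y$gene_id); id <- match(genes, d$gene_id)
  if (anyNA(iy) || anyNA(id)) stop("contrasts cover different gene sets")
  if (!length(genes))
    return(data.frame(gene_id = character(), category = character(),
                      fc_n = numeric(), fc_y = numeric(), fc_d = numeric(),
                      gated = logical()))
  gated <- n$p < alpha & y$p[iy] < alpha
  category <- classify_gene(n$log2FC, y$log2FC[iy], d$log2FC[id])
  category[!gated] <- "none"
  data.frame(gene_id = genes, category = category,
             fc_n = n$log2FC, fc_y = y$log2FC[iy], fc_d = d$log2FC[id],
             gated = gated, row.names = NULL)
}

#' Exact Venn region cardinalities for 2-4 gene sets
#'
#' Every region of the Venn partition (2^k - 1 membership signatures)
#' gets its exclusive cardinality; signature `"110"` means "in set 1 and
#' set 2 but not set 3", in the order of `sets`.
#'
#' @param sets named list of 2-4 character vectors
#' @return list with `regions` (named integer vector over signatures)
#'   and `totals` (per-set sizes)
#' @export
overlap_counts <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) stop("need 2-4 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("duplicate set name")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1, function(row) paste(as.integer(row), collapse = ""))
  all_sigs <- vapply(1:(2^k - 1), function(i) {
    bits <- as.integer(intToBits(i))[k:1]  # intToBits is little-endian
    paste(bits, collapse = "")
  }, "")
  regions <- setNames(integer(length(all_sigs)), all_sigs)
  tb <- table(sig)
  regions[names(tb)] <- as.integer(tb)
  list(regions = regions,
       totals = setNames(lengths(sets), names(sets)))
}

#' Write category calls as TSV
#' @param calls a [classify_all()] result
#' @param path output path
#' @export
write_category_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write Venn region counts as JSON keyed by region signature
#' @param ov an [overlap_counts()] result
#' @param path output path
#' @export
write_overlaps_json <- function(ov, path) {
  jsonlite::write_json(list(regions = as.list(ov$regions),
                            totals = as.list(ov$totals)),
                       path, auto_unbox = TRUE)
  invisible(NULL)
}
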
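#' @importFrom stats var pt pnorm
NULL

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes
#' expressed in every sample, of the ratio of the gene's count to its
#' geometric mean across samples.  Factors are rescaled to geometric
#' mean 1 so identical libraries get factor 1 exactly.
#'
#' @param m a [count_matrix()]
#' @return named numeric vector of positive factors, one per sample
#' @export
size_factors <- function(m) {
  k <- m$counts
  keep <- rowSums(k > 0) == ncol(k)
  if (!any(keep)) stop("cannot normalize: no gene expressed in all samples")
  k <- k[keep, , drop = FALSE]
  loggeo <- rowMeans(log(k))
  sf <- apply(k, 2, function(col) median(exp(log(col) - loggeo)))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m$counts))
}

.norm_counts <- function(m) {
  sweep(m$counts, 2, size_factors(m), "/")
}

#' Test one knockdown-vs-control contrast
#'
#' Minimal differential-expression stage with the standard contract
#' (per-gene log2 fold change, nominal p, base mean) but deliberately
#' none of the machinery of a full DE package: no shrinkage, no outlier
#' or independent filtering.  log2FC = log2((mean normalized treated +
#' 0.5) / (mean normalized control + 0.5)).  The p-value comes from a
#' Wald statistic on the log2 difference of group means, with a
#' method-of-moments negative-binomial variance per group (Poisson
#' fallback when the sample variance does not exceed the mean) and a
#' Student-t reference with n_t + n_c - 2 degrees of freedom, which is
#' calibrated at the 2-3 replicates typical of these designs.
#'
#' @param m a [count_matrix()]
#' @param treated,control condition labels, each with >= 2 replicates
#' @return data.frame: `gene_id`, `log2FC`, `p`, `base_mean`
#' @export
test_contrast <- function(m, treated, control) {
  cond <- m$samples$condition
  for (cc in c(treated, control)) {
    if (!cc %in% cond) stop("condition absent: ", cc)
    if (sum(cond == cc) < 2) stop("single replicate in condition ", cc)
  }
  nc <- .norm_counts(m)
  A <- nc[, cond == treated, drop = FALSE]
  B <- nc[, cond == control, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  lfc <- log2((mA + 0.5) / (mB + 0.5))
  vA <- pmax(apply(A, 1, var), mA)  # MoM NB variance, Poisson floor
  vB <- pmax(apply(B, 1, var), mB)
  sA <- vA / ncol(A) / ((mA + 0.5)^2 * log(2)^2)
  sB <- vB / ncol(B) / ((mB + 0.5)^2 * log(2)^2)
  se <- sqrt(sA + sB)
  df <- ncol(A) + ncol(B) - 2
  p <- ifelse(se == 0, 1, 2 * pt(-abs(lfc / se), df = df))
  p[lfc == 0] <- 1  # identical group means: p = 1 by convention
  data.frame(gene_id = rownames(m$counts), log2FC = lfc, p = p,
             base_mean = rowMeans(nc), row.names = NULL)
}

#' Contrast names of the knockdown design
#' @export
CONTRASTS <- c("siNELFA", "siYAP", "siNELFA_siYAP")

#' Build the full three-contrast table
#'
#' Runs [test_contrast()] for each knockdown against `siControl` and
#' stacks the results in long form.
#'
#' @param m a [count_matrix()]
#' @return data.frame of class `contrast_table`: `gene_id`, `contrast`,
#'   `log2FC`, `p`, `base_mean`
#' @export
contrast_table <- function(m) {
  out <- do.call(rbind, lapply(CONTRASTS, function(cc) {
    t <- test_contrast(m, cc, "siControl")
    t$contrast <- cc
    t
  }))
  out <- out[, c("gene_id", "contrast", "log2FC", "p", "base_mean")]
  class(out) <- c("contrast_table", "data.frame")
  out
}

.contrast_slice <- function(tab, contrast) {
  if (!contrast %in% tab$contrast) stop("unknown contrast name: ", contrast)
  tab[tab$contrast == contrast, , drop = FALSE]
}

#' Significantly perturbed genes of one contrast
#'
#' Strict nominal threshold (`p < alpha`); no fold-change cutoff is
#' applied at this step.
#'
#' @param tab a [contrast_table()]
#' @param contrast one of `CONTRASTS`
#' @param alpha nominal significance level in (0,1), default 0.05
#' @return character vector of gene ids
#' @export
significant_genes <- function(tab, contrast, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!nrow(tab)) return(character(0))
  sl <- .contrast_slice(tab, contrast)
  sl$gene_id[sl$p < alpha]
}

#' Write a contrast table as one wide TSV
#'
#' One row per gene; per-contrast `log2FC_*` and `p_*` columns plus the
#' shared base mean.
#' @param tab a [contrast_table()]
#' @param path output path
#' @export
write_contrast_table <- function(tab, path) {
  genes <- unique(tab$gene_id)
  out <- data.frame(gene_id = genes)
  for (cc in unique(tab$contrast)) {
    sl <- .contrast_slice(tab, cc)
    i <- match(genes, sl$gene_id)
    out[[paste0("log2FC_", cc)]] <- sl$log2FC[i]
    out[[paste0("p_", cc)]] <- sl$p[i]
  }
  out$base_mean <- tab$base_mean[match(genes, tab$gene_id)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write a two-column RNK file (gene, score)
#' @param ranked a [make_ranked_list()] result
#' @param path output path
#' @export
write_rnk <- function(ranked, path) {
  write.table(ranked, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a two-column RNK file
#' @param path RNK path
#' @return `ranked_list` data.frame (`gene_id`, `score`), descending
#' @export
read_rnk <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("gene_id", "score")
  ranked_list(df$gene_id, df$score)
}
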
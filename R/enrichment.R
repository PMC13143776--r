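#' @importFrom stats fisher.test
NULL

#' Construct a ranked gene list
#'
#' Genes sorted by score (log2 fold change) descending; ties are broken
#' by gene id, lexicographically, so the order is strict and
#' reproducible.
#'
#' @param gene_id,score parallel vectors; gene ids must be unique
#' @return data.frame of class `ranked_list` (`gene_id`, `score`)
#' @export
ranked_list <- function(gene_id, score) {
  if (anyDuplicated(gene_id)) stop("duplicate genes in ranking")
  o <- order(-score, gene_id, method = "radix")
  df <- data.frame(gene_id = as.character(gene_id)[o], score = score[o],
                   row.names = NULL)
  class(df) <- c("ranked_list", "data.frame")
  df
}

#' Rank the significant genes of one contrast
#'
#' Genes with `p < alpha` in the contrast, ranked by log2 fold change
#' descending (ties by gene id).
#'
#' @param tab a [contrast_table()]
#' @param contrast one of `CONTRASTS`
#' @param alpha significance filter, default 0.05
#' @return a [ranked_list()]
#' @export
make_ranked_list <- function(tab, contrast, alpha = 0.05) {
  sl <- .contrast_slice(tab, contrast)
  sl <- sl[sl$p < alpha, , drop = FALSE]
  if (nrow(sl) < 10) stop("ranking too short: fewer than 10 genes pass p < ", alpha)
  ranked_list(sl$gene_id, sl$log2FC)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic GSEA running-sum statistic: walking down the ranking,
#' genes in the set add `|score|^weight / sum(hit |score|^weight)` and
#' genes outside subtract `1/(N - n_hits)`; the enrichment score is the
#' signed maximum deviation of the running sum from zero.  If every hit
#' score is zero the hit increments fall back to uniform `1/n_hits`.
#'
#' @param ranked a [ranked_list()]
#' @param set character vector of gene ids; must intersect the ranking
#' @param weight exponent on the scores, default 1 (the weighted
#'   statistic used by the standard tools)
#' @return ES in `[-1, 1]`
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  hit <- ranked$gene_id %in% set
  nh <- sum(hit)
  if (nh == 0) stop("empty intersection between set and ranking")
  N <- nrow(ranked)
  w <- abs(ranked$score)^weight
  denom <- sum(w[hit])
  inc <- if (denom > 0) w / denom else rep(1 / nh, N)
  step <- ifelse(hit, inc, 0) - ifelse(hit, 0, 1 / (N - nh))
  if (nh == N) step <- inc  # degenerate: no misses to subtract
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Enrichment score with gene-sampling null, NES and nominal p
#'
#' Null enrichment scores are generated by drawing `n_perm` random gene
#' sets of the same size from the ranking.  NES is the observed ES
#' divided by the mean |null ES| of matching sign; the nominal p-value is
#' `(1 + #{same-sign null at least as extreme}) / (1 + #same-sign null)`.
#' Deterministic given `seed`.
#'
#' @param ranked a [ranked_list()]
#' @param set gene set
#' @param weight score exponent, default 1
#' @param n_perm number of null draws, >= 100
#' @param seed integer seed for the null draws
#' @return list: `es`, `nes`, `p`, `size`, `n_perm`
#' @export
gsea_nes_p <- function(ranked, set, weight = 1, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 100)
  es <- gsea_es(ranked, set, weight)
  size <- sum(ranked$gene_id %in% set)
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nrow(ranked), size)
      gsea_es(ranked, ranked$gene_id[idx], weight)
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, p = p, size = size, n_perm = n_perm)
}

#' Run GSEA over a gene-set collection
#'
#' Each set is intersected with the ranking universe and kept if its
#' effective size lies in `[min_size, max_size]`.
#'
#' @param ranked a [ranked_list()]
#' @param collection a [read_gene_sets()] collection (named list)
#' @param weight,n_perm,seed passed to [gsea_nes_p()]
#' @param min_size,max_size effective set-size bounds (defaults 5, 500)
#' @return data.frame: `name`, `size`, `es`, `nes`, `p`
#' @export
run_gsea <- function(ranked, collection, weight = 1, n_perm = 1000,
                     min_size = 5, max_size = 500, seed = 1) {
  rows <- lapply(names(collection), function(nm) {
    size <- sum(ranked$gene_id %in% collection[[nm]])
    if (size < min_size || size > max_size) return(NULL)
    r <- gsea_nes_p(ranked, collection[[nm]], weight, n_perm, seed)
    data.frame(name = nm, size = r$size, es = r$es, nes = r$nes, p = r$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(name = character(), size = integer(),
                      es = numeric(), nes = numeric(), p = numeric())
  out[order(out$p, -abs(out$nes)), , drop = FALSE]
}

#' Fisher-exact overlap enrichment of a gene list against a term
#'
#' One-sided (enrichment) Fisher exact test on the 2x2 table of
#' membership in the differential list versus the term, within the
#' stated universe.  The odds ratio is the sample `ad/bc`, with the
#' Haldane +0.5 correction applied to every cell when any cell is zero.
#'
#' @param deg differential gene list (subset of `universe`)
#' @param term target gene set (subset of `universe`)
#' @param universe background gene ids
#' @return list: `overlap`, `p`, `odds_ratio`, `deg_size`, `term_size`,
#'   `universe_size`
#' @export
fisher_overlap <- function(deg, term, universe) {
  universe <- unique(universe)
  deg <- unique(intersect(deg, universe))
  term <- unique(intersect(term, universe))
  if (!length(universe) || !length(deg)) stop("empty universe or gene list")
  a <- length(intersect(deg, term))
  b <- length(deg) - a
  cc <- length(term) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "greater")$p.value
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(overlap = a, p = p, odds_ratio = or,
       deg_size = length(deg), term_size = length(term),
       universe_size = length(universe))
}

#' Fisher overlap of a list against every term of a collection
#' @param deg differential gene list
#' @param collection named list of term gene sets
#' @param universe background gene ids
#' @return data.frame: `term`, `overlap`, `p`, `odds_ratio`
#' @export
run_fisher_overlap <- function(deg, collection, universe) {
  rows <- lapply(names(collection), function(nm) {
    r <- fisher_overlap(deg, collection[[nm]], universe)
    data.frame(term = nm, overlap = r$overlap, p = r$p,
               odds_ratio = r$odds_ratio)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
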
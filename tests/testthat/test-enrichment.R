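test_that("ranked lists sort by score with a lexicographic tie rule", {
  tab <- do.call(rbind, lapply(c("g1", "g2", "g3"), function(g)
    data.frame(gene_id = g, contrast = "siNELFA",
               log2FC = c(g1 = 2, g2 = -1, g3 = 0.5)[[g]],
               p = 0.01, base_mean = 10)))
  class(tab) <- c("contrast_table", "data.frame")
  expect_error(make_ranked_list(tab, "siNELFA", 0.05), "ranking too short")
  r <- ranked_list(tab$gene_id, tab$log2FC)
  expect_equal(r$gene_id, c("g1", "g3", "g2"))
  tie <- ranked_list(c("b", "a"), c(1, 1))
  expect_equal(tie$gene_id, c("a", "b"))
  expect_error(ranked_list(c("a", "a"), 1:2), "duplicate")
})

test_that("enrichment score equals the brute-force running sum", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 10
    r <- ranked_list(paste0("g", sample(100, n)), sort(runif(n, -5, 10),
                                                       decreasing = TRUE))
    set <- r$gene_id[sample(n, 3)]
    for (w in c(0, 1, 1.5))
      expect_equal(gsea_es(r, set, weight = w),
                   gsea_es_oracle(r$gene_id, r$score, set, weight = w),
                   tolerance = 1e-12)
  }
  # the specific positions {1,4,9} of a 10..1 ranking
  r <- ranked_list(paste0("g", 1:10), 10:1)
  set <- r$gene_id[c(1, 4, 9)]
  expect_equal(gsea_es(r, set, 1),
               gsea_es_oracle(r$gene_id, r$score, set, 1), tolerance = 1e-12)
})

test_that("top-k sets score exactly +1 and bottom-k exactly -1", {
  r <- ranked_list(paste0("g", 1:50), 50:1)
  expect_equal(gsea_es(r, r$gene_id[1:5], 1), 1)
  expect_equal(gsea_es(r, r$gene_id[46:50], 1), -1)
  expect_error(gsea_es(r, "absent"), "empty intersection")
})

test_that("the enrichment score is invariant under positive score rescaling", {
  set.seed(42)
  r <- ranked_list(paste0("g", 1:40), sort(rnorm(40), decreasing = TRUE))
  set <- r$gene_id[sample(40, 8)]
  for (w in c(0.5, 1, 2)) {
    a <- gsea_es(r, set, w)
    r2 <- ranked_list(r$gene_id, r$score * 7.3)
    expect_equal(gsea_es(r2, set, w), a, tolerance = 1e-12)
  }
})

test_that("enrichment scores agree with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(43)
  r <- ranked_list(paste0("g", 1:100), sort(rnorm(100), decreasing = TRUE))
  for (k in c(5, 15, 40)) {
    set <- r$gene_id[sample(100, k)]
    ours <- gsea_es(r, set, weight = 1)
    ref <- fgsea::calcGseaStat(setNames(r$score, r$gene_id),
                               which(r$gene_id %in% set),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("permutation NES and p are deterministic and extreme for top sets", {
  r <- ranked_list(paste0("g", 1:60), 60:1)
  a <- gsea_nes_p(r, r$gene_id[1:6], n_perm = 200, seed = 5)
  b <- gsea_nes_p(r, r$gene_id[1:6], n_perm = 200, seed = 5)
  expect_identical(a, b)
  expect_gt(a$nes, 1)
  # ES = 1 is maximal, so p sits at the +1-smoothed floor of the null
  expect_lte(a$p, 0.05)
})

test_that("permutation p-values are near-uniform for random sets", {
  set.seed(44)
  r <- ranked_list(paste0("g", 1:100), sort(rnorm(100), decreasing = TRUE))
  ps <- vapply(1:400, function(i) {
    set <- r$gene_id[sample(100, 10)]
    gsea_nes_p(r, set, n_perm = 200, seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("Fisher overlap p equals the hypergeometric tail sum", {
  # brute-force oracle: direct summation of the hypergeometric tail
  tail_sum <- function(a, deg, term, uni)
    sum(dhyper(a:min(deg, term), term, uni - term, deg))
  r <- fisher_overlap(paste0("g", 1:10), paste0("g", c(1:5, 11:25)),
                      paste0("g", 1:100))
  expect_equal(r$overlap, 5)
  expect_equal(r$p, tail_sum(5, 10, 20, 100), tolerance = 1e-12)

  set.seed(45)
  for (i in 1:25) {
    uni_n <- sample(20:200, 1)
    uni <- paste0("g", seq_len(uni_n))
    deg <- sample(uni, sample(2:(uni_n %/% 3), 1))
    term <- sample(uni, sample(2:(uni_n %/% 2), 1))
    r <- fisher_overlap(deg, term, uni)
    expect_equal(r$p,
                 tail_sum(r$overlap, length(deg), length(term), uni_n),
                 tolerance = 1e-12)
  }
})

test_that("odds ratio is ad/bc with Haldane correction at zero cells", {
  # proportional table: overlap equals expectation, odds ratio 1
  uni <- paste0("g", 1:100)
  deg <- uni[1:20]
  term <- c(uni[1:10], uni[21:60])  # |term|=50, overlap 10 = 20*50/100
  r <- fisher_overlap(deg, term, uni)
  expect_equal(r$odds_ratio, 1)
  # deg entirely inside term = universe: degenerate, p = 1
  r2 <- fisher_overlap(uni[1:10], uni, uni)
  expect_equal(r2$p, 1)
  expect_true(is.finite(r2$odds_ratio))  # Haldane keeps it finite
  expect_error(fisher_overlap(character(0), term, uni), "empty")
})
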
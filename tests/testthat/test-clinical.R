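test_that("composite IHC score multiplies the printed percent bins by intensity", {
  expect_equal(composite_score(75, 3), 9)
  expect_equal(composite_score(0, 3), 0)
  # bin edges exactly as printed: 10% -> bin 1, 11% -> bin 2, 50/51 likewise
  expect_equal(ihc_bin(c(0, 1, 10, 11, 50, 51, 100)),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(composite_score(120, 2), "\\[0,100\\]")
  expect_error(composite_score(50, 5), "0..3")
  # the attainable score range is exactly the products of 0..3 x 0..3
  grid <- expand.grid(pct = c(0, 5, 30, 80), int = 0:3)
  expect_setequal(composite_score(grid$pct, grid$int),
                  as.vector(outer(0:3, 0:3)))
})

test_that("ROC cutoff maximizes Youden's J with the smaller-cutoff tie rule", {
  scores <- c(1, 2, 8, 9)
  outcome <- c(0, 0, 1, 1)
  r <- roc_cutoff(scores, outcome)
  expect_equal(r$cutoff, 5)   # smallest midpoint achieving J = 1
  expect_equal(r$youden, 1)
  expect_equal(c(r$sensitivity, r$specificity), c(1, 1))
  expect_error(roc_cutoff(1:4, c(1, 1, 1, 1)), "single-class")
  expect_error(roc_cutoff(rep(3, 6), c(0, 1, 0, 1, 0, 1)), "identical")
})

test_that("ROC cutoff agrees with exhaustive threshold search", {
  set.seed(51)
  for (i in 1:20) {
    scores <- sample(0:9, 40, replace = TRUE)
    outcome <- rbinom(40, 1, plogis((scores - 4) / 2))
    if (length(unique(outcome)) < 2 || length(unique(scores)) < 2) next
    r <- roc_cutoff(scores, outcome)
    # oracle: every candidate threshold, first maximum wins
    u <- sort(unique(scores))
    cand <- (head(u, -1) + tail(u, -1)) / 2
    J <- vapply(cand, function(ct) {
      sens <- mean(scores[outcome == 1] >= ct)
      spec <- mean(scores[outcome == 0] < ct)
      sens + spec - 1
    }, numeric(1))
    expect_equal(r$youden, max(J), tolerance = 1e-9)
    expect_equal(r$cutoff, min(cand[J >= max(J) - 1e-9]))
  }
})

test_that("Kaplan-Meier estimates behave at the boundaries", {
  all_cens <- km_curve(c(3, 7, 12), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))
  single <- km_curve(5, 1)
  expect_equal(km_at(single, 5), 0)
  expect_equal(km_at(single, 4.9), 1)
})

test_that("Kaplan-Meier matches the exponential closed form at the median", {
  h <- 0.02
  cohort <- simulate_cohort(
    200, group_hazards = c(HighYAP_HighNELFA = h, HighYAP_LowNELFA = h,
                           LowYAP_HighNELFA = h, LowYAP_LowNELFA = h),
    censor_months = 60, seed = 99)
  km <- km_curve(cohort$records$os_months, cohort$records$os_event)
  expect_lt(abs(km_at(km, log(2) / h) - 0.5), 0.08)
})

test_that("log-rank: identical groups give statistic 0, four groups give df 3", {
  time <- c(2, 5, 9, 14, 20)
  event <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(rep(time, 2), rep(event, 2),
                     rep(c("a", "b"), each = 5))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  cohort <- simulate_cohort(60, seed = 52)
  lr4 <- logrank_test(cohort$records$os_months, cohort$records$os_event,
                      cohort$truth$group)
  expect_equal(lr4$df, 3)
  expect_error(logrank_test(time, event, rep("a", 5)), ">= 2 groups")
})

test_that("log-rank holds its nominal size and detects a hazard ratio of 4", {
  eq <- c(HighYAP_HighNELFA = 0.02, HighYAP_LowNELFA = 0.02,
          LowYAP_HighNELFA = 0.02, LowYAP_LowNELFA = 0.02)
  rej <- vapply(1:400, function(i) {
    cs <- simulate_cohort(100, group_hazards = eq, seed = 60000 + i)
    g <- sub("_.*", "", cs$truth$group)  # YAP high vs low
    logrank_test(cs$records$os_months, cs$records$os_event, g)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.075)
  hr4 <- c(HighYAP_HighNELFA = 0.032, HighYAP_LowNELFA = 0.032,
           LowYAP_HighNELFA = 0.008, LowYAP_LowNELFA = 0.008)
  pow <- vapply(1:100, function(i) {
    cs <- simulate_cohort(100, group_hazards = hr4, seed = 70000 + i)
    g <- sub("_.*", "", cs$truth$group)
    logrank_test(cs$records$os_months, cs$records$os_event, g)$p < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.9)
})

test_that("chi-square contingency equals the textbook statistic, uncorrected", {
  set.seed(53)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    r <- chi2_contingency(tab)
    # independent textbook computation: sum (O - E)^2 / E
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(r$df, 2)
    expect_equal(r$p, pchisq(sum((tab - E)^2 / E), 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # proportional rows: exact independence
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  r <- chi2_contingency(prop)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(chi2_contingency(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("stratification partitions the cohort into exhaustive groups", {
  df <- tiny_cohort(12)
  s1 <- stratify(df, "single_marker", cutoffs = list(yap = 4), marker = "yap")
  expect_setequal(unique(s1$group), c("high", "low"))
  sj <- stratify(df, "joint", cutoffs = list(yap = 4, nelfa = 4))
  expect_equal(sum(table(sj$group)), nrow(df))
  expect_equal(as.character(sj$group[sj$yap_score >= 4 & sj$nelfa_score >= 4][1]),
               "HighYAP_HighNELFA")
  expect_error(stratify(df, "joint", cutoffs = list(yap = 4)), "nelfa")
})

test_that("stratified survival orders groups by their planted hazards", {
  hz <- c(HighYAP_HighNELFA = 0.06, HighYAP_LowNELFA = 0.02,
          LowYAP_HighNELFA = 0.02, LowYAP_LowNELFA = 0.005)
  hits <- vapply(1:20, function(i) {
    cs <- simulate_cohort(200, group_hazards = hz, seed = 80000 + i)
    st <- stratify(cs$records, "joint", cutoffs = list(yap = 4, nelfa = 4))
    worst <- st$group == "HighYAP_HighNELFA"
    best <- st$group == "LowYAP_LowNELFA"
    t50 <- 30
    kw <- km_at(km_curve(st$os_months[worst], st$os_event[worst]), t50)
    kb <- km_at(km_curve(st$os_months[best], st$os_event[best]), t50)
    kb > kw
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("median split labels and tie rule are monotone-invariant", {
  v <- 1:10
  s <- median_split(v)
  expect_equal(s$cutoff, 5.5)
  expect_equal(sum(s$labels == "high"), 5)
  # odd n: the middle value sits at the median and is labelled low
  s2 <- median_split(c(1, 2, 3, 4, 5))
  expect_equal(s2$labels[3], "low")
  expect_error(median_split(rep(2, 6)), "degenerate")
  expect_error(median_split(1:3), "n >= 4")
  set.seed(54)
  x <- rnorm(31)
  expect_equal(median_split(exp(x))$labels, median_split(x)$labels)
})
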
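#' @importFrom stats chisq.test pchisq median
#' @importFrom survival Surv survfit survdiff
NULL

#' Bin a percent-positive IHC score
#'
#' The standard binning: 0% -> 0; 1-10% -> 1; 11-50% -> 2; 51-100% -> 3.
#' Vectorized.
#'
#' @param percent staining percentage in `[0, 100]`
#' @return integer bin in 0..3
#' @export
ihc_bin <- function(percent) {
  if (any(percent < 0 | percent > 100)) stop("percent outside [0,100]")
  ifelse(percent == 0, 0L,
         ifelse(percent <= 10, 1L, ifelse(percent <= 50, 2L, 3L)))
}

#' Composite IHC score: binned percent x intensity
#'
#' @param percent staining percentage in `[0, 100]`
#' @param intensity staining intensity, integer 0..3
#' @return integer composite score in `{0,...,9}` (products of 0..3 bins
#'   and intensities)
#' @export
composite_score <- function(percent, intensity) {
  if (!all(intensity %in% 0:3)) stop("intensity outside 0..3")
  ihc_bin(percent) * as.integer(intensity)
}

#' ROC cutoff maximizing Youden's J
#'
#' Scans every midpoint between distinct observed scores, labelling
#' `score >= cutoff` as "high" (test positive), and returns the cutoff
#' maximizing J = sensitivity + specificity - 1.  Ties in J are broken
#' toward the smaller cutoff.
#'
#' @param scores per-patient numeric scores
#' @param outcome binary event flags (both classes must be present)
#' @return list: `cutoff`, `sensitivity`, `specificity`, `youden`
#' @export
roc_cutoff <- function(scores, outcome) {
  if (length(unique(outcome)) < 2) stop("ROC undefined: single-class outcome")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("ROC undefined: all scores identical (J = 0)")
  cand <- (u[-length(u)] + u[-1]) / 2
  best <- NULL
  for (ct in cand) {
    pos <- scores >= ct
    sens <- sum(pos & outcome == 1) / sum(outcome == 1)
    spec <- sum(!pos & outcome == 0) / sum(outcome == 0)
    J <- sens + spec - 1
    if (is.null(best) || J > best$youden + 1e-12)
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec,
                   youden = J)
  }
  best
}

#' Kaplan-Meier product-limit curve
#'
#' @param time follow-up times (months), non-negative
#' @param event event flags (1 = event, 0 = censored)
#' @return data.frame: `time`, `n_risk`, `n_event`, `survival`
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Survival probability at a time point from a KM curve
#' @param km a [km_curve()] data.frame
#' @param t time point
#' @return estimated S(t)
#' @export
km_at <- function(km, t) {
  i <- which(km$time <= t)
  if (!length(i)) 1 else km$survival[max(i)]
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' Observed-minus-expected events summed over event times with the
#' hypergeometric variance; df = number of groups - 1; p from the
#' chi-square upper tail.
#'
#' @param time,event survival times and event flags
#' @param group group labels (>= 2 groups, >= 1 event overall)
#' @return list: `chisq`, `df`, `p`
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (sum(event) < 1) stop("no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(chisq = sd$chisq, df = df, p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Pearson chi-square contingency test (no continuity correction)
#'
#' The uncorrected Pearson statistic `sum (O - E)^2 / E` with
#' df = (r-1)(c-1); all row and column sums must be positive.  No Yates
#' correction is applied anywhere, including 2x2 tables.
#'
#' @param table r x c matrix of non-negative counts
#' @return list: `observed`, `statistic`, `df`, `p`
#' @export
chi2_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(observed = table, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}

#' Stratify a cohort by composite marker scores
#'
#' Composite YAP and NELFA scores are computed from the percent and
#' intensity columns; "high" means score >= the marker's cutoff.
#'
#' @param records a [clinical_table()]
#' @param mode `"single_marker"` (one marker: high/low) or `"joint"`
#'   (YAP x NELFA four groups)
#' @param cutoffs named numeric: `yap` and/or `nelfa` cutoffs (from
#'   [roc_cutoff()] or [median_split()])
#' @param marker which marker when `mode = "single_marker"`
#' @return the records with `yap_score`, `nelfa_score` and `group` added
#' @export
stratify <- function(records, mode = c("single_marker", "joint"),
                     cutoffs, marker = c("yap", "nelfa")) {
  mode <- match.arg(mode)
  records$yap_score <- composite_score(records$yap_percent,
                                       records$yap_intensity)
  records$nelfa_score <- composite_score(records$nelfa_percent,
                                         records$nelfa_intensity)
  if (mode == "single_marker") {
    marker <- match.arg(marker)
    if (is.null(cutoffs[[marker]])) stop("missing cutoff for ", marker)
    score <- records[[paste0(marker, "_score")]]
    records$group <- ifelse(score >= cutoffs[[marker]], "high", "low")
  } else {
    if (is.null(cutoffs[["yap"]]) || is.null(cutoffs[["nelfa"]]))
      stop("joint mode needs yap and nelfa cutoffs")
    yh <- records$yap_score >= cutoffs[["yap"]]
    nh <- records$nelfa_score >= cutoffs[["nelfa"]]
    records$group <- ifelse(yh & nh, "HighYAP_HighNELFA",
                     ifelse(yh & !nh, "HighYAP_LowNELFA",
                     ifelse(!yh & nh, "LowYAP_HighNELFA",
                            "LowYAP_LowNELFA")))
  }
  records
}

#' Median split of continuous expression values
#'
#' Cutoff at the sample median; values strictly above are "high", values
#' at or below the median are "low" (documented tie rule).  Invariant
#' under monotone transformation of the values.
#'
#' @param values per-patient expression (n >= 4, not all identical)
#' @return list: `cutoff` (the median), `labels` (character "high"/"low")
#' @export
median_split <- function(values) {
  if (length(values) < 4) stop("need n >= 4")
  if (length(unique(values)) == 1) stop("degenerate split: all values identical")
  m <- median(values)
  list(cutoff = m, labels = ifelse(values > m, "high", "low"))
}
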
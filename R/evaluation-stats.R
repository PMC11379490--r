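#' Paired 2x2 reclassification table for cases
#'
#' Cross-classifies each case by the clinical rule and the IRT rule:
#' `a` = high by both, `b` = up-classified (clinical not-high, IRT high),
#' `c` = down-classified, `d` = low by both. When the second classifier is
#' the union rule (clinical OR IRT), `c` is structurally zero.
#'
#' @param assessment A [assess_risk()] result (case rows).
#' @return A `reclass_table` list with `n`, `a`, `b`, `c`, `d`.
#' @export
reclass_table <- function(assessment) {
  ch <- assessment$clinical_high
  ih <- assessment$irt_high
  out <- list(n = length(ch),
              a = sum(ch & ih), b = sum(!ch & ih),
              c = sum(ch & !ih), d = sum(!ch & !ih))
  stopifnot(out$a + out$b + out$c + out$d == out$n)
  structure(out, class = "reclass_table")
}

#' Sensitivity with binomial confidence interval
#'
#' Point estimate `100 * k / n` with a 95% CI: Clopper-Pearson exact by
#' default, or Wilson score / Wald on request.
#'
#' @param k Cases flagged positive (0..n).
#' @param n Number of cases (>= 1).
#' @param method `"clopper-pearson"`, `"wilson"`, or `"wald"`.
#' @param conf Confidence level (default 0.95).
#' @return A list with `estimate`, `lower`, `upper` (all percent), `k`, `n`.
#' @export
sensitivity_ci <- function(k, n, method = c("clopper-pearson", "wilson",
                                            "wald"), conf = 0.95) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- k / n
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- switch(method,
    "clopper-pearson" = as.numeric(binom.test(k, n,
                                              conf.level = conf)$conf.int),
    wilson = {
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    wald = pmin(pmax(p + c(-1, 1) * z * sqrt(p * (1 - p) / n), 0), 1))
  list(estimate = 100 * p, lower = 100 * ci[1], upper = 100 * ci[2],
       k = k, n = n, method = method)
}

#' Paired difference in sensitivity with Wald inference
#'
#' For two classifiers evaluated on the same `n` cases with `b`
#' discordant-up and `c` discordant-down cases, the difference in
#' sensitivity is `(b - c) / n` with sampling variance
#' `(b + c - (b - c)^2 / n) / n^2`; the 95% CI is the standard Wald
#' interval and the p-value the two-sided normal test of zero difference
#' (the paired comparison used for the headline sensitivity uplift).
#' `b = c = 0` returns a zero difference with a degenerate CI flag.
#'
#' @param b Up-classified count. @param c Down-classified count.
#' @param n Cases; `b + c <= n`.
#' @param conf Confidence level.
#' @return List with `diff`, `lower`, `upper` (percent), `se` (proportion
#'   scale), `z`, `p_value`, `degenerate`.
#' @export
paired_sensitivity_diff <- function(b, c, n, conf = 0.95) {
  if (b < 0 || c < 0 || n < 1 || b + c > n) stop("require 0 <= b + c <= n")
  d <- (b - c) / n
  v <- (b + c - (b - c)^2 / n) / n^2
  if (b == 0 && c == 0)
    return(list(diff = 0, lower = 0, upper = 0, se = 0, z = 0, p_value = 1,
                degenerate = TRUE))
  zq <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(v)
  z <- d / se
  list(diff = 100 * d, lower = 100 * (d - zq * se),
       upper = 100 * (d + zq * se), se = se, z = z,
       p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Relative increase in cases identified
#'
#' `100 * b / k_base`: the up-classified count as a percentage of the cases
#' the clinical score already flagged.
#'
#' @param b Up-classified cases. @param k_base Clinical-positive cases
#'   (>= 1).
#' @return Percent.
#' @export
relative_increase <- function(b, k_base) {
  if (k_base < 1) stop("k_base must be >= 1")
  100 * b / k_base
}

#' Case net reclassification index
#'
#' `100 * (b - c) / n`: net proportion of cases moved into the high-risk
#' category by the IRT. With matched controls a full NRI is not meaningful,
#' so only the case component is offered.
#'
#' @param b,c Up- and down-classified case counts. @param n Cases.
#' @return Percent.
#' @export
case_nri <- function(b, c, n) {
  if (n < 1) stop("n must be >= 1")
  if (b + c > n) stop("b + c must not exceed n")
  100 * (b - c) / n
}

#' Odds ratio of up-classification, cases vs controls
#'
#' Among subjects flagged low-risk by the clinical score, compares the odds
#' of being up-classified by the IRT between cases and controls. Point
#' estimate is the 2x2 cross-product; the 95% CI is the conditional exact
#' (Fisher) interval. A zero cell leaves the exact CI valid but flags the
#' point estimate.
#'
#' @param case_up Up-classified cases. @param case_low Clinical-low cases.
#' @param ctrl_up Up-classified controls. @param ctrl_low Clinical-low
#'   controls.
#' @return List with `or`, `lower`, `upper`, `p_value` (Fisher exact,
#'   two-sided), `zero_cell`.
#' @export
upclass_odds_ratio <- function(case_up, case_low, ctrl_up, ctrl_low) {
  if (case_low < 1 || ctrl_low < 1) stop("both groups must be non-empty")
  if (case_up > case_low || ctrl_up > ctrl_low)
    stop("up counts cannot exceed low-risk group sizes")
  tab <- matrix(c(case_up, case_low - case_up,
                  ctrl_up, ctrl_low - ctrl_up), nrow = 2, byrow = TRUE)
  zero_cell <- any(tab == 0)
  or <- if (zero_cell) NA_real_ else
    (tab[1, 1] / tab[1, 2]) / (tab[2, 1] / tab[2, 2])
  ft <- fisher.test(tab)
  list(or = or, lower = ft$conf.int[1], upper = ft$conf.int[2],
       p_value = ft$p.value, zero_cell = zero_cell)
}

#' Case enrichment in upper PRS percentiles
#'
#' For each upper-tail cut `q` (e.g. 0.20 for the top 20%), computes the
#' fraction of cases whose standardised PRS is at or above the reference
#' `(1 - q)`-quantile, and the fold enrichment `observed / q` (1 = no
#' enrichment).
#'
#' @param case_z Standardised PRS of cases.
#' @param ref_z Standardised PRS of the reference distribution.
#' @param cuts Upper-tail fractions in (0, 1); default the conventional
#'   set 20/10/5/3/1%.
#' @return An `enrichment_curve` data frame: `cut`, `threshold`,
#'   `observed`, `fold`.
#' @export
percentile_enrichment <- function(case_z, ref_z,
                                  cuts = c(0.20, 0.10, 0.05, 0.03, 0.01)) {
  if (length(ref_z) == 0) stop("reference must be non-empty")
  if (any(cuts <= 0 | cuts >= 1)) stop("cuts must lie in (0, 1)")
  cuts <- sort(cuts, decreasing = TRUE)
  thr <- quantile(ref_z, probs = 1 - cuts, names = FALSE, type = 7)
  observed <- vapply(thr, function(t) mean(case_z >= t), numeric(1))
  out <- data.frame(cut = cuts, threshold = thr, observed = observed,
                    fold = observed / cuts)
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

#' Baseline characteristics table with case/control tests
#'
#' Continuous rows: mean (SD) per group and the two-sample Student t-test
#' (equal variances). Categorical rows: n (%) per level and the Pearson
#' chi-squared test — with continuity correction for 2x2 tables only, none
#' for larger tables (the convention of standard statistical environments).
#' Constant continuous columns are reported without a test.
#'
#' @param cases,controls Participant tables.
#' @param continuous,categorical Column names to summarise.
#' @return A data frame: `variable`, `type`, `cases`, `controls`
#'   (formatted), `p_value`.
#' @export
baseline_table <- function(cases, controls,
                           continuous = c("age", "sbp", "dbp", "bmi",
                                          "total_chol", "hdl", "qrisk2"),
                           categorical = c("sex", "ethnicity", "smoking",
                                           "diabetes", "statin")) {
  if (nrow(cases) == 0 || nrow(controls) == 0)
    stop("both groups must be non-empty")
  rows <- list()
  for (v in intersect(continuous, names(cases))) {
    x <- cases[[v]]; y <- controls[[v]]
    p <- if (sd(x) == 0 && sd(y) == 0) NA_real_ else
      t.test(x, y, var.equal = TRUE)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, type = "continuous",
      cases = sprintf("%.1f (%.1f)", mean(x), sd(x)),
      controls = sprintf("%.1f (%.1f)", mean(y), sd(y)),
      p_value = p, stringsAsFactors = FALSE)
  }
  for (v in intersect(categorical, names(cases))) {
    x <- as.character(cases[[v]]); y <- as.character(controls[[v]])
    lev <- sort(unique(c(x, y)))
    tab <- rbind(table(factor(x, lev)), table(factor(y, lev)))
    p <- if (length(lev) < 2) NA_real_ else
      chisq.test(tab, correct = length(lev) == 2)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, type = "categorical",
      cases = paste(sprintf("%s: %d (%.1f%%)", lev, tab[1, ],
                            100 * tab[1, ] / sum(tab[1, ])),
                    collapse = "; "),
      controls = paste(sprintf("%s: %d (%.1f%%)", lev, tab[2, ],
                               100 * tab[2, ] / sum(tab[2, ])),
                       collapse = "; "),
      p_value = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Chi-squared p-value for a 2 x k count table
#'
#' Pearson chi-squared with continuity correction applied for 2x2 tables
#' only — the convention [baseline_table()] uses.
#'
#' @param counts_cases,counts_controls Integer vectors of per-level counts.
#' @return Two-sided p-value.
#' @export
table_chisq_p <- function(counts_cases, counts_controls) {
  tab <- rbind(counts_cases, counts_controls)
  chisq.test(tab, correct = ncol(tab) == 2)$p.value
}

#' Parameterised preventable-events model
#'
#' Expected extra events prevented per `scale` patient-years when newly
#' identified high-risk individuals are treated:
#' `E = newly_high_fraction x uptake x rrr x annual_event_rate x scale`.
#' All terms enter linearly, so uncertainty in any input propagates
#' proportionally.
#'
#' @param newly_high_fraction Fraction of the population newly classified
#'   high risk by the combined rule.
#' @param uptake Fraction of those who start treatment.
#' @param rrr Relative risk reduction of treatment.
#' @param annual_event_rate Annual event rate among the newly identified.
#' @param scale Patient-years scale (default 1e5).
#' @return Events prevented per `scale` patient-years.
#' @export
preventable_events <- function(newly_high_fraction, uptake, rrr,
                               annual_event_rate, scale = 1e5) {
  fr <- c(newly_high_fraction, uptake, rrr)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (annual_event_rate < 0) stop("annual_event_rate must be >= 0")
  newly_high_fraction * uptake * rrr * annual_event_rate * scale
}

#' Headline evaluation of a clinical score vs its combination with the IRT
#'
#' Given the case assessment, computes the clinical-only sensitivity, the
#' union-rule (clinical OR IRT) sensitivity, the paired Wald comparison,
#' the relative increase, and the case-NRI; optionally the up-classification
#' odds ratio against a control assessment.
#'
#' @param case_assessment [assess_risk()] rows for cases.
#' @param control_assessment Optional [assess_risk()] rows for controls.
#' @return An `evaluation_report` list.
#' @export
evaluate_uplift <- function(case_assessment, control_assessment = NULL) {
  rt <- reclass_table(case_assessment)
  k_base <- rt$a + rt$c                 # clinical-high cases
  k_comb <- rt$a + rt$b + rt$c          # union rule: clinical OR IRT
  out <- list(
    reclass = rt,
    clinical = sensitivity_ci(k_base, rt$n),
    combined = sensitivity_ci(k_comb, rt$n),
    uplift = paired_sensitivity_diff(rt$b, 0L, rt$n),
    relative_increase = if (k_base > 0) relative_increase(rt$b, k_base)
                        else NA_real_,
    case_nri = case_nri(rt$b, rt$c, rt$n),
    irt_only_diff = paired_sensitivity_diff(rt$b, rt$c, rt$n))
  stopifnot(out$combined$estimate >= out$clinical$estimate)
  if (!is.null(control_assessment)) {
    ct <- reclass_table(control_assessment)
    if (rt$b + rt$d >= 1 && ct$b + ct$d >= 1)
      out$upclass_or <- upclass_odds_ratio(rt$b, rt$b + rt$d,
                                           ct$b, ct$b + ct$d)
  }
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Clinical score:      %.1f%% of cases high risk (95%% CI %.1f-%.1f)\n",
              x$clinical$estimate, x$clinical$lower, x$clinical$upper))
  cat(sprintf("Clinical OR IRT:     %.1f%% (95%% CI %.1f-%.1f)\n",
              x$combined$estimate, x$combined$lower, x$combined$upper))
  cat(sprintf("Absolute uplift:     %.1f%% (95%% CI %.1f-%.1f, p = %.2g)\n",
              x$uplift$diff, x$uplift$lower, x$uplift$upper,
              x$uplift$p_value))
  if (is.finite(x$relative_increase))
    cat(sprintf("Relative increase:   %.1f%%\n", x$relative_increase))
  cat(sprintf("Case-NRI (IRT alone): %.1f%%\n", x$case_nri))
  if (!is.null(x$upclass_or))
    cat(sprintf("Up-classification OR: %.2f (95%% CI %.2f-%.2f, p = %.3f)\n",
                x$upclass_or$or, x$upclass_or$lower, x$upclass_or$upper,
                x$upclass_or$p_value))
  invisible(x)
}
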
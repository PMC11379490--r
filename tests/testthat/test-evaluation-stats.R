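test_that("sensitivity point estimates and exact CIs match printed precision", {
  s <- sensitivity_ci(120, 195)
  expect_equal(round(s$estimate, 1), 61.5)
  expect_equal(round(s$lower, 1), 54.3)
  expect_equal(round(s$upper, 1), 68.4)
  s2 <- sensitivity_ci(134, 195)
  expect_equal(round(s2$estimate, 1), 68.7)
  expect_equal(round(s2$lower, 1), 61.7)
  expect_equal(round(s2$upper, 1), 75.2)
  s0 <- sensitivity_ci(0, 10)
  expect_equal(s0$estimate, 0)
  expect_equal(s0$lower, 0)
  expect_error(sensitivity_ci(5, 0), "n must")
  expect_error(sensitivity_ci(11, 10), "k must")
})

test_that("Clopper-Pearson bounds equal root-finding on the binomial tail", {
  k <- 7; n <- 25
  s <- sensitivity_ci(k, n)
  lower <- uniroot(function(p) 1 - pbinom(k - 1, n, p) - 0.025,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- uniroot(function(p) pbinom(k, n, p) - 0.025,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  expect_equal(s$lower, 100 * lower, tolerance = 1e-6)
  expect_equal(s$upper, 100 * upper, tolerance = 1e-6)
})

test_that("paired Wald difference reproduces the headline uplift intervals", {
  d <- paired_sensitivity_diff(14, 0, 195)
  expect_equal(round(d$diff, 1), 7.2)
  expect_equal(round(d$lower, 1), 3.6)
  expect_equal(round(d$upper, 1), 10.8)
  expect_equal(signif(d$p_value, 1), 1e-4)

  d2 <- paired_sensitivity_diff(14, 0, 173)
  expect_equal(round(d2$diff, 1), 8.1)
  expect_equal(round(d2$lower, 1), 4.0)
  expect_equal(round(d2$upper, 1), 12.2)

  expect_equal(paired_sensitivity_diff(5, 5, 100)$diff, 0)
  deg <- paired_sensitivity_diff(0, 0, 50)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(paired_sensitivity_diff(60, 50, 100), "b \\+ c")
})

test_that("Wald CI contains the point estimate and narrows with n", {
  widths <- vapply(c(50, 200, 800, 3200), function(n) {
    b <- round(0.08 * n); c <- round(0.02 * n)
    d <- paired_sensitivity_diff(b, c, n)
    expect_gte(d$diff, d$lower)
    expect_lte(d$diff, d$upper)
    d$upper - d$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("paired Wald interval agrees with a bootstrap of the indicators", {
  b <- 14; n <- 195
  d <- paired_sensitivity_diff(b, 0, n)
  set.seed(121)
  ind <- c(rep(1, b), rep(0, n - b))  # per-case up-classification indicator
  boot <- replicate(1e4, mean(sample(ind, n, replace = TRUE)))
  boot_ci <- 100 * quantile(boot, c(0.025, 0.975), names = FALSE)
  wald_width <- d$upper - d$lower
  boot_width <- boot_ci[2] - boot_ci[1]
  expect_lt(abs(wald_width - boot_width) / wald_width, 0.10)
})

test_that("relative increase and case-NRI come from raw counts", {
  expect_equal(round(relative_increase(14, 120), 1), 11.7)
  expect_equal(round(relative_increase(9, 19), 1), 47.4)
  expect_equal(relative_increase(0, 120), 0)
  expect_error(relative_increase(5, 0), "k_base")

  expect_equal(case_nri(7, 7, 100), 0)
  expect_equal(round(case_nri(14, 12, 195), 1), 1.0)
  # with no down-classification the case-NRI is the paired difference
  expect_equal(case_nri(14, 0, 195), paired_sensitivity_diff(14, 0, 195)$diff)
})

test_that("up-classification OR matches cross-product and exact enumeration", {
  eq <- upclass_odds_ratio(2, 10, 2, 10)
  expect_equal(eq$or, 1.0)
  sw <- upclass_odds_ratio(2, 10, 2, 10)
  expect_equal(eq$lower, sw$lower)

  res <- upclass_odds_ratio(14, 75, 16, 187)
  expect_equal(res$or, (14 / 61) / (16 / 171), tolerance = 1e-12)

  # oracle: invert the noncentral hypergeometric tail for the exact CI
  x <- 14; m1 <- 75; m2 <- 187; k <- 14 + 16
  support <- max(0, k - m2):min(k, m1)
  tail_ge <- function(psi)
    sum(exp(lchoose(m1, support) + lchoose(m2, k - support) +
              support * log(psi))[support >= x]) /
      sum(exp(lchoose(m1, support) + lchoose(m2, k - support) +
                support * log(psi)))
  tail_le <- function(psi)
    sum(exp(lchoose(m1, support) + lchoose(m2, k - support) +
              support * log(psi))[support <= x]) /
      sum(exp(lchoose(m1, support) + lchoose(m2, k - support) +
                support * log(psi)))
  lower <- uniroot(function(l) tail_ge(exp(l)) - 0.025, c(-10, 10),
                   tol = 1e-10)$root
  upper <- uniroot(function(l) tail_le(exp(l)) - 0.025, c(-10, 10),
                   tol = 1e-10)$root
  expect_equal(res$lower, exp(lower), tolerance = 1e-4)
  expect_equal(res$upper, exp(upper), tolerance = 1e-4)

  expect_error(upclass_odds_ratio(5, 0, 2, 10), "non-empty")
  expect_true(upclass_odds_ratio(0, 10, 2, 10)$zero_cell)
})

test_that("percentile enrichment is null-calibrated and exact in edge cases", {
  set.seed(122)
  ref <- rnorm(2e5)
  cases_null <- rnorm(5e4)
  e <- percentile_enrichment(cases_null, ref)
  expect_true(all(abs(e$fold - 1) < 0.15))
  expect_true(all(diff(e$observed) <= 0))  # observed non-increasing in cut

  # every case above the 80th reference percentile: fold = 1 / 0.2
  ref2 <- seq(-3, 3, length.out = 1000)
  thr <- quantile(ref2, 0.8, names = FALSE)
  e2 <- percentile_enrichment(rep(thr + 1, 50), ref2, cuts = 0.2)
  expect_equal(e2$fold, 5.0)

  expect_error(percentile_enrichment(1, numeric(0)), "non-empty")
  expect_error(percentile_enrichment(1, rnorm(10), cuts = 1.2), "cuts")
})

test_that("enrichment under a mean shift matches the normal closed form", {
  set.seed(123)
  ref <- rnorm(3e5)
  cases <- rnorm(1e5, 0.5, 1)
  cuts <- c(0.20, 0.10, 0.05)
  e <- percentile_enrichment(cases, ref, cuts = cuts)
  pred <- pnorm(qnorm(1 - cuts) - 0.5, lower.tail = FALSE) / cuts
  for (i in seq_along(cuts)) {
    p <- pred[i] * cuts[i]
    se <- sqrt(p * (1 - p) / 1e5) / cuts[i]
    expect_lt(abs(e$fold[i] - pred[i]), 4 * se)
  }
})

test_that("baseline tables use Student t and df-aware chi-squared", {
  expect_equal(round(table_chisq_p(c(120, 42, 33), c(209, 102, 85)), 3),
               0.128)
  expect_equal(round(table_chisq_p(c(67, 39, 89), c(116, 74, 206)), 3),
               0.322)

  set.seed(124)
  cases <- make_participants(80, qrisk2 = rnorm(80, 12, 5))
  cases$smoking <- sample(c("current", "ex", "never"), 80, replace = TRUE)
  controls <- make_participants(160, qrisk2 = rnorm(160, 11, 5))
  controls$smoking <- sample(c("current", "ex", "never"), 160,
                             replace = TRUE)
  bt <- baseline_table(cases, controls,
                       continuous = "qrisk2", categorical = "smoking")
  expect_equal(bt$p_value[bt$variable == "qrisk2"],
               t.test(cases$qrisk2, controls$qrisk2,
                      var.equal = TRUE)$p.value)
  lev <- c("current", "ex", "never")
  tab <- rbind(table(factor(cases$smoking, lev)),
               table(factor(controls$smoking, lev)))
  expect_equal(bt$p_value[bt$variable == "smoking"],
               chisq.test(tab, correct = FALSE)$p.value)

  ident <- baseline_table(cases, cases, continuous = "qrisk2",
                          categorical = "smoking")
  expect_equal(ident$p_value[2], 1)
  expect_error(baseline_table(cases[0, ], controls), "non-empty")
})

test_that("the prevention model is the linear product it claims to be", {
  expect_equal(preventable_events(0, 0.25, 0.25, 0.005), 0)
  expect_equal(preventable_events(0.05, 1.0, 0.25, 0.005),
               0.05 * 0.25 * 0.005 * 1e5)  # = 6.25 per 1e5 patient-years
  e1 <- preventable_events(0.052, 0.25, 0.25, 0.004)
  e4 <- preventable_events(0.052, 1.0, 0.25, 0.004)
  expect_equal(e4 / e1, 4)
  expect_error(preventable_events(1.2, 0.5, 0.5, 0.01), "fractions")
})

test_that("evaluate_uplift wires the reclassification counts together", {
  # 20 cases: 10 high/high, 3 up, 2 down, 5 low/low
  a <- data.frame(clinical_high = c(rep(TRUE, 12), rep(FALSE, 8)),
                  irt_high = c(rep(TRUE, 10), FALSE, FALSE,
                               TRUE, TRUE, TRUE, rep(FALSE, 5)))
  rep <- evaluate_uplift(a)
  expect_equal(rep$reclass$a, 10)
  expect_equal(rep$reclass$b, 3)
  expect_equal(rep$reclass$c, 2)
  expect_equal(rep$reclass$d, 5)
  expect_equal(rep$clinical$k, 12)
  expect_equal(rep$combined$k, 15)
  expect_equal(rep$uplift$diff, 100 * 3 / 20)
  expect_equal(rep$case_nri, 100 * 1 / 20)
})
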
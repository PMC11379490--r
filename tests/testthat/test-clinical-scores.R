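# Independent oracle: evaluate the shipped coefficient CSVs term by term,
# separately from the package's vectorised implementation.
pce_oracle <- function(age, sex, race, smoker, sbp, bp_treated, diabetes,
                       tc_mgdl, hdl_mgdl) {
  tab <- read.csv(system.file("extdata", "pce_coefficients.csv",
                              package = "cvdprs"), comment.char = "#")
  g <- tab[tab$group == paste(race, sex, sep = "_"), ]
  vals <- c(ln_age = log(age), ln_age_sq = log(age)^2,
            ln_tc = log(tc_mgdl), ln_age_ln_tc = log(age) * log(tc_mgdl),
            ln_hdl = log(hdl_mgdl),
            ln_age_ln_hdl = log(age) * log(hdl_mgdl),
            ln_sbp_treated = if (bp_treated) log(sbp) else 0,
            ln_age_ln_sbp_treated = if (bp_treated) log(age) * log(sbp) else 0,
            ln_sbp_untreated = if (bp_treated) 0 else log(sbp),
            ln_age_ln_sbp_untreated = if (bp_treated) 0 else
              log(age) * log(sbp),
            smoker = smoker, ln_age_smoker = log(age) * smoker,
            diabetes = diabetes)
  xb <- 0
  for (r in seq_len(nrow(g))) {
    term <- g$term[r]
    if (term %in% names(vals)) xb <- xb + g$value[r] * vals[[term]]
  }
  100 * (1 - g$value[g$term == "s10"] ^
           exp(xb - g$value[g$term == "mean_xb"]))
}

score2_oracle <- function(age, sex, smoker, sbp, tchol, hdl, region) {
  tab <- read.csv(system.file("extdata", "score2_coefficients.csv",
                              package = "cvdprs"), comment.char = "#")
  sc <- read.csv(system.file("extdata", "score2_scales.csv",
                             package = "cvdprs"), comment.char = "#")
  g <- tab[tab$sex == sex, ]
  vals <- c(cage = (age - 60) / 5, smoker = smoker,
            csbp = (sbp - 120) / 20, ctchol = tchol - 6,
            chdl = (hdl - 1.3) / 0.5)
  vals <- c(vals, smoker_cage = vals[["smoker"]] * vals[["cage"]],
            csbp_cage = vals[["csbp"]] * vals[["cage"]],
            ctchol_cage = vals[["ctchol"]] * vals[["cage"]],
            chdl_cage = vals[["chdl"]] * vals[["cage"]])
  lp <- 0
  for (r in seq_len(nrow(g)))
    if (g$term[r] %in% names(vals)) lp <- lp + g$value[r] * vals[[g$term[r]]]
  uncal <- 1 - g$value[g$term == "s10"] ^ exp(lp)
  s <- sc[sc$region == region & sc$sex == sex, ]
  100 * (1 - exp(-exp(s$scale1 + s$scale2 * log(-log(1 - uncal)))))
}

test_that("PCE risk equals independent evaluation of the shipped tables", {
  set.seed(101)
  for (i in 1:25) {
    age <- runif(1, 40, 79)
    sex <- sample(c("male", "female"), 1)
    race <- sample(c("white", "black"), 1)
    smoker <- sample(0:1, 1); treated <- sample(0:1, 1)
    dm <- sample(0:1, 1)
    sbp <- runif(1, 95, 190)
    tc <- runif(1, 130, 320); hdl <- runif(1, 25, 95)
    expect_equal(
      pce_risk(age, sex, race, smoker, sbp, treated, dm, tc, hdl,
               chol_unit = "mg/dL"),
      pce_oracle(age, sex, race, smoker, sbp, treated, dm, tc, hdl),
      tolerance = 1e-10)
  }
})

test_that("PCE is monotone in SBP and consistent across cholesterol units", {
  base <- function(sbp) pce_risk(60, "male", "white", 0, sbp, 0, 0, 5.5, 1.3)
  risks <- vapply(seq(100, 180, 10), base, numeric(1))
  expect_true(all(diff(risks) > 0))

  r_mmol <- pce_risk(60, "female", "black", 1, 140, 1, 0, 5.2, 1.1)
  r_mgdl <- pce_risk(60, "female", "black", 1, 140, 1, 0,
                     5.2 * 38.67, 1.1 * 38.67, chol_unit = "mg/dL")
  expect_equal(r_mmol, r_mgdl, tolerance = 1e-12)

  expect_error(pce_risk(39, "male", "white", 0, 120, 0, 0, 5, 1.3), "ages")
  expect_error(pce_risk(80, "male", "white", 0, 120, 0, 0, 5, 1.3), "ages")
})

test_that("SCORE2 equals the oracle, rises with smoking, benign 40s are low", {
  set.seed(102)
  for (i in 1:25) {
    age <- runif(1, 40, 69)
    sex <- sample(c("male", "female"), 1)
    smoker <- sample(0:1, 1)
    sbp <- runif(1, 95, 190)
    tc <- runif(1, 3.5, 8.5); hdl <- runif(1, 0.7, 2.4)
    region <- sample(c("low", "moderate", "high", "very_high"), 1)
    expect_equal(score2_risk(age, sex, smoker, sbp, tc, hdl, region),
                 score2_oracle(age, sex, smoker, sbp, tc, hdl, region),
                 tolerance = 1e-10)
  }
  expect_gt(score2_risk(55, "male", 1, 140, 6, 1.3),
            score2_risk(55, "male", 0, 140, 6, 1.3))
  expect_lt(score2_risk(40, "female", 0, 110, 4.5, 1.6), 5)
  expect_error(score2_risk(75, "male", 0, 120, 5, 1.3), "ages")
  expect_error(score2_risk(55, "male", 0, 120, 5, 1.3, region = "arctic"),
               "unknown region")
})

test_that("QRISK2 passthrough returns stored scores untouched", {
  tab <- make_participants(3, qrisk2 = c(12.6, 0, 7.7))
  expect_equal(as.numeric(qrisk2_passthrough(tab)), c(12.6, 0, 7.7))
  tab$qrisk2 <- NULL
  expect_error(qrisk2_passthrough(tab), "surrogate disabled")
  out <- qrisk2_passthrough(tab, allow_surrogate = TRUE)
  expect_equal(attr(out, "source"), "surrogate")
  expect_true(all(out > 0 & out < 100))
})

test_that("the surrogate lands in the configured population band", {
  cfg <- sim_config(n_subjects = 10000, n_variants = 5, seed = 103)
  gm <- simulate_genotypes(cfg)
  coh <- simulate_cohort(cfg, gm, simulate_weights(gm, seed = 104))
  expect_gt(mean(coh$qrisk2), 8)
  expect_lt(mean(coh$qrisk2), 16)
  expect_gt(sd(coh$qrisk2), 4)
  expect_lt(sd(coh$qrisk2), 12)
})

test_that("categorisation respects guideline thresholds and partitions", {
  expect_equal(categorize(12.6, scheme = "qrisk2"), "high")
  expect_equal(categorize(9.99, scheme = "qrisk2"), "intermediate")
  expect_equal(categorize(10, scheme = "qrisk2"), "high")
  expect_equal(categorize(5, scheme = "qrisk2"), "intermediate")
  expect_equal(categorize(4.999, scheme = "qrisk2"), "low")
  expect_equal(categorize(7.5, scheme = "pce"), "high")
  expect_equal(categorize(7.49, scheme = "pce"), "intermediate")
  # same score, different age bands
  expect_equal(categorize(3.0, age = 45, scheme = "score2"), "high")
  expect_equal(categorize(3.0, age = 55, scheme = "score2"), "low")
  expect_equal(categorize(7.5, age = 72, scheme = "score2"), "high")
  expect_error(categorize(5, scheme = threshold_scheme("nope")))
  # partition: every finite score maps to exactly one category
  set.seed(105)
  sc <- runif(200, 0, 40)
  cats <- categorize(sc, scheme = "qrisk2")
  expect_true(all(cats %in% c("low", "intermediate", "high")))
})
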
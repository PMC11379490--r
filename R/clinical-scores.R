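# Coefficient tables ship as CSV under inst/extdata and are cached per
# session; provenance and variable transforms are documented in the files.
.cs_env <- new.env(parent = emptyenv())

.load_table <- function(file) {
  if (is.null(.cs_env[[file]])) {
    path <- system.file("extdata", file, package = "cvdprs")
    if (!nzchar(path)) stop("missing shipped data file: ", file)
    .cs_env[[file]] <- read.csv(path, comment.char = "#",
                                stringsAsFactors = FALSE)
  }
  .cs_env[[file]]
}

MMOL_TO_MGDL <- 38.67

#' ASCVD pooled cohort equations 10-year risk
#'
#' Race- and sex-specific Cox model for 10-year first atherosclerotic CVD
#' risk: `risk = 100 * (1 - S10 ^ exp(XB - mean_XB))` with the published
#' coefficient tables shipped as package data. Cholesterol may be given in
#' mmol/L (converted internally, x 38.67) or mg/dL. Individuals of other
#' ancestries are scored with the white coefficients, the convention the
#' source guideline recommends.
#'
#' @param age Age in years, 40-79.
#' @param sex `"male"` or `"female"`.
#' @param race `"white"`, `"black"`, or `"other"` (scored as white).
#' @param smoker Current smoker flag (0/1 or logical).
#' @param sbp Systolic blood pressure, mmHg.
#' @param bp_treated On antihypertensive treatment flag.
#' @param diabetes Diabetes flag.
#' @param total_chol,hdl Cholesterol values, units per `chol_unit`.
#' @param chol_unit `"mmol/L"` (default) or `"mg/dL"`.
#' @return 10-year risk in percent, in (0, 100). Vectorised.
#' @export
pce_risk <- function(age, sex, race = "white", smoker, sbp,
                     bp_treated = 0, diabetes = 0, total_chol, hdl,
                     chol_unit = c("mmol/L", "mg/dL")) {
  chol_unit <- match.arg(chol_unit)
  n <- length(age)
  if (any(age < 40 | age > 79))
    stop("pce_risk is defined for ages 40-79; got age outside range")
  sex <- rep_len(as.character(sex), n)
  race <- rep_len(as.character(race), n)
  race[race == "other"] <- "white"
  if (!all(sex %in% c("male", "female"))) stop("sex must be male/female")
  if (!all(race %in% c("white", "black")))
    stop("race must be white/black/other")
  smoker <- rep_len(as.numeric(smoker), n)
  bp_treated <- rep_len(as.numeric(bp_treated), n)
  diabetes <- rep_len(as.numeric(diabetes), n)
  if (chol_unit == "mmol/L") {
    total_chol <- total_chol * MMOL_TO_MGDL
    hdl <- hdl * MMOL_TO_MGDL
  }

  tab <- .load_table("pce_coefficients.csv")
  cf <- function(group, term) {
    v <- tab$value[tab$group == group & tab$term == term]
    if (length(v) == 0) 0 else v
  }
  group <- paste(race, sex, sep = "_")
  la <- log(age); lt <- log(total_chol); lh <- log(hdl); ls <- log(sbp)
  risk <- numeric(n)
  for (g in unique(group)) {
    i <- group == g
    xb <- cf(g, "ln_age") * la[i] +
      cf(g, "ln_age_sq") * la[i]^2 +
      cf(g, "ln_tc") * lt[i] +
      cf(g, "ln_age_ln_tc") * la[i] * lt[i] +
      cf(g, "ln_hdl") * lh[i] +
      cf(g, "ln_age_ln_hdl") * la[i] * lh[i] +
      ifelse(bp_treated[i] == 1,
             cf(g, "ln_sbp_treated") * ls[i] +
               cf(g, "ln_age_ln_sbp_treated") * la[i] * ls[i],
             cf(g, "ln_sbp_untreated") * ls[i] +
               cf(g, "ln_age_ln_sbp_untreated") * la[i] * ls[i]) +
      cf(g, "smoker") * smoker[i] +
      cf(g, "ln_age_smoker") * la[i] * smoker[i] +
      cf(g, "diabetes") * diabetes[i]
    risk[i] <- 100 * (1 - cf(g, "s10") ^ exp(xb - cf(g, "mean_xb")))
  }
  risk
}

#' SCORE2 10-year cardiovascular risk
#'
#' Sex-specific Cox linear predictor on centred, scaled risk factors with
#' age interactions, baseline 10-year survival, and region recalibration:
#' `calibrated = 1 - exp(-exp(scale1 + scale2 * ln(-ln(1 - uncalibrated))))`.
#' Coefficients and the four region scale pairs ship as package data.
#'
#' @param age Age in years, 40-69.
#' @param sex `"male"` or `"female"`.
#' @param smoker Current smoker flag.
#' @param sbp Systolic blood pressure, mmHg.
#' @param total_chol,hdl Cholesterol in mmol/L.
#' @param region Calibration region: `"low"`, `"moderate"`, `"high"`,
#'   `"very_high"`.
#' @return 10-year risk in percent, in (0, 100). Vectorised.
#' @export
score2_risk <- function(age, sex, smoker, sbp, total_chol, hdl,
                        region = "low") {
  n <- length(age)
  if (any(age < 40 | age > 69))
    stop("score2_risk is defined for ages 40-69; got age outside range")
  if (length(region) != 1 || is.na(region)) stop("a single region is required")
  sex <- rep_len(as.character(sex), n)
  if (!all(sex %in% c("male", "female"))) stop("sex must be male/female")
  smoker <- rep_len(as.numeric(smoker), n)

  tab <- .load_table("score2_coefficients.csv")
  scales <- .load_table("score2_scales.csv")
  if (!region %in% scales$region)
    stop("unknown region '", region, "'; expected one of: ",
         paste(unique(scales$region), collapse = ", "))
  cf <- function(s, term) tab$value[tab$sex == s & tab$term == term]

  cage <- (age - 60) / 5
  csbp <- (sbp - 120) / 20
  ctch <- (total_chol - 6) / 1
  chdl <- (hdl - 1.3) / 0.5
  risk <- numeric(n)
  for (s in unique(sex)) {
    i <- sex == s
    lp <- cf(s, "cage") * cage[i] + cf(s, "smoker") * smoker[i] +
      cf(s, "csbp") * csbp[i] + cf(s, "ctchol") * ctch[i] +
      cf(s, "chdl") * chdl[i] +
      cf(s, "smoker_cage") * smoker[i] * cage[i] +
      cf(s, "csbp_cage") * csbp[i] * cage[i] +
      cf(s, "ctchol_cage") * ctch[i] * cage[i] +
      cf(s, "chdl_cage") * chdl[i] * cage[i]
    uncal <- 1 - cf(s, "s10") ^ exp(lp)
    sc <- scales[scales$region == region & scales$sex == s, ]
    risk[i] <- 100 * (1 - exp(-exp(sc$scale1 + sc$scale2 *
                                     log(-log(1 - uncal)))))
  }
  risk
}

#' QRISK2 passthrough
#'
#' QRISK2 is a licensed algorithm and is deliberately not re-implemented:
#' in practice the score is read from GP records and treated as data. This
#' returns the stored `qrisk2` column unchanged. When the column is absent
#' and `allow_surrogate = TRUE`, the labelled [qrisk2_surrogate()] is
#' computed from the table's covariates instead (synthetic cohorts only).
#'
#' @param table A participant table.
#' @param allow_surrogate Compute the surrogate when no stored scores exist.
#' @return Numeric 10-year risk in percent; attribute `source` is
#'   `"stored"` or `"surrogate"`.
#' @export
qrisk2_passthrough <- function(table, allow_surrogate = FALSE) {
  if (!is.null(table$qrisk2)) {
    out <- as.numeric(table$qrisk2)
    attr(out, "source") <- attr(table$qrisk2, "source") %||% "stored"
    return(out)
  }
  if (!allow_surrogate)
    stop("no qrisk2 column and surrogate disabled; supply stored scores ",
         "or set allow_surrogate = TRUE")
  out <- qrisk2_surrogate(age = table$age, sex = table$sex,
                          ethnicity = table$ethnicity,
                          smoking = table$smoking, sbp = table$sbp,
                          bmi = table$bmi, total_chol = table$total_chol,
                          hdl = table$hdl, diabetes = table$diabetes)
  attr(out, "source") <- "surrogate"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logistic QRISK2 surrogate (synthetic cohorts only)
#'
#' A fixed logistic approximation that maps the generated covariates to a
#' 10-year risk percentage with the location and spread of GP-recorded
#' QRISK2 scores in a 40-74 screening population (mean about 12%, SD about
#' 7%). It is NOT the QRISK2 algorithm (which is licensed and has many more
#' inputs) and is labelled surrogate wherever it is used; it exists solely
#' so synthetic cohorts are self-contained.
#'
#' @param age Years. @param sex `"male"`/`"female"`.
#' @param ethnicity `"white"`/`"non-white"`.
#' @param smoking `"current"`, `"ex"`, `"never"`.
#' @param sbp mmHg. @param bmi kg/m^2.
#' @param total_chol,hdl mmol/L. @param diabetes 0/1.
#' @return 10-year risk in percent, in (0, 100).
#' @export
qrisk2_surrogate <- function(age, sex, ethnicity, smoking, sbp, bmi,
                             total_chol, hdl, diabetes) {
  lp <- -2.62 +
    0.072 * (age - 57.5) +
    0.40 * (sex == "male") +
    0.42 * (smoking == "current") + 0.15 * (smoking == "ex") +
    0.009 * (sbp - 133) +
    0.014 * (bmi - 28) +
    0.14 * (total_chol / hdl - 4.2) +
    0.80 * (diabetes == 1) +
    0.12 * (ethnicity != "white")
  100 * plogis(lp)
}

#' High-risk threshold schemes
#'
#' Maps a 10-year risk percentage (and age, for SCORE2) to a category.
#' Schemes follow the respective guidelines:
#' * `qrisk2`: `<5` low, `[5, 10)` intermediate, `>= 10` high.
#' * `pce`: `<5` low, `[5, 7.5)` intermediate, `>= 7.5` high.
#' * `score2`: high iff the score is at or above the age-band threshold
#'   (`< 50` years: 2.5%; `50-69`: 5%; `>= 70`: 7.5%, configurable); below
#'   threshold is reported as low (no intermediate band is used).
#'
#' Thresholds are left-closed on the high side (`>=` is high).
#'
#' @param name Scheme name: `"qrisk2"`, `"pce"`, or `"score2"`.
#' @param score2_bands For `score2`: named vector `c(age1 = t1, age2 = t2,
#'   Inf = t3)` giving the threshold for ages below each break; default
#'   `c("50" = 2.5, "70" = 5, "Inf" = 7.5)`.
#' @return A `threshold_scheme` object.
#' @export
threshold_scheme <- function(name = c("qrisk2", "pce", "score2"),
                             score2_bands = c("50" = 2.5, "70" = 5,
                                              "Inf" = 7.5)) {
  name <- match.arg(name)
  structure(list(name = name, score2_bands = score2_bands),
            class = "threshold_scheme")
}

#' Categorise a 10-year risk score against a threshold scheme
#'
#' @param score Risk in percent.
#' @param age Age in years (used by the SCORE2 scheme only).
#' @param scheme A [threshold_scheme()] or scheme name.
#' @return Character vector over `{"low", "intermediate", "high"}`; every
#'   finite score maps to exactly one category.
#' @export
#' @examples
#' categorize(12.6, scheme = "qrisk2")  # "high"
#' categorize(9.99, scheme = "qrisk2")  # "intermediate"
categorize <- function(score, age = NULL, scheme) {
  if (is.character(scheme)) scheme <- threshold_scheme(scheme)
  stopifnot(inherits(scheme, "threshold_scheme"))
  if (any(!is.finite(score))) stop("scores must be finite")
  switch(scheme$name,
    qrisk2 = ifelse(score >= 10, "high",
                    ifelse(score >= 5, "intermediate", "low")),
    pce = ifelse(score >= 7.5, "high",
                 ifelse(score >= 5, "intermediate", "low")),
    score2 = {
      if (is.null(age)) stop("the score2 scheme requires age")
      breaks <- as.numeric(names(scheme$score2_bands))
      thr <- unname(scheme$score2_bands[vapply(age, function(a)
        which(a < breaks)[1], integer(1))])
      ifelse(score >= thr, "high", "low")
    })
}
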
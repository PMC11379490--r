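#' Default covariate marginals for a synthetic NHS Health Check cohort
#'
#' Marginal distributions of the baseline covariates used by
#' [simulate_cohort()]. Defaults describe a middle-aged UK primary-care
#' screening population: invitees aged 40-74, mean age about 57.5 years,
#' roughly 62% male, 76.5% white ethnicity, about 31% current smokers and
#' 10-11% already on a statin at assessment.
#'
#' @param age_mean,age_sd Mean and SD of age in years (truncated to
#'   `age_range`).
#' @param age_range Lower and upper age bounds (years) for the screening
#'   programme (default 40-74).
#' @param male_frac Fraction male.
#' @param white_frac Fraction of white ethnicity.
#' @param smoking_probs Named probabilities for `current`, `ex`, `never`
#'   smoking; must sum to 1.
#' @param sbp_mean,sbp_sd Systolic blood pressure, mmHg.
#' @param dbp_mean,dbp_sd Diastolic blood pressure, mmHg.
#' @param bmi_mean,bmi_sd Body mass index, kg/m^2.
#' @param tchol_mean,tchol_sd Total cholesterol, mmol/L.
#' @param hdl_mean,hdl_sd HDL cholesterol, mmol/L.
#' @param diabetes_frac Fraction with diabetes.
#' @param statin_frac Fraction already taking a statin.
#' @return A named list of marginal parameters.
#' @export
covariate_marginals <- function(age_mean = 57.5, age_sd = 9.4,
                                age_range = c(40, 74),
                                male_frac = 0.62,
                                white_frac = 0.765,
                                smoking_probs = c(current = 0.31, ex = 0.19,
                                                  never = 0.50),
                                sbp_mean = 133.2, sbp_sd = 15.9,
                                dbp_mean = 80.7, dbp_sd = 10.3,
                                bmi_mean = 27.9, bmi_sd = 5.3,
                                tchol_mean = 5.5, tchol_sd = 1.1,
                                hdl_mean = 1.4, hdl_sd = 0.4,
                                diabetes_frac = 0.024,
                                statin_frac = 0.105) {
  m <- list(age_mean = age_mean, age_sd = age_sd, age_range = age_range,
            male_frac = male_frac, white_frac = white_frac,
            smoking_probs = smoking_probs,
            sbp_mean = sbp_mean, sbp_sd = sbp_sd,
            dbp_mean = dbp_mean, dbp_sd = dbp_sd,
            bmi_mean = bmi_mean, bmi_sd = bmi_sd,
            tchol_mean = tchol_mean, tchol_sd = tchol_sd,
            hdl_mean = hdl_mean, hdl_sd = hdl_sd,
            diabetes_frac = diabetes_frac, statin_frac = statin_frac)
  fr <- c(m$male_frac, m$white_frac, m$diabetes_frac, m$statin_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(m$smoking_probs) - 1) > 1e-8)
    stop("smoking_probs must sum to 1")
  if (any(m$smoking_probs < 0)) stop("smoking_probs must be non-negative")
  if (!identical(sort(names(m$smoking_probs)), c("current", "ex", "never")))
    stop("smoking_probs must be named current/ex/never")
  m
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-cohort generator: the genotype
#' panel size and allele-frequency range, the per-SD log-odds effect of the
#' standardised polygenic score on 10-year events (`prs_beta`), an optional
#' target population event rate, covariate marginals, the case-mix
#' proportions for the hierarchical event labels, and the run seed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_variants Number of variants (>= 1).
#' @param allele_freq_range Pair of effect-allele frequencies in (0, 1).
#' @param prs_beta Log-odds per SD of the standardised PRS. The default,
#'   `log(1.6)`, is a documented assumption: an odds ratio of 1.6 per SD is
#'   typical of genome-wide CVD scores.
#' @param baseline_event_rate Optional 10-year event probability in (0, 1);
#'   when supplied, the clinical log-odds are shifted by a constant so that
#'   the population mean event probability (at `prs_beta = 0`) equals it.
#'   `NULL` uses the clinical risks unshifted.
#' @param covariate_marginals See [covariate_marginals()].
#' @param event_type_probs Named probabilities over the hierarchical event
#'   labels `cvd_death`, `mi_acs`, `pci_cabg`, `stroke`; default is the
#'   observed case mix 5.6/57.9/12.8/23.5%.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10000L, n_variants = 100L,
                       allele_freq_range = c(0.05, 0.5),
                       prs_beta = log(1.6),
                       baseline_event_rate = NULL,
                       covariate_marginals = cvdprs::covariate_marginals(),
                       event_type_probs = c(cvd_death = 11, mi_acs = 113,
                                            pci_cabg = 25, stroke = 46) / 195,
                       seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (length(allele_freq_range) != 2 ||
      any(allele_freq_range <= 0) || any(allele_freq_range >= 1) ||
      allele_freq_range[1] > allele_freq_range[2])
    stop("allele_freq_range must be an increasing pair inside (0, 1)")
  if (!is.finite(prs_beta)) stop("prs_beta must be finite")
  if (!is.null(baseline_event_rate) &&
      (baseline_event_rate <= 0 || baseline_event_rate >= 1))
    stop("baseline_event_rate must lie in (0, 1)")
  if (abs(sum(event_type_probs) - 1) > 1e-8 || any(event_type_probs < 0))
    stop("event_type_probs must be non-negative and sum to 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_variants = as.integer(n_variants),
                 allele_freq_range = allele_freq_range,
                 prs_beta = prs_beta,
                 baseline_event_rate = baseline_event_rate,
                 covariate_marginals = covariate_marginals,
                 event_type_probs = event_type_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# non-complementary allele pairs, so no strand-ambiguous variants arise
# by default (A/T and C/G pairs are excluded at PRS alignment)
.allele_pairs <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T"),
                        ncol = 2, byrow = TRUE)

#' Construct a genotype matrix object
#'
#' @param dosages Numeric n x m matrix of effect-allele dosages in `[0, 2]`;
#'   `NA` marks missing calls.
#' @param variants Data frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `af` (effect-allele frequency).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  req <- c("id", "chrom", "pos", "effect_allele", "other_allele", "af")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (ncol(dosages) != nrow(variants))
    stop("ncol(dosages) must equal nrow(variants)")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (any(variants$pos <= 0) || any(variants$pos != floor(variants$pos)))
    stop("positions must be positive integers")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("non-missing dosages must lie in [0, 2]")
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = as.data.frame(variants)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Simulate hard-call genotypes in Hardy-Weinberg proportions
#'
#' Draws per-variant effect-allele frequencies uniformly from
#' `config$allele_freq_range` and genotypes as Binomial(2, af) dosages, i.e.
#' exact Hardy-Weinberg proportions before any injected violations.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] with variant metadata (unique ids,
#'   chromosome, 1-based position, non-complementary allele pair, drawn
#'   allele frequency) and no missing calls.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$n_variants
  af <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
  dos <- matrix(rbinom(n * m, 2L, rep(af, each = n)), nrow = n, ncol = m)
  pair <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                        drop = FALSE]
  swap <- runif(m) < 0.5
  eff <- ifelse(swap, pair[, 2], pair[, 1])
  oth <- ifelse(swap, pair[, 1], pair[, 2])
  variants <- data.frame(
    id = sprintf("var%05d", seq_len(m)),
    chrom = as.character(sample.int(22L, m, replace = TRUE)),
    pos = sort(sample.int(1e8L, m, replace = FALSE)),
    effect_allele = eff, other_allele = oth, af = af,
    stringsAsFactors = FALSE)
  genotype_matrix(dos, variants)
}

#' Simulate a PRS weight set for a genotype panel
#'
#' Gaussian per-allele weights for every variant in `gm`, on the log-odds
#' scale of the underlying score. The raw score is standardised downstream,
#' so only the relative spread of weights matters.
#'
#' @param gm A [genotype_matrix()].
#' @param weight_sd SD of the Gaussian weights.
#' @param seed Integer seed.
#' @return A `prs_weights` data frame (see [read_weights()] for columns).
#' @export
simulate_weights <- function(gm, weight_sd = 0.1, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  set.seed(seed)
  v <- gm$variants
  w <- data.frame(rsID = v$id, chr_name = v$chrom, chr_position = v$pos,
                  effect_allele = v$effect_allele,
                  other_allele = v$other_allele,
                  effect_weight = rnorm(nrow(v), 0, weight_sd),
                  stringsAsFactors = FALSE)
  class(w) <- c("prs_weights", "data.frame")
  w
}

#' Plant QC-filter violations into a clean genotype matrix
#'
#' Modifies disjoint sets of variants so that exactly the requested number
#' fail each pre-imputation filter: low call rate (calls set missing to
#' reach the target call rate), low minor allele frequency (dosages set
#' to the monomorphic major genotype), and Hardy-Weinberg violation (all
#' subjects made heterozygous, allele frequency 0.5 — grossly excess
#' heterozygosity).
#'
#' @param gm A [genotype_matrix()].
#' @param n_low_call,n_low_maf,n_hwe Counts of variants to corrupt per
#'   filter; must sum to at most the number of variants.
#' @param call_rate Call rate planted for low-call variants (default 0.90).
#' @param seed Integer seed.
#' @return The modified `genotype_matrix` with attribute `planted`, a list
#'   of the variant ids assigned to each violation.
#' @export
inject_qc_violations <- function(gm, n_low_call = 0L, n_low_maf = 0L,
                                 n_hwe = 0L, call_rate = 0.90, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- ncol(gm$dosages)
  n <- nrow(gm$dosages)
  total <- n_low_call + n_low_maf + n_hwe
  if (total > m)
    stop("requested violations (", total, ") exceed n_variants (", m, ")")
  set.seed(seed)
  idx <- sample.int(m, total)
  i_call <- idx[seq_len(n_low_call)]
  i_maf <- idx[n_low_call + seq_len(n_low_maf)]
  i_hwe <- idx[n_low_call + n_low_maf + seq_len(n_hwe)]
  for (j in i_call) {
    n_miss <- max(ceiling((1 - call_rate) * n), 1L)
    gm$dosages[sample.int(n, n_miss), j] <- NA_real_
  }
  for (j in i_maf) {
    gm$dosages[, j] <- 0
    gm$variants$af[j] <- 0
  }
  for (j in i_hwe) {
    gm$dosages[, j] <- 1
    gm$variants$af[j] <- 0.5
  }
  attr(gm, "planted") <- list(low_call = gm$variants$id[i_call],
                              low_maf = gm$variants$id[i_maf],
                              hwe = gm$variants$id[i_hwe])
  gm
}

# Shift constant c such that mean(plogis(lp + c)) == rate, solved on a
# bracketing interval; lp are clinical log-odds.
.calibrate_offset <- function(lp, rate) {
  f <- function(c) mean(plogis(lp + c)) - rate
  uniroot(f, lower = -20, upper = 20, tol = 1e-10)$root
}

#' Simulate a screened cohort with PRS-dependent 10-year events
#'
#' Generates baseline covariates from the configured marginals (drawn
#' independently), computes a clinical 10-year risk via the labelled
#' QRISK2 surrogate ([qrisk2_surrogate()]), scores and cohort-standardises
#' the polygenic score from `gm` and `weights`, and draws the 10-year event
#' indicator from
#' \deqn{logit P(event) = logit(clinical/100) + \beta z - \beta^2/2,}
#' where `z` is the standardised PRS. The \eqn{-\beta^2/2} offset makes the
#' generator mean-preserving on the odds scale: marginally over
#' \eqn{z \sim N(0,1)} the mean event odds equal the clinical odds, so the
#' generator is the exact inverse model of the integrated risk tool and
#' supports parameter-recovery tests. Event types are assigned by the
#' configured hierarchy proportions; event times are uniform on (0, 10]
#' years.
#'
#' @param config A [sim_config()].
#' @param gm A [genotype_matrix()] for the same subjects.
#' @param weights A PRS weight set scoring `gm`'s variants.
#' @return A `participant table` data frame: `id`, `age`, `sex`,
#'   `ethnicity`, `smoking`, `sbp`, `dbp`, `bmi`, `total_chol`, `hdl`,
#'   `diabetes`, `statin`, `qrisk2` (surrogate, %), `prs_z` (the generative
#'   standardised score), `event`, `event_type`, `event_time`. The QRISK2
#'   column carries attribute `source = "surrogate"`.
#' @export
simulate_cohort <- function(config, gm, weights) {
  stopifnot(inherits(config, "sim_config"), inherits(gm, "genotype_matrix"))
  n <- config$n_subjects
  if (nrow(gm$dosages) != n)
    stop("genotype matrix rows must equal config$n_subjects")
  mar <- config$covariate_marginals
  set.seed(config$seed + 1L)

  rtrunc <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)
  age <- rtrunc(n, mar$age_mean, mar$age_sd, mar$age_range[1], mar$age_range[2])
  sex <- ifelse(runif(n) < mar$male_frac, "male", "female")
  ethnicity <- ifelse(runif(n) < mar$white_frac, "white", "non-white")
  smoking <- sample(names(mar$smoking_probs), n, replace = TRUE,
                    prob = mar$smoking_probs)
  sbp <- rtrunc(n, mar$sbp_mean, mar$sbp_sd, 80, 220)
  dbp <- rtrunc(n, mar$dbp_mean, mar$dbp_sd, 40, 140)
  bmi <- rtrunc(n, mar$bmi_mean, mar$bmi_sd, 15, 55)
  total_chol <- rtrunc(n, mar$tchol_mean, mar$tchol_sd, 2.0, 12)
  hdl <- rtrunc(n, mar$hdl_mean, mar$hdl_sd, 0.5, 3.5)
  diabetes <- as.integer(runif(n) < mar$diabetes_frac)
  statin <- as.integer(runif(n) < mar$statin_frac)

  qrisk2 <- qrisk2_surrogate(age = age, sex = sex, ethnicity = ethnicity,
                             smoking = smoking, sbp = sbp, bmi = bmi,
                             total_chol = total_chol, hdl = hdl,
                             diabetes = diabetes)

  raw <- score_prs(gm, weights)$raw
  z <- as.numeric(scale(raw))
  if (!all(is.finite(z))) stop("degenerate PRS: zero variance across cohort")

  lp <- qlogis(qrisk2 / 100)
  if (!all(is.finite(lp))) {
    bad <- which(!is.finite(lp))[1]
    stop("clinical risk outside (0, 100) for subject ", bad,
         " (qrisk2 = ", qrisk2[bad], ")")
  }
  if (!is.null(config$baseline_event_rate))
    lp <- lp + .calibrate_offset(lp, config$baseline_event_rate)
  beta <- config$prs_beta
  p <- plogis(lp + beta * z - beta^2 / 2)
  event <- as.integer(runif(n) < p)
  event_type <- rep(NA_character_, n)
  ne <- sum(event)
  if (ne > 0)
    event_type[event == 1] <- sample(names(config$event_type_probs), ne,
                                     replace = TRUE,
                                     prob = config$event_type_probs)
  event_time <- rep(NA_real_, n)
  if (ne > 0) event_time[event == 1] <- runif(ne, 0, 10)

  tab <- data.frame(id = sprintf("S%06d", seq_len(n)),
                    age = age, sex = sex, ethnicity = ethnicity,
                    smoking = smoking, sbp = sbp, dbp = dbp, bmi = bmi,
                    total_chol = total_chol, hdl = hdl,
                    diabetes = diabetes, statin = statin,
                    qrisk2 = qrisk2, prs_z = z,
                    event = event, event_type = event_type,
                    event_time = event_time,
                    stringsAsFactors = FALSE)
  attr(tab$qrisk2, "source") <- "surrogate"
  tab
}
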
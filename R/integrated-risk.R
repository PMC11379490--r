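#' Integrated risk tool configuration
#'
#' The integrated risk tool (IRT) updates a clinical 10-year risk with the
#' standardised polygenic score on the log-odds scale. `beta` is the
#' log-odds per SD of PRS; `calibration_offset` (default `beta^2/2`) keeps
#' the combination mean-preserving on the odds scale when the PRS is
#' standard normal and independent of the clinical score, so the IRT
#' returns risk on the same percentage scale and actionable threshold as
#' the clinical score. Set the offset to 0 to mimic an uncalibrated
#' combination.
#'
#' @param beta Log-odds per PRS SD; default `log(1.6)` (documented
#'   assumption, see the methods vignette).
#' @param calibration_offset Log-odds constant subtracted from every
#'   combined linear predictor.
#' @param scheme Threshold scheme name or [threshold_scheme()] the IRT
#'   inherits from its clinical score.
#' @return An `irt_config` object.
#' @export
irt_config <- function(beta = log(1.6), calibration_offset = beta^2 / 2,
                       scheme = "qrisk2") {
  if (!is.finite(beta) || !is.finite(calibration_offset))
    stop("beta and calibration_offset must be finite")
  if (is.character(scheme)) scheme <- threshold_scheme(scheme)
  structure(list(beta = beta, calibration_offset = calibration_offset,
                 scheme = scheme), class = "irt_config")
}

#' Combine clinical risk with the standardised PRS
#'
#' `irt = 100 * logistic(logit(clinical/100) + beta * prs_z - offset)`.
#' Strictly increasing in both the clinical risk and the PRS; the identity
#' map when `beta = 0` (the default offset is then also 0).
#'
#' @param clinical Clinical 10-year risk in percent, strictly inside
#'   (0, 100).
#' @param prs_z Standardised PRS.
#' @param cfg An [irt_config()].
#' @return IRT 10-year risk in percent, in (0, 100). Vectorised.
#' @export
integrate_risk <- function(clinical, prs_z, cfg = irt_config()) {
  stopifnot(inherits(cfg, "irt_config"))
  if (any(!is.finite(clinical)) || any(clinical <= 0) || any(clinical >= 100))
    stop("clinical risk must lie strictly inside (0, 100) percent")
  if (any(!is.finite(prs_z))) stop("prs_z must be finite")
  100 * plogis(qlogis(clinical / 100) + cfg$beta * prs_z -
                 cfg$calibration_offset)
}

#' Per-subject risk assessment: clinical vs integrated categories
#'
#' Computes the clinical and IRT risk categories under the configured
#' threshold scheme and derives the reclassification flags: `combined_high`
#' (high by the clinical score OR by the IRT — the union rule) and
#' `direction` (`up` = clinical not-high but IRT high; `down` = clinical
#' high but IRT not-high; otherwise `none`). Subjects with missing PRS are
#' excluded and reported.
#'
#' @param table Participant table with a `qrisk2` (or other clinical score)
#'   column named by `score_col`.
#' @param prs_z Standardised PRS vector aligned to `table` rows.
#' @param cfg An [irt_config()]; its scheme categorises both scores.
#' @param score_col Name of the clinical score column (default "qrisk2").
#' @return A data frame of class `risk_assessment`: `id`, `clinical_pct`,
#'   `clinical_cat`, `irt_pct`, `irt_cat`, `clinical_high`, `irt_high`,
#'   `combined_high`, `direction`; attribute `counts` holds the up/down/none
#'   totals and `n_excluded` the number dropped for missing PRS.
#' @export
assess_risk <- function(table, prs_z, cfg = irt_config(),
                        score_col = "qrisk2") {
  stopifnot(inherits(cfg, "irt_config"))
  clinical <- as.numeric(table[[score_col]])
  if (is.null(table[[score_col]])) stop("missing score column: ", score_col)
  keep <- is.finite(prs_z)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(n_excluded, " subject(s) excluded for missing PRS")
  table <- table[keep, , drop = FALSE]
  clinical <- clinical[keep]
  prs_z <- prs_z[keep]

  irt <- integrate_risk(clinical, prs_z, cfg)
  age <- table$age
  clin_cat <- categorize(clinical, age, cfg$scheme)
  irt_cat <- categorize(irt, age, cfg$scheme)
  clin_high <- clin_cat == "high"
  irt_high <- irt_cat == "high"
  direction <- ifelse(!clin_high & irt_high, "up",
                      ifelse(clin_high & !irt_high, "down", "none"))
  out <- data.frame(id = table$id %||% seq_len(nrow(table)),
                    clinical_pct = clinical, clinical_cat = clin_cat,
                    irt_pct = irt, irt_cat = irt_cat,
                    clinical_high = clin_high, irt_high = irt_high,
                    combined_high = clin_high | irt_high,
                    direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(up = sum(direction == "up"),
                           down = sum(direction == "down"),
                           none = sum(direction == "none"))
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("risk_assessment", "data.frame")
  out
}
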
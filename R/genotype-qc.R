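#' Pre-imputation variant QC thresholds
#'
#' Defaults are the standard array-QC filters applied before imputation:
#' exclude variants with call rate below 98%, minor allele frequency below
#' 0.005, or exact Hardy-Weinberg test p-value below 1e-6.
#'
#' @param min_call_rate Minimum fraction of non-missing calls, in (0, 1).
#' @param min_maf Minimum minor allele frequency, in (0, 1).
#' @param hwe_p_floor Minimum Hardy-Weinberg exact p-value, in (0, 1).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.98, min_maf = 0.005,
                          hwe_p_floor = 1e-6) {
  v <- c(min_call_rate, hwe_p_floor)
  if (any(!is.finite(v)) || any(v <= 0) || any(v >= 1))
    stop("call-rate and HWE thresholds must lie in (0, 1)")
  if (!is.finite(min_maf) || min_maf < 0 || min_maf >= 1)
    stop("min_maf must lie in [0, 1); 0 disables the MAF filter")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor), class = "qc_thresholds")
}

#' Exact test for Hardy-Weinberg proportions
#'
#' Two-sided conditional exact test on genotype counts: given the observed
#' allele counts, the p-value is the total conditional probability of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count. Probabilities are computed by the stable
#' mid-out recurrence on the heterozygote count.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (AA homozygote,
#'   heterozygote, aa homozygote); total must be >= 1.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # HW proportions: p = 1
#' hwe_exact_test(50, 0, 50)    # gross heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype is required")
  n_a <- 2 * n_aa + n_Aa
  n_rare <- min(n_a, 2L * n - n_a)
  if (n_rare == 0) return(1)  # monomorphic: single attainable table

  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # unnormalised probabilities by recurrence from the smallest het count:
  # moving one rare and one common homozygote into two heterozygotes
  # multiplies the probability by 4*hom_r*hom_c / ((h+2)*(h+1)).
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    logp[k] <- logp[k - 1L] +
      log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hets == n_Aa]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Apply pre-imputation variant QC filters
#'
#' Filters are applied in the fixed order call rate, then minor allele
#' frequency, then Hardy-Weinberg: a variant is attributed to the first
#' filter it fails. MAF is computed from non-missing dosages; for the exact
#' Hardy-Weinberg test, dosages are rounded to the nearest called genotype
#' (0/1/2) and the test is run over all subjects.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with `genotypes` (the surviving [genotype_matrix()], with
#'   `af` recomputed from non-missing dosages) and `report`, a `qc_report`
#'   list: per-filter removed ids and counts, and the surviving count.
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  d <- gm$dosages
  if (ncol(d) == 0) stop("genotype matrix has no variants")
  m <- ncol(d)

  call_rate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  maf <- pmin(af, 1 - af)

  g <- round(d)
  g[g < 0] <- 0; g[g > 2] <- 2
  hwe_p <- vapply(seq_len(m), function(j) {
    gj <- g[!is.na(g[, j]), j]
    if (length(gj) == 0) return(1)
    hwe_exact_test(sum(gj == 0), sum(gj == 1), sum(gj == 2))
  }, numeric(1))

  fail_call <- call_rate < thresholds$min_call_rate
  fail_maf <- !fail_call & (is.na(maf) | maf < thresholds$min_maf)
  fail_hwe <- !fail_call & !fail_maf & hwe_p < thresholds$hwe_p_floor
  keep <- !(fail_call | fail_maf | fail_hwe)

  ids <- gm$variants$id
  report <- structure(list(
    n_input = m,
    n_removed_call_rate = sum(fail_call),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_surviving = sum(keep),
    removed_call_rate = ids[fail_call],
    removed_maf = ids[fail_maf],
    removed_hwe = ids[fail_hwe],
    thresholds = thresholds), class = "qc_report")

  out <- genotype_matrix(d[, keep, drop = FALSE],
                         gm$variants[keep, , drop = FALSE])
  out$variants$af <- af[keep]
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d variants in; removed %d (call rate)",
                     " + %d (MAF) + %d (HWE); %d surviving\n"),
              x$n_input, x$n_removed_call_rate, x$n_removed_maf,
              x$n_removed_hwe, x$n_surviving))
  invisible(x)
}
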
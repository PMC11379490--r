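# Shared fixture builders and independent oracles.

# A tiny genotype matrix from explicit dosages / metadata.
make_gm <- function(dosages, effect = NULL, other = NULL, af = NULL,
                    chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  genotype_matrix(dosages, data.frame(
    id = paste0("v", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% seq_len(m) * 100L,
    effect_allele = effect %||% rep("A", m),
    other_allele = other %||% rep("G", m),
    af = af %||% colMeans(dosages, na.rm = TRUE) / 2,
    stringsAsFactors = FALSE))
}

make_weights <- function(gm, w) {
  v <- gm$variants
  out <- data.frame(rsID = v$id, chr_name = v$chrom, chr_position = v$pos,
                    effect_allele = v$effect_allele,
                    other_allele = v$other_allele,
                    effect_weight = w, stringsAsFactors = FALSE)
  class(out) <- c("prs_weights", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent HWE oracle: direct log-factorial enumeration of the
# conditional distribution of the heterozygote count given allele counts.
hwe_brute <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  hom_r <- (n_rare - hets) / 2
  hom_c <- n - hets - hom_r
  logp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(hets) -
    lfactorial(hom_c) + hets * log(2) +
    lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hets == n_Aa]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Double-loop PRS oracle (mean-imputed missing effective dosages).
score_brute <- function(gm, weights) {
  v <- gm$variants
  n <- nrow(gm$dosages)
  eff <- matrix(NA_real_, n, nrow(weights))
  wvec <- numeric(nrow(weights))
  for (j in seq_len(nrow(weights))) {
    gi <- which(v$id == weights$rsID[j])
    if (length(gi) != 1) next
    flip <- weights$effect_allele[j] == v$other_allele[gi]
    for (i in seq_len(n)) {
      d <- gm$dosages[i, gi]
      eff[i, j] <- if (flip) 2 - d else d
    }
    wvec[j] <- weights$effect_weight[j]
  }
  scores <- numeric(n)
  for (j in seq_len(ncol(eff))) {
    col <- eff[, j]
    mu <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- mu
    for (i in seq_len(n)) scores[i] <- scores[i] + wvec[j] * col[i]
  }
  scores
}

# Minimal participant table for evaluation-level tests.
make_participants <- function(n, qrisk2, event = 0,
                              event_type = NA_character_) {
  data.frame(id = paste0("P", seq_len(n)),
             age = rep(55, n), sex = rep("male", n),
             ethnicity = rep("white", n), smoking = rep("never", n),
             sbp = rep(130, n), dbp = rep(80, n), bmi = rep(27, n),
             total_chol = rep(5.5, n), hdl = rep(1.4, n),
             diabetes = 0L, statin = 0L,
             qrisk2 = rep_len(qrisk2, n),
             event = rep_len(event, n),
             event_type = rep_len(event_type, n),
             event_time = NA_real_, stringsAsFactors = FALSE)
}
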
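#' Align a PRS weight set to a genotype panel
#'
#' Matches weight-file variants to panel variants by shared id (or by
#' `chrom:pos` where either side lacks ids), checks allele concordance, and
#' classifies each match as `direct` (weight effect allele equals the
#' panel's counted allele) or `flipped` (weight effect allele equals the
#' panel's other allele, so the effective dosage is `2 - d`).
#' Strand-ambiguous variants (A/T or C/G allele pairs) are excluded and
#' counted, since no strand information is modelled; matches whose allele
#' pair disagrees are dropped as mismatches.
#'
#' @param gm A [genotype_matrix()].
#' @param weights A PRS weight set (see [read_weights()]).
#' @return A list of class `prs_alignment`: `map`, a data frame with
#'   `variant_idx` (column in `gm`), `weight`, `flipped`; and counts
#'   `n_matched`, `n_flipped`, `n_ambiguous`, `n_mismatch`,
#'   `unmatched_weights` (ids in the weight set absent from the panel).
#' @export
align_weights <- function(gm, weights) {
  stopifnot(inherits(gm, "genotype_matrix"))
  req <- c("rsID", "effect_allele", "other_allele", "effect_weight")
  if (!all(req %in% names(weights)))
    stop("weight set must have columns: ", paste(req, collapse = ", "))
  if (!all(is.finite(weights$effect_weight)))
    stop("weights must be finite")

  wkey <- as.character(weights$rsID)
  gkey <- as.character(gm$variants$id)
  use_pos <- anyNA(wkey) || anyNA(gkey) || !any(wkey %in% gkey)
  if (use_pos) {
    if (!all(c("chr_name", "chr_position") %in% names(weights)))
      stop("no id overlap and no chr_name/chr_position columns to fall back on")
    wkey <- paste(weights$chr_name, weights$chr_position, sep = ":")
    gkey <- paste(gm$variants$chrom, gm$variants$pos, sep = ":")
  }
  if (anyDuplicated(wkey))
    stop("duplicate keys in weight set: ",
         paste(unique(wkey[duplicated(wkey)]), collapse = ", "))
  if (anyDuplicated(gkey))
    stop("duplicate keys in genotype panel: ",
         paste(unique(gkey[duplicated(gkey)]), collapse = ", "))

  gi <- match(wkey, gkey)
  matched <- !is.na(gi)
  unmatched <- wkey[!matched]

  wi <- which(matched)
  gi <- gi[matched]
  we <- toupper(weights$effect_allele[wi])
  wo <- toupper(weights$other_allele[wi])
  ge <- toupper(gm$variants$effect_allele[gi])
  go <- toupper(gm$variants$other_allele[gi])

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- we == comp[wo]
  direct <- we == ge & wo == go
  flipped <- we == go & wo == ge
  mismatch <- !direct & !flipped
  keep <- !ambiguous & !mismatch

  map <- data.frame(variant_idx = gi[keep],
                    weight = weights$effect_weight[wi][keep],
                    flipped = flipped[keep])
  structure(list(map = map,
                 n_matched = sum(keep),
                 n_flipped = sum(flipped[keep]),
                 n_ambiguous = sum(ambiguous),
                 n_mismatch = sum(mismatch & !ambiguous),
                 unmatched_weights = unmatched),
            class = "prs_alignment")
}

#' Score a polygenic risk score from dosages and weights
#'
#' Computes `raw_i = sum_j w_j * e_ij` over aligned variants, where the
#' effective dosage `e_ij` is the dosage for direct matches and `2 - d` for
#' flipped matches. Missing dosages are imputed to the variant's mean
#' effective dosage (`2 x` effect-allele frequency) under the default
#' policy; the alternative `"skip"` policy drops missing variants for that
#' subject and rescales by the number of scored variants.
#'
#' @param gm A [genotype_matrix()].
#' @param weights A PRS weight set.
#' @param alignment Optional precomputed [align_weights()] result.
#' @param missing_policy `"mean_impute"` (default) or `"skip"`.
#' @return A data frame with `id` (subject index or rownames), `raw`, and
#'   `n_missing` (count of missing aligned variants per subject). Subjects
#'   missing every aligned variant get `raw = NA` and a warning, never a
#'   silent 0.
#' @export
score_prs <- function(gm, weights, alignment = NULL,
                      missing_policy = c("mean_impute", "skip")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  missing_policy <- match.arg(missing_policy)
  if (is.null(alignment)) alignment <- align_weights(gm, weights)
  map <- alignment$map
  if (nrow(map) == 0) stop("no variants aligned; cannot score")

  d <- gm$dosages[, map$variant_idx, drop = FALSE]
  e <- sweep(d, 2, ifelse(map$flipped, 2, 0), function(x, a) abs(a - x))
  # abs(0 - x) = x for direct; abs(2 - x) = 2 - x for d in [0,2]
  miss <- is.na(e)
  n_missing <- rowSums(miss)
  k <- ncol(e)

  if (missing_policy == "mean_impute") {
    mu <- colMeans(e, na.rm = TRUE)
    mu[is.nan(mu)] <- 2 * gm$variants$af[map$variant_idx][is.nan(mu)]
    for (j in which(colSums(miss) > 0)) e[miss[, j], j] <- mu[j]
    raw <- as.numeric(e %*% map$weight)
  } else {
    e0 <- e
    e0[miss] <- 0
    raw <- as.numeric(e0 %*% map$weight)
    n_used <- k - n_missing
    raw <- ifelse(n_used > 0, raw * k / n_used, NA_real_)
  }
  all_missing <- n_missing == k
  raw[all_missing] <- NA_real_
  if (any(all_missing))
    warning(sum(all_missing), " subject(s) missing all aligned variants; ",
            "scores set to NA")
  ids <- rownames(gm$dosages)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(gm$dosages)))
  data.frame(id = ids, raw = raw, n_missing = n_missing,
             stringsAsFactors = FALSE)
}

#' Principal components of a genotype panel
#'
#' Truncated SVD of the column-centred dosage matrix (missing dosages
#' imputed to the column mean), giving the ancestry axes used to
#' standardise raw polygenic scores. The returned object can project new
#' subjects into the same PC space.
#'
#' @param gm A [genotype_matrix()] (the reference panel).
#' @param K Number of components.
#' @return A list of class `genotype_pca`: `scores` (n x K), `rotation`,
#'   `center`, `K`.
#' @export
genotype_pcs <- function(gm, K = 4L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  K <- min(K, ncol(d), nrow(d) - 1L)
  pc <- prcomp(d, center = TRUE, scale. = FALSE, rank. = K)
  structure(list(scores = pc$x[, seq_len(K), drop = FALSE],
                 rotation = pc$rotation[, seq_len(K), drop = FALSE],
                 center = pc$center, K = K),
            class = "genotype_pca")
}

#' Project subjects onto reference principal components
#'
#' @param pca A [genotype_pcs()] object.
#' @param gm A [genotype_matrix()] over the same variants (same order).
#' @return An n x K matrix of PC scores in the reference space.
#' @export
project_pcs <- function(pca, gm) {
  stopifnot(inherits(pca, "genotype_pca"), inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  if (ncol(d) != length(pca$center))
    stop("panel has ", ncol(d), " variants; PCA expects ", length(pca$center))
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- pca$center[j]
  }
  sweep(d, 2, pca$center) %*% pca$rotation
}

#' Fit the ancestry standardisation model for raw PRS
#'
#' Regresses raw scores from an external reference sample on K principal
#' components by least squares and stores the residual SD, so that study
#' scores can be standardised to approximately zero mean and unit variance
#' given ancestry. With `K = 0` this reduces to plain z-scoring against the
#' reference mean and SD. A single homoscedastic residual SD is used; see
#' the methods vignette for the rationale and the PC-regressed variance
#' alternative.
#'
#' @param raw Numeric raw scores of the reference sample.
#' @param pcs Reference PC matrix (n x >= K); ignored when `K = 0`.
#' @param K Number of PCs for the mean model.
#' @return A list of class `ancestry_model`: `K`, `coef` (intercept + K
#'   slopes), `resid_sd`.
#' @export
fit_ancestry_model <- function(raw, pcs = NULL, K = 0L) {
  raw <- as.numeric(raw)
  n <- length(raw)
  if (n <= K + 1) stop("reference size must exceed K + 1")
  if (K == 0) {
    cf <- c(intercept = mean(raw))
    rsd <- sd(raw)
  } else {
    pcs <- as.matrix(pcs)[, seq_len(K), drop = FALSE]
    X <- cbind(1, pcs)
    if (qr(X)$rank < ncol(X)) stop("collinear principal components")
    fit <- lm.fit(X, raw)
    cf <- fit$coefficients
    names(cf) <- c("intercept", paste0("PC", seq_len(K)))
    rsd <- sqrt(sum(fit$residuals^2) / (n - K - 1))
  }
  if (!is.finite(rsd)) stop("residual SD is not finite")
  structure(list(K = K, coef = cf, resid_sd = rsd),
            class = "ancestry_model")
}

#' Standardise raw PRS given ancestry PCs
#'
#' `PRS_z = (raw - predicted mean from PCs) / residual SD` under the fitted
#' [fit_ancestry_model()]. In the reference sample the result has mean
#' approximately 0 and SD approximately 1.
#'
#' @param raw Numeric raw scores.
#' @param pcs PC matrix for these subjects (ignored when the model has
#'   `K = 0`).
#' @param model An `ancestry_model`.
#' @param sd_tol Error if the model residual SD is below this (degenerate
#'   reference fit).
#' @return A data frame of class `standardized_prs` with columns `raw`,
#'   `prs_z`.
#' @export
standardize_prs <- function(raw, pcs = NULL, model, sd_tol = 1e-8) {
  stopifnot(inherits(model, "ancestry_model"))
  if (model$resid_sd < sd_tol)
    stop("residual SD below tolerance (", model$resid_sd,
         "): reference scores are (near-)deterministic in the PCs")
  raw <- as.numeric(raw)
  if (model$K == 0) {
    mu <- model$coef[["intercept"]]
  } else {
    pcs <- as.matrix(pcs)[, seq_len(model$K), drop = FALSE]
    mu <- as.numeric(cbind(1, pcs) %*% model$coef)
  }
  out <- data.frame(raw = raw, prs_z = (raw - mu) / model$resid_sd)
  class(out) <- c("standardized_prs", "data.frame")
  out
}
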
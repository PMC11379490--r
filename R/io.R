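.provenance_line <- function(config_hash = "none") {
  sprintf("# cvdprs %s config_hash=%s", .cvdprs_version(), config_hash)
}

#' Read a genotype dosage matrix
#'
#' Supports two formats. `vcf`: dosages from the `DS` FORMAT field (parsed
#' with vcfR); records lacking `DS` fall back to a hard-call dosage from
#' `GT`, with a message. `dosage`: the package's tab-delimited layout —
#' variant metadata columns (`id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `af`) followed by one column per subject; `#` lines are
#' ignored. Positions are 1-based throughout.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    fmt_keys <- strsplit(v@gt[, "FORMAT"], ":")
    has_ds <- vapply(fmt_keys, function(k) "DS" %in% k, logical(1))
    n_var <- nrow(fix)
    if (all(has_ds)) {
      dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    } else {
      message(sum(!has_ds), " record(s) without DS; using GT hard calls")
      dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
      gt <- vcfR::extract.gt(v, element = "GT")
      hard <- matrix(vapply(gt, function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1]]))
      }, numeric(1)), nrow = n_var)
      miss <- is.na(dos)
      dos[miss] <- hard[miss]
    }
    dos <- t(dos)  # vcfR is variants x subjects
    variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                           pos = as.integer(fix$POS),
                           effect_allele = fix$ALT, other_allele = fix$REF,
                           af = colMeans(dos, na.rm = TRUE) / 2,
                           stringsAsFactors = FALSE)
    gm <- genotype_matrix(dos, variants)
    return(gm)
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  meta_cols <- c("id", "chrom", "pos", "effect_allele", "other_allele", "af")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss))
    stop("dosage file missing column(s): ", paste(miss, collapse = ", "))
  subj <- setdiff(names(tab), meta_cols)
  if (length(subj) == 0) stop("dosage file has no subject columns")
  dos <- t(as.matrix(tab[, subj, drop = FALSE]))
  rownames(dos) <- subj
  genotype_matrix(dos, tab[, meta_cols])
}

#' Write a genotype matrix
#'
#' `dosage` writes the package's tab-delimited layout with a provenance
#' header line; `vcf` writes a minimal VCFv4.2 with the dosage in the `DS`
#' FORMAT field (effect allele as ALT). Missing dosages become `.` (VCF)
#' or `NA` (dosage).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param format `"dosage"` or `"vcf"`.
#' @param ids Subject ids (default `S1..Sn` or dosage rownames).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("dosage", "vcf"),
                            ids = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  format <- match.arg(format)
  n <- nrow(gm$dosages)
  if (is.null(ids)) ids <- rownames(gm$dosages) %||% paste0("S", seq_len(n))
  if (format == "dosage") {
    tab <- cbind(gm$variants, as.data.frame(t(gm$dosages)))
    names(tab) <- c(names(gm$variants), ids)
    con <- file(path, "w")
    writeLines(.provenance_line(), con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  } else {
    v <- gm$variants
    ds <- apply(gm$dosages, 1, function(r)
      ifelse(is.na(r), ".", formatC(r, format = "g", digits = 6)))
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(v))
    gtcols <- apply(ds, 1, paste, collapse = "\t")
    lines <- c("##fileformat=VCFv4.2",
               sprintf("##source=cvdprs_%s", .cvdprs_version()),
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t"),
               paste(v$chrom, v$pos, v$id, v$other_allele, v$effect_allele,
                     ".", "PASS", ".", "DS", gtcols, sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a PRS weight file
#'
#' Tab-delimited with header, PGS-Catalog-compatible columns: `rsID`,
#' `chr_name`, `chr_position`, `effect_allele`, `other_allele`,
#' `effect_weight`. Comment lines starting `#` are skipped; duplicate
#' `rsID`s are an error.
#'
#' @param path File path.
#' @return A `prs_weights` data frame.
#' @export
read_weights <- function(path) {
  w <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("rsID", "chr_name", "chr_position", "effect_allele",
           "other_allele", "effect_weight")
  miss <- setdiff(req, names(w))
  if (length(miss))
    stop("weight file missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(w$rsID))
    stop("duplicate rsID(s) in weight file: ",
         paste(unique(w$rsID[duplicated(w$rsID)]), collapse = ", "))
  if (!all(is.finite(w$effect_weight))) stop("weights must be finite")
  class(w) <- c("prs_weights", "data.frame")
  w
}

#' Write a PRS weight file
#'
#' @param weights A `prs_weights` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  con <- file(path, "w")
  writeLines(.provenance_line(), con)
  utils::write.table(as.data.frame(weights), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write / read a participant table as CSV
#'
#' The column dictionary is documented in [simulate_cohort()].
#'
#' @param table Participant table. @param path File path.
#' @return `path` / the table.
#' @export
write_participants <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' End-to-end pipeline configuration
#'
#' Collects every stage's parameters. `sim` drives the synthetic-cohort
#' generator; set `paths` instead to ingest real inputs (genotypes,
#' weights, phenotypes). A single global `seed` feeds every stochastic
#' stage.
#'
#' @param sim A [sim_config()] (synthetic mode) or `NULL`.
#' @param paths Named list of input paths (`genotypes`, `weights`,
#'   `phenotypes`) when not simulating.
#' @param qc A [qc_thresholds()].
#' @param irt An [irt_config()].
#' @param match_ratio,match_caliper Matching parameters
#'   (see [match_controls()]).
#' @param n_pcs PCs for ancestry standardisation.
#' @param seed Global seed.
#' @param out_dir Output directory (created if absent).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            qc = qc_thresholds(), irt = irt_config(),
                            match_ratio = 2L, match_caliper = NULL,
                            n_pcs = 4L, seed = 1L,
                            out_dir = tempfile("cvdprs_run_")) {
  if (is.null(sim) && is.null(paths))
    stop("either sim or paths must be supplied")
  structure(list(sim = sim, paths = paths, qc = qc, irt = irt,
                 match_ratio = match_ratio, match_caliper = match_caliper,
                 n_pcs = n_pcs, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with keys mirroring [pipeline_config()] /
#'   [sim_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  qc <- if (!is.null(y$qc)) do.call(qc_thresholds, y$qc) else qc_thresholds()
  irt <- if (!is.null(y$irt)) do.call(irt_config, y$irt) else irt_config()
  pipeline_config(sim = sim, paths = y$paths, qc = qc, irt = irt,
                  match_ratio = y$match_ratio %||% 2L,
                  match_caliper = y$match_caliper,
                  n_pcs = y$n_pcs %||% 4L,
                  seed = y$seed %||% 1L,
                  out_dir = y$out_dir %||% tempfile("cvdprs_run_"))
}

#' Run the full evaluation pipeline
#'
#' Sequences all stages: simulate (or ingest) genotypes, weights, and
#' phenotypes; variant QC; PRS alignment, scoring and ancestry
#' standardisation against a simulated external reference panel;
#' clinical-score categorisation; IRT integration; hierarchical case
#' selection and 2:1 propensity matching; and the headline evaluation.
#' Every stage's outputs, the effective configuration, and the seed are
#' written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The evaluation report list (invisibly written as
#'   `report.json`), with components `report` (an `evaluation_report`),
#'   `design` (the `matched_design`), `qc` (the `qc_report`),
#'   `assessment`, `cohort`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }

  # --- stage 1: inputs -----------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    gm <- simulate_genotypes(sim)
    weights <- simulate_weights(gm, seed = config$seed + 10L)
    cohort <- simulate_cohort(sim, gm, weights)
    # external reference panel: fresh subjects drawn at the study panel's
    # allele frequencies, sharing its variant metadata
    set.seed(config$seed + 20L)
    n_ref <- max(500L, min(2000L, sim$n_subjects))
    ref_dos <- matrix(rbinom(n_ref * ncol(gm$dosages), 2L,
                             rep(gm$variants$af, each = n_ref)),
                      nrow = n_ref)
    gm_ref <- genotype_matrix(ref_dos, gm$variants)
    logf("simulated cohort: n=%d, m=%d", nrow(cohort), ncol(gm$dosages))
  } else {
    gm <- read_genotypes(config$paths$genotypes)
    weights <- read_weights(config$paths$weights)
    cohort <- read_participants(config$paths$phenotypes)
    gm_ref <- NULL
    logf("ingested cohort: n=%d, m=%d", nrow(cohort), ncol(gm$dosages))
  }

  # --- stage 2: variant QC -------------------------------------------
  qc <- apply_qc(gm, config$qc)
  gm_qc <- qc$genotypes
  logf("QC: %d -> %d variants", qc$report$n_input, qc$report$n_surviving)

  # --- stage 3: PRS scoring + standardisation ------------------------
  aln <- align_weights(gm_qc, weights)
  raw <- score_prs(gm_qc, weights, alignment = aln)$raw
  if (!is.null(gm_ref)) {
    keep <- match(gm_qc$variants$id, gm$variants$id)
    gm_ref_qc <- genotype_matrix(gm_ref$dosages[, keep, drop = FALSE],
                                 gm_ref$variants[keep, , drop = FALSE])
    pca <- genotype_pcs(gm_ref_qc, K = config$n_pcs)
    ref_raw <- score_prs(gm_ref_qc, weights,
                         alignment = align_weights(gm_ref_qc, weights))$raw
    model <- fit_ancestry_model(ref_raw, pca$scores, K = config$n_pcs)
    std <- standardize_prs(raw, project_pcs(pca, gm_qc), model)
  } else {
    model <- fit_ancestry_model(raw, K = 0L)
    std <- standardize_prs(raw, model = model)
  }
  logf("PRS: %d variants aligned (%d flipped, %d ambiguous)",
       aln$n_matched, aln$n_flipped, aln$n_ambiguous)

  # --- stage 4: clinical score + IRT ---------------------------------
  cohort$qrisk2 <- qrisk2_passthrough(cohort, allow_surrogate = TRUE)
  assessment <- assess_risk(cohort, std$prs_z, config$irt)

  # --- stage 5: case selection + matching ----------------------------
  cases <- select_cases(cohort)
  pool <- cohort[cohort$event == 0, , drop = FALSE]
  ps <- fit_propensity(cohort)
  design <- match_controls(cases, pool,
                           ps_cases = ps[cohort$event == 1],
                           ps_pool = ps[cohort$event == 0],
                           ratio = config$match_ratio,
                           caliper = config$match_caliper,
                           seed = config$seed)
  logf("matched %d controls to %d cases (ratio %.2f)",
       length(design$control_ids), length(design$case_ids),
       design$achieved_ratio)

  # --- stage 6: evaluation -------------------------------------------
  case_assess <- assessment[assessment$id %in% cases$id, , drop = FALSE]
  ctrl_assess <- assessment[assessment$id %in% design$control_ids, ,
                            drop = FALSE]
  report <- evaluate_uplift(case_assess, ctrl_assess)
  enrich <- percentile_enrichment(
    std$prs_z[cohort$id %in% cases$id],
    std$prs_z[cohort$id %in% design$control_ids])

  # --- persist --------------------------------------------------------
  write_participants(cohort, file.path(config$out_dir, "cohort.csv"))
  utils::write.table(design$smd_table,
                     file.path(config$out_dir, "smd_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(design$matches, file.path(config$out_dir, "matches.csv"),
            row.names = FALSE)
  write.csv(assessment, file.path(config$out_dir, "assessment.csv"),
            row.names = FALSE)
  report_json <- list(
    seed = config$seed,
    version = .cvdprs_version(),
    qc = qc$report[c("n_input", "n_removed_call_rate", "n_removed_maf",
                     "n_removed_hwe", "n_surviving")],
    reclass = unclass(report$reclass),
    clinical_sensitivity = report$clinical,
    combined_sensitivity = report$combined,
    uplift = report$uplift,
    relative_increase = report$relative_increase,
    case_nri = report$case_nri,
    upclass_or = report$upclass_or,
    enrichment = enrich,
    achieved_ratio = design$achieved_ratio,
    max_smd_after = max(design$smd_table$smd_after, na.rm = TRUE))
  jsonlite::write_json(report_json, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(report = report, design = design, qc = qc$report,
                 assessment = assessment, cohort = cohort,
                 enrichment = enrich, prs = std, out_dir = config$out_dir))
}
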
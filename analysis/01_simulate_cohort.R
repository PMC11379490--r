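#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screening cohort the rest of the
# workflow analyses — genotype panel, PRS weight set, and a participant
# table with covariates, surrogate clinical risk scores and 10-year
# events whose log-odds carry a log(1.6)-per-SD polygenic effect.
# Cohort size 10,000 with an 8% ten-year event fraction keeps every
# downstream stage (propensity matching in particular) in the regime the
# nested case-control design assumes: many more controls than cases.

library(cvdprs)

seed <- 2026L
dir.create("scratch/analysis", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_subjects = 10000L, n_variants = 200L,
                  prs_beta = log(1.6), baseline_event_rate = 0.08,
                  seed = seed)
gm <- simulate_genotypes(cfg)
weights <- simulate_weights(gm, seed = seed + 1L)
cohort <- simulate_cohort(cfg, gm, weights)

write_genotypes(gm, "scratch/analysis/genotypes.tsv")
write_weights(weights, "scratch/analysis/weights.txt")
write_participants(cohort, "scratch/analysis/cohort.csv")
yaml::write_yaml(list(seed = seed, n_subjects = cfg$n_subjects,
                      n_variants = cfg$n_variants,
                      prs_beta = cfg$prs_beta,
                      baseline_event_rate = cfg$baseline_event_rate),
                 "scratch/analysis/config.yaml")

summary_tab <- data.frame(
  quantity = c("subjects", "variants", "mean_age", "male_pct", "white_pct",
               "current_smoker_pct", "statin_pct", "mean_qrisk2",
               "sd_qrisk2", "event_pct"),
  value = round(c(nrow(cohort), ncol(gm$dosages), mean(cohort$age),
                  100 * mean(cohort$sex == "male"),
                  100 * mean(cohort$ethnicity == "white"),
                  100 * mean(cohort$smoking == "current"),
                  100 * mean(cohort$statin), mean(cohort$qrisk2),
                  sd(cohort$qrisk2), 100 * mean(cohort$event)), 2))
write.csv(summary_tab, "results/01_cohort_summary.csv", row.names = FALSE)

cat("Simulated", nrow(cohort), "subjects x", ncol(gm$dosages), "variants\n")
cat(sprintf("Mean surrogate QRISK2 %.1f%% (SD %.1f); event fraction %.1f%%\n",
            mean(cohort$qrisk2), sd(cohort$qrisk2),
            100 * mean(cohort$event)))
cat("Wrote scratch/analysis/{genotypes.tsv,weights.txt,cohort.csv}",
    "and results/01_cohort_summary.csv\n")
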
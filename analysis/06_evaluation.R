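#!/usr/bin/env Rscript
# Stage 6: the headline question — does adding the PRS to the clinical
# score identify more of the future cases as high risk? Paired sensitivity
# comparison (union rule vs clinical alone, Wald inference on the
# discordant counts), case-NRI, up-classification odds ratio vs matched
# controls, and enrichment of cases in the upper PRS percentiles.

library(cvdprs)
stopifnot(file.exists("scratch/analysis/assessment.csv"),
          file.exists("scratch/analysis/matches.csv"))

cohort <- read_participants("scratch/analysis/cohort.csv")
assessment <- read.csv("scratch/analysis/assessment.csv")
scores <- read.csv("scratch/analysis/prs_scores.csv")
matches <- read.csv("scratch/analysis/matches.csv")

case_ids <- cohort$id[cohort$event == 1]
ctrl_ids <- matches$control_id
case_assess <- assessment[assessment$id %in% case_ids, ]
ctrl_assess <- assessment[assessment$id %in% ctrl_ids, ]

report <- evaluate_uplift(case_assess, ctrl_assess)
print(report)

enrich <- percentile_enrichment(scores$prs_z[scores$id %in% case_ids],
                                scores$prs_z[scores$id %in% ctrl_ids])
cat("\nEnrichment of cases above reference PRS percentiles:\n")
print(enrich, digits = 3)

# age 40-54 subset: clinical scores are weakest where age contributes least
young <- case_assess[case_assess$id %in%
                       cohort$id[cohort$age < 55 & cohort$event == 1], ]
rep_young <- evaluate_uplift(young)
cat(sprintf("\nAges 40-54 (%d cases): clinical %.1f%% -> combined %.1f%%\n",
            rep_young$reclass$n, rep_young$clinical$estimate,
            rep_young$combined$estimate))

out <- list(all = list(reclass = unclass(report$reclass),
                       clinical = report$clinical,
                       combined = report$combined,
                       uplift = report$uplift,
                       relative_increase = report$relative_increase,
                       case_nri = report$case_nri,
                       upclass_or = report$upclass_or),
            age40_54 = list(reclass = unclass(rep_young$reclass),
                            clinical = rep_young$clinical,
                            combined = rep_young$combined),
            enrichment = enrich)
jsonlite::write_json(out, "results/06_evaluation.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
write.csv(enrich, "results/06_enrichment.csv", row.names = FALSE)
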
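#!/usr/bin/env Rscript
# Stage 3: score the polygenic risk score on the QC-passing variants and
# standardise it against an external reference panel via the PC-regression
# model (4 PCs), so the study scores land on the ~N(0,1) scale the
# integration step expects.

library(cvdprs)
stopifnot(file.exists("scratch/analysis/genotypes_qc.tsv"))

gm <- read_genotypes("scratch/analysis/genotypes_qc.tsv")
weights <- read_weights("scratch/analysis/weights.txt")
cohort <- read_participants("scratch/analysis/cohort.csv")

aln <- align_weights(gm, weights)
cat(sprintf("Aligned %d variants (%d flipped, %d strand-ambiguous excluded, %d unmatched weights)\n",
            aln$n_matched, aln$n_flipped, aln$n_ambiguous,
            length(aln$unmatched_weights)))
raw <- score_prs(gm, weights, alignment = aln)$raw

# reference panel: fresh genotypes at the panel's allele frequencies
set.seed(2028L)
n_ref <- 1500L
ref <- genotype_matrix(
  matrix(rbinom(n_ref * ncol(gm$dosages), 2L,
                rep(gm$variants$af, each = n_ref)), nrow = n_ref),
  gm$variants)
pca <- genotype_pcs(ref, K = 4)
model <- fit_ancestry_model(score_prs(ref, weights)$raw, pca$scores, K = 4)
std <- standardize_prs(raw, project_pcs(pca, gm), model)

cat(sprintf("Standardised PRS: mean %.3f, SD %.3f in the study cohort\n",
            mean(std$prs_z), sd(std$prs_z)))
z_case <- std$prs_z[cohort$event == 1]
z_non <- std$prs_z[cohort$event == 0]
cat(sprintf("Mean PRS: events %.3f vs event-free %.3f (shift %.2f SD)\n",
            mean(z_case), mean(z_non), mean(z_case) - mean(z_non)))

scores <- data.frame(id = cohort$id, raw = std$raw, prs_z = std$prs_z)
write.csv(scores, "scratch/analysis/prs_scores.csv", row.names = FALSE)
write.csv(data.frame(group = c("events", "event_free"),
                     mean_prs = round(c(mean(z_case), mean(z_non)), 3),
                     sd_prs = round(c(sd(z_case), sd(z_non)), 3)),
          "results/03_prs_by_outcome.csv", row.names = FALSE)
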
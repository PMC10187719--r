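#!/usr/bin/env Rscript
# Stage 2: clumping+thresholding PRS from the written interchange files.
#
# Clumping uses the standard parameters (p <= 0.1, r2 < 0.2, 250 kb windows,
# MAF >= 0.01); scores exclude the 2 MB APOE region on chr19, are adjusted for
# the first three principal components, standardized, and augmented into
# PRS.AD with the two APOE-tag SNPs. Quintile/decile bins are computed over
# the pooled analysis cohort.

library(famprs)

loaded <- read_cohort_dir("scratch/data")
cohort <- ascertain_families(loaded$cohort)
scored <- score_cohort(cohort, loaded$panel, loaded$stats)

rep <- attr(scored, "clump_report")
message(sprintf("clumping: %d retained, %d removed by LD, %d filtered by p, %d by MAF",
                sum(rep$status == "retained"), sum(rep$status == "removed_ld"),
                sum(rep$status == "filtered_p"), sum(rep$status == "filtered_maf")))
message(sprintf("PRS computed for %d individuals from %d SNPs",
                nrow(scored), attr(scored, "n_snps_used")))

out <- scored[, c("iid", "PRS_RAW", "PRS_ADJ", "PRS_STD", "PRS_AD", "PRS_AD_STD",
                  "QUINTILE", "DECILE", "PCTILE")]
names(out)[1] <- "IID"
write.table(out, "results/02_prs_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(rep, "results/02_clump_report.json", auto_unbox = TRUE)
saveRDS(scored, "scratch/scored_cohort.rds")  # staging for stages 3-5
message("wrote results/02_prs_scores.tsv and results/02_clump_report.json")
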
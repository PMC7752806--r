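#!/usr/bin/env Rscript
# Stage 3: score PCL-5, PHQ-8, AMBI and the concussion screen; derive
# PTSD/MDD/BI/mTBI group flags. Reads results/cohort.csv; writes
# results/scored_subjects.csv.

library(blinkcr)

cohort <- read_cohort("results/cohort.csv")
scored <- score_subjects(cohort)
write.csv(scored, "results/scored_subjects.csv", row.names = FALSE)

cat("Scored", nrow(scored), "subjects.\n")
cat(sprintf("PTSD+ (PCL-5 >= 33): %d   mTBI+: %d   BI (AMBI > 15.5): %d   MDD+ (PHQ-8 >= 10): %d\n",
            sum(scored$ptsd_positive), sum(scored$mtbi_positive),
            sum(scored$bi_positive), sum(scored$mdd_aggregate_positive)))
cat("\nGroup means (PCL-5 / PHQ-8 / AMBI):\n")
grp <- interaction(ifelse(scored$ptsd_positive, "PTSD+", "PTSD-"),
                   ifelse(scored$mtbi_positive, "mTBI+", "mTBI-"), sep = "/")
agg <- aggregate(cbind(pcl_total, phq_total, ambi_total) ~ grp,
                 data = cbind(scored, grp = grp), FUN = mean)
agg[, -1] <- round(agg[, -1], 2)
print(agg, row.names = FALSE)
cat("\nWrote results/scored_subjects.csv\n")
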
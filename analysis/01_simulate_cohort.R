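#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 54-veteran cohort and its conditioning
# schedules. Writes results/cohort.csv and two example schedules.

library(blinkcr)

seed <- 20260923L
dir.create("results", showWarnings = FALSE)

cohort <- sample_cohort(n = 54, seed = seed)
write_cohort(cohort, "results/cohort.csv")

cat("Cohort of", nrow(cohort), "subjects:\n")
print(table(cohort$group))
cat("\nLatent learning profiles (generator truth, not used by analysis):\n")
print(table(cohort$latent_profile, cohort$ptsd_group,
            dnn = c("profile", "PTSD+")))

s1 <- generate_schedule(1, seed = seed)
s2 <- generate_schedule(2, seed = seed + 1L)
write_schedule(s1, "results/example_schedule_week1.csv")
write_schedule(s2, "results/example_schedule_week2.csv")
cat(sprintf("\nWeek 1 schedule: %d trials (%d US-alone + %d acquisition), max same-type run %d\n",
            nrow(s1), sum(s1$kind == "US_ALONE"),
            sum(s1$phase == "acquisition"), max_run_length(s1)))
cat(sprintf("Week 2 schedule: %d trials, max same-type run %d\n",
            nrow(s2), max_run_length(s2)))
cat("\nWrote results/cohort.csv and example schedules.\n")
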
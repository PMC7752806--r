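#!/usr/bin/env Rscript
# Stage 4: the inferential models. Week 1 is a 2 x 2 x 6 (PTSD x mTBI x
# Training Block) mixed ANCOVA with age as covariate, Week 2 the matching
# 2 x 2 x 3 model; sphericity is checked with Mauchly's test and the
# Greenhouse-Geisser correction applied when it rejects. Post-hoc pooled
# t-tests compare PTSD groups within each mTBI stratum on Week-2 CR%,
# Bonferroni-corrected. Reads results/learning_series.csv and
# results/scored_subjects.csv; writes results/ancova_week1.csv,
# results/ancova_week2.csv and results/posthoc.csv.

library(blinkcr)

ser <- read.csv("results/learning_series.csv")
scored <- read.csv("results/scored_subjects.csv")
stopifnot(identical(ser$subject_id, scored$subject_id))
Y <- as.matrix(ser[, -1])
between <- data.frame(ptsd = scored$ptsd_positive,
                      mtbi = scored$mtbi_positive)

for (wk in 1:2) {
  cols <- if (wk == 1) 1:6 else 7:9
  res <- mixed_rm_ancova(Y[, cols], between, scored$age)
  mau <- attr(res, "mauchly")
  cat(sprintf("\n== Week %d (%d blocks) ==\n", wk, length(cols)))
  cat(sprintf("Mauchly: W = %.3f, chi-sq(%d) = %.2f, p = %.3f%s\n",
              mau$W, mau$df, mau$chi_sq, mau$p,
              if (attr(res, "gg_applied"))
                sprintf("; GG epsilon = %.2f applied", res$gg_epsilon[
                  res$stratum == "within"][1]) else "; sphericity retained"))
  print(cbind(res[, c("effect", "df_num", "df_den")],
              F = round(res$F, 2), p = round(res$p, 3),
              partial_eta_sq = round(res$partial_eta_sq, 2)),
        row.names = FALSE)
  write.csv(as.data.frame(res), sprintf("results/ancova_week%d.csv", wk),
            row.names = FALSE)
}

# post-hoc: PTSD effect on mean Week-2 CR% within mTBI strata
w2 <- rowMeans(Y[, 7:9])
rows <- list()
for (m in c(FALSE, TRUE)) {
  sel <- scored$mtbi_positive == m
  tt <- two_sample_t(w2[sel & scored$ptsd_positive],
                     w2[sel & !scored$ptsd_positive])
  rows[[length(rows) + 1L]] <- data.frame(
    stratum = if (m) "mTBI+" else "mTBI-",
    mean_diff = tt$mean_diff, t = tt$t, df = tt$df, p = tt$p)
}
post <- do.call(rbind, rows)
post$p_bonferroni <- bonferroni_adjust(post$p)
cat("\nPost-hoc Week-2 PTSD+ vs PTSD- by mTBI stratum (pooled t):\n")
print(cbind(post[, "stratum", drop = FALSE],
            round(post[, -1], 3)), row.names = FALSE)
write.csv(post, "results/posthoc.csv", row.names = FALSE)
cat("\nWrote results/ancova_week[12].csv and results/posthoc.csv\n")
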
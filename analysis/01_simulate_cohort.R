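#!/usr/bin/env Rscript
# Stage 1: simulate the virtual monitoring cohort.
#
# Generates 100 virtual adults receiving a 0.6 mg/kg rocuronium bolus under
# the published population PD parameters: T1/Tc sampled every 30 s, MEP
# amplitudes in four muscles at each 10% T1/Tc recovery increment plus a
# 2-min periodic schedule, amplitude-dependent proportional noise from the
# bi-exponential CV model, and a 1 uV recording floor. Writes the long-format
# data and exploratory summaries under results/cohort/.

suppressPackageStartupMessages(library(rocumep))
seed <- 2026
out <- "results/cohort"

cohort <- generate_cohort(n = 100, seed = seed)
write_cohort_csv(cohort, out)

es <- exploratory_summaries(cohort)
dir.create(file.path(out, "summaries"), showWarnings = FALSE, recursive = TRUE)
for (nm in names(es)) {
  utils::write.csv(es[[nm]], file.path(out, "summaries", paste0(nm, ".csv")),
                   row.names = FALSE)
}

cat("Simulated", nrow(cohort$subjects), "subjects,",
    nrow(cohort$records), "records (seed", seed, ")\n\n")

cat("Pooled amplitude skew (mean vs median, uV) by muscle:\n")
amp <- subset(cohort$records, endpoint != "t1tc")
for (m in c("Del", "APB", "TA", "AH")) {
  v <- amp$value[amp$endpoint == m]
  cat(sprintf("  %-3s mean %7.0f  median %6.0f  max/min ratio %6.0f\n",
              m, mean(v), median(v), max(v) / min(v)))
}
cat("\nAs in the monitored cohort, means exceed medians everywhere",
    "(right-skewed log-normal amplitudes) and amplitudes span ~3 orders",
    "of magnitude.\n\n")

cen <- shape_census(cohort)
cat("Individual mu-T1/Tc curve shapes across muscles:\n")
print(as.data.frame(tapply(cen$n, cen$shape, sum)))
cat("\nAll five qualitative shapes arise from between-subject variability",
    "in EC50 and Hill alone.\nWrote", out, "\n")
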
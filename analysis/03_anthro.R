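#!/usr/bin/env Rscript
# Stage 3: undernutrition classification and prevalence accounting per
# wave: means and SDs of the three Z-scores, prevalence of stunting /
# underweight / wasting / any failure (CIAF >= 1), and the excess
# prevalence after subtracting the 2.3% natural background.

library(malnut)

fx <- read_fixture(file.path("results", "fixture"))
records <- fx$records

rows <- list()
for (w in sort(unique(records$wave))) {
  s <- summarize_prevalence(records, w)
  mr <- missingness_report(records, w)
  cat(sprintf("\nWave %s (n = %d complete, %.1f%% missing):\n",
              w, s$n, mr$missing_pct))
  for (o in c("haz", "waz", "whz")) {
    cat(sprintf("  %s mean (SD): %.2f (%.2f)\n", toupper(o),
                s$mean[[o]], s$sd[[o]]))
  }
  for (cond in names(s$prevalence_pct)) {
    cat(sprintf("  %-12s %5.1f%%  (excess %5.1f%%)\n", cond,
                s$prevalence_pct[[cond]], s$excess_prevalence_pct[[cond]]))
  }
  rows[[w]] <- data.frame(
    wave = w, n = s$n, condition = names(s$prevalence_pct),
    prevalence_pct = unname(s$prevalence_pct),
    excess_prevalence_pct = unname(s$excess_prevalence_pct))
}
write.csv(do.call(rbind, rows), file.path("results", "prevalence.csv"),
          row.names = FALSE)
cat("\nWrote results/prevalence.csv\n")
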
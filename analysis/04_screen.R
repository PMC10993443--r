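#!/usr/bin/env Rscript
# Stage 4: bivariate screening on the baseline wave. Continuous
# determinants get Pearson or Spearman correlations (normality-driven
# choice) with the |r| >= 0.10 & p < 0.05 reportability rule;
# dichotomous determinants get folded-F-branched t-tests; categorical
# determinants get one-way GLM F-tests with variance explained; and the
# categorical pairs are probed for effect modification. No multiplicity
# correction is applied at this stage.

library(malnut)

full <- normalize_record_types(
  read.csv(file.path("results", "linked.csv"), stringsAsFactors = FALSE))
base <- full[full$wave == sort(unique(full$wave))[1L], ]
outcomes <- c("haz", "waz", "whz")

rows <- list()
for (o in outcomes) {
  for (v in c("mvhi", "altitude", "pop_density")) {
    r <- correlate(base[[o]], base[[v]], variable = v)
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = o, variable = v, test = paste0("corr_", r$method),
      statistic = r$r, p = r$p, reportable = r$reportable)
  }
  for (v in c("female", "hungry_season", "suppl_food", "noise_bin")) {
    t <- ttest_dichotomous(base[[o]], base[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = o, variable = v, test = paste0("ttest_", t$branch),
      statistic = t$diff_means, p = t$p, reportable = t$p < 0.05)
  }
  for (v in c("age_cat", "bmi_class", "wealth")) {
    a <- anova_categorical(base[[o]], base[[v]], variable = v)
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = o, variable = v, test = "glm_F",
      statistic = a$F, p = a$p, reportable = a$p < 0.05)
  }
}
tab <- do.call(rbind, rows)
tab <- tab[order(tab$outcome, tab$p), ]
write.csv(tab, file.path("results", "screen.csv"), row.names = FALSE)

for (o in outcomes) {
  hits <- tab[tab$outcome == o & tab$reportable, "variable"]
  cat(sprintf("%s: %d of %d screened determinants reportable (%s)\n",
              toupper(o), length(hits), sum(tab$outcome == o),
              paste(hits, collapse = ", ")))
}

# effect modification among the categorical determinants, baseline HAZ
im <- interaction_screen(base$haz, base$age_cat, base$bmi_class)
cat(sprintf("Age x maternal-BMI interaction on HAZ: p = %.3f (%s)\n",
            im$interaction_p,
            if (im$modifies) "modifies" else "no modification"))
cat("Wrote results/screen.csv\n")
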
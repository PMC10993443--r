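#!/usr/bin/env Rscript
# Stage 5: explanatory models of the three Z-scores on the baseline
# wave. Backwards p-value selection (levels leave independently) gives
# the main model; 100 resamples of a random 75% of the data, each
# re-selected from scratch, give per-effect selection frequencies and
# averaged estimates. Effects below 20% selection frequency are
# dropped; the main model is compared against the subsample average.

library(malnut)

SEED <- 1234
full <- normalize_record_types(
  read.csv(file.path("results", "linked.csv"), stringsAsFactors = FALSE))
base <- full[full$wave == sort(unique(full$wave))[1L], ]
vars <- c("female", "hungry_season", "suppl_food", "noise_bin",
          "age_cat", "bmi_class", "wealth")
X <- build_design(base, vars)
outcomes <- c("haz", "waz", "whz")

all_eff <- list()
for (o in outcomes) {
  main <- suppressWarnings(backward_select(base[[o]], X))
  st <- stability_select(base[[o]], X, n_resamples = 100, fraction = 0.75,
                         retain = 0.20, seed = SEED + match(o, outcomes))
  cmp <- compare_models(main, st)
  cat(sprintf("\n%s: adjusted R^2 = %.4f, %d effects selected, verdict %s\n",
              toupper(o), main$adj_r_square, length(main$selected),
              cmp$verdict))
  e <- st$effects
  e$outcome <- o
  e$in_main <- e$effect %in% main$selected
  print(e[e$retained | e$in_main,
          c("effect", "selection_frequency", "avg_estimate", "retained",
            "in_main")], row.names = FALSE)
  all_eff[[o]] <- e
}
write.csv(do.call(rbind, all_eff), file.path("results", "modelsel.csv"),
          row.names = FALSE)
cat("\nWrote results/modelsel.csv\n")
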
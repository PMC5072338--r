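#!/usr/bin/env Rscript

# Stage 5: stomatal model selection with and without a circadian oscillator.
#
# The full 12-model grid (Ball-Berry / Leuning / Medlyn, each with and
# without minimal conductance g0 and with and without the sinusoidal
# oscillator on the slope g1) is fitted to the leaf data under the three
# calibration/validation splits: entire set -> entire set, changing ->
# constant, constant -> changing. Models are fitted per species; validation
# pools species; AIC, delta-AIC and Akaike weights rank the grid.
#
# Usage: Rscript analysis/05_fit_stomatal_models.R   (after 01_simulate.R)

suppressMessages(library(circaflux))

env <- read.csv("results/data/env.csv")
leaf <- read.csv("results/data/leaf.csv")
w <- env_windows(env)
leaf <- leaf[leaf$t_h >= w$entrain[1], ]  # final entrainment day + constant
d <- merge_leaf_env(leaf, env)

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
reports <- list()
for (s in c("all", "cha_con", "con_cha")) {
  rep <- run_scheme(s, d)
  reports[[s]] <- rep$table
  best <- rep$table[1, ]
  message(sprintf(
    "%-8s best: %-11s (weight %.3f, dAIC runner-up %.1f, validation R2 %.3f)",
    rep$scheme$label, best$model, best$weight, rep$table$delta_aic[2],
    best$r2_validation))
  r2_osc <- max(rep$table$r2_validation[rep$table$oscillator])
  r2_no <- max(rep$table$r2_validation[!rep$table$oscillator])
  message(sprintf("         validation R2: %.3f with oscillator vs %.3f without",
                  r2_osc, r2_no))
}
jsonlite::write_json(reports, "results/models/report.json",
                     dataframe = "rows", digits = NA, pretty = TRUE)
message("wrote: results/models/report.json")
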
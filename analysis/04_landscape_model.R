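#!/usr/bin/env Rscript
# Stage 4 — landscape-stressor random forest.
#
# Site-level model of mean mussel density against the 13 landscape variables
# (subcatchment and 200-m riparian-buffer scales). With the study's six sites
# the ranking is illustrative only (13 predictors cannot be ranked from six
# rows); the generator's effect structure is therefore also demonstrated at
# a larger synthetic site count, where the four urbanization stressors
# (D_RuralSet, D_Street, P_RuralSet, D_Road) recover as the top block.

suppressMessages(library(musselhab))

land_pred <- c("R_Area", "N_Forest", "N_Agriculture", "N_Pasture",
               "N_RuralSet", "Can_Cover", "P_Forest", "P_Agriculture",
               "P_Pasture", "D_RuralSet", "D_Street", "P_RuralSet", "D_Road")

landscape <- read.csv("results/landscape.csv", stringsAsFactors = FALSE)
for (sp in c("castalia", "anodontites")) {
  landscape$response <- transform_density(landscape[[paste0("dens_", sp)]])
  f <- grow_forest(landscape, "response", land_pred, mtry = 3, ntree = 300,
                   seed = 1)
  cat(sprintf("%s (6 sites): oob MSE %.4f, pseudo-R2 %.1f%%\n",
              sp, f$oob_mse, 100 * f$pseudo_r2))
}

cat("\nlarger synthetic site set (n = 60, strong urbanization effect):\n")
ls <- simulate_landscape(nsites = 60, effect = 2, seed = 1)
L <- ls$landscape
L$response <- transform_density(20 * ls$multiplier)
imp <- importance_reseeded(L, "response", land_pred, mtry = 4, ntree = 300,
                           seed = 1, reseeds = 5)
print(imp[, c("predictor", "pct_inc_mse", "rank")], row.names = FALSE)
write.csv(imp, "results/importance_landscape_synthetic.csv", row.names = FALSE)
cat("-> urbanization-buffer stressors dominate; agriculture and pasture are\n",
    "   generated with no effect and rank accordingly.\n")
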
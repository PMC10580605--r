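#!/usr/bin/env Rscript
# Fit and compare the four lodging-score predictors (stepwise MLR, the
# 3-9-8 sigmoid network, RBF epsilon-SVR, 100-tree random forest) on the
# study table with one shared 75/25 split, and export the metric grid
# plus per-model observed/predicted scatter data.
suppressPackageStartupMessages(library(lodgescore))

traits <- read.csv("results/study/traits.csv")
cmp <- compare_models(
  traits,
  list(mlr = mlr_config(), ann = ann_config(seed = 1),
       svr = svr_config(), rf = rf_config(seed = 1)),
  train_fraction = 0.75, split_seed = 1)
export_comparison(cmp, "results/study")

cat(sprintf("split: %d training / %d testing\n",
            cmp$split_sizes["train"], cmp$split_sizes["test"]))
print(cmp$grid[, c("model", "split", "r2", "rmse", "nrmse_range", "mae",
                   "coverage25", "rank")], digits = 3)

g <- cmp$grid
cat(sprintf("\nRF training R2 %.3f vs MLR training R2 %.3f\n",
            g$r2[g$model == "rf" & g$split == "training"],
            g$r2[g$model == "mlr" & g$split == "training"]))
cat(sprintf("RF testing RMSE %.3f vs SVR testing RMSE %.3f\n",
            g$rmse[g$model == "rf" & g$split == "testing"],
            g$rmse[g$model == "svr" & g$split == "testing"]))
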
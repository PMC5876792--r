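#!/usr/bin/env Rscript
# Class separability (average univariate-Gaussian Bhattacharyya distance per
# class pair) in the subspace of the three strongest vs the three weakest
# discriminant contributors, on the per-particle table from 02_pipeline.R.

library(scatterid)

pt <- read_feature_table("results/run/features_particle.csv")
model <- read_lda_model("results/run/lda_model.json")
cw <- contribution_weights(model)

top3 <- head(cw$feature, 3)
bottom3 <- tail(cw$feature, 3)
sep_top <- separability_report(pt, features = top3)
sep_bottom <- separability_report(pt, features = bottom3)

cat("top-3 features:   ", paste(top3, collapse = ", "), "\n")
print(round(sep_top$distances, 3))
cat(sprintf("mean: %.3f\n\n", sep_top$mean))
cat("bottom-3 features:", paste(bottom3, collapse = ", "), "\n")
print(round(sep_bottom$distances, 3))
cat(sprintf("mean: %.3f\n", sep_bottom$mean))

out <- rbind(
  data.frame(subset = "top3", pair = names(sep_top$distances),
             distance = unname(sep_top$distances)),
  data.frame(subset = "bottom3", pair = names(sep_bottom$distances),
             distance = unname(sep_bottom$distances)))
write.csv(out, "results/bhattacharyya.csv", row.names = FALSE)
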
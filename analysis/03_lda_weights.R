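#!/usr/bin/env Rscript
# Contribution weights of the 43 retained features in the single
# discriminant (reads the model written by 02_pipeline.R).

library(scatterid)

model <- read_lda_model("results/run/lda_model.json")
cw <- contribution_weights(model)
write.csv(cw, "results/lda_weights_ranked.csv", row.names = FALSE)

cat("top 10 contributors (squared weights sum to 1):\n")
print(head(cw, 10), digits = 3)

grp <- function(p) sum(cw$weight[grepl(p, cw$feature)])
cat(sprintf("\nsquared-weight mass by family:\n"))
cat(sprintf("  time-domain stats      %.3f\n",
            sum(cw$weight[cw$feature %in%
                            c("M", "SD", "Skew", "Kurt", "IQR", "E")])))
cat(sprintf("  Nakagami               %.3f\n", grp("nakagami")))
cat(sprintf("  DCT-derived            %.3f\n", grp("DCT")))
cat(sprintf("  wavelet relative power %.3f\n", grp("^E_(Haar|Db10)")))
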
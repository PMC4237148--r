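#!/usr/bin/env Rscript
# Differentiation layers and ecotype contrasts: pairwise Weir-Cockerham FST
# and mean allelic differences on the neutral and positive-outlier locus
# sets, the between/within-ecotype FST ratio sets compared by Mann-Whitney,
# and the Yates-corrected 2x2 contrasts of allelic-difference magnitudes.
# Requires results/classification.tsv from 02_outlier_scan.R.

library(ecoscan)

gm <- read_vcf("results/data/genotypes.vcf")
popmap <- read_popmap("results/data/popmap.tsv", gm)
gm <- suppressWarnings(filter_snps(gm))
cls <- read.table("results/classification.tsv", sep = "\t", header = TRUE)

neutral <- cls$locus[cls$label == "neutral"]
outlier <- cls$locus[cls$label == "positive"]

fst_n <- pairwise_fst(gm, popmap, neutral, "neutral")
fst_o <- pairwise_fst(gm, popmap, outlier, "outlier")
diff_n <- allelic_difference_matrix(gm, popmap, neutral, "neutral")
diff_o <- allelic_difference_matrix(gm, popmap, outlier, "outlier")

write_layer <- function(layer, name) {
  write.table(data.frame(pop = rownames(layer$values), layer$values,
                         check.names = FALSE),
              file.path("results", name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}
write_layer(fst_n, "fst_neutral.tsv")
write_layer(fst_o, "fst_outlier.tsv")
write_layer(diff_n, "diff_neutral.tsv")
write_layer(diff_o, "diff_outlier.tsv")

rn <- ratio_set(fst_n, popmap, "ecotype1", "ecotype2")
ro <- ratio_set(fst_o, popmap, "ecotype1", "ecotype2")
mw <- mann_whitney(rn$ratios, ro$ratios)
cat("between/within-ecotype FST ratios:\n")
cat(sprintf("  neutral: mean %.2f (range %.2f-%.2f, N = %d)\n",
            rn$mean, rn$min, rn$max, rn$n))
cat(sprintf("  outlier: mean %.2f (range %.2f-%.2f, N = %d)\n",
            ro$mean, ro$min, ro$max, ro$n))
cat(sprintf("  Mann-Whitney U = %g, Z = %.2f, p = %.4g\n", mw$U, mw$z, mw$p))

x2 <- chi2_contrast(diff_n, diff_o, popmap, "ecotype1", "ecotype2")
cat(sprintf("allelic differences between vs within ecotypes: %.1f-fold (outlier) vs %.1f-fold (neutral), Yates chi2 = %.2f, p = %.4g\n",
            x2$fold_ratios["outlier"], x2$fold_ratios["neutral"],
            x2$statistic, x2$p_value))
og <- outgroup_contrast(diff_n, diff_o, popmap, "ecotype1", "ecotype2",
                        "ecotype3")
cat(sprintf("ecotypes vs outgroup contrast: Yates chi2 = %.2f, p = %.4g\n",
            og$statistic, og$p_value))

stats <- data.frame(
  quantity = c("neutral_ratio_mean", "neutral_ratio_min", "neutral_ratio_max",
               "outlier_ratio_mean", "outlier_ratio_min", "outlier_ratio_max",
               "mann_whitney_U", "mann_whitney_Z", "mann_whitney_p",
               "chi2_between_within", "chi2_between_within_p",
               "chi2_outgroup", "chi2_outgroup_p"),
  value = c(rn$mean, rn$min, rn$max, ro$mean, ro$min, ro$max,
            mw$U, mw$z, mw$p, x2$statistic, x2$p_value,
            og$statistic, og$p_value))
write.table(stats, "results/contrast.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
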
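#!/usr/bin/env Rscript
# Reciprocal fixed differences per population pair, on the neutral and
# positive-outlier locus sets, each count tested against the panmictic
# Poisson-binomial sampling null (starred when P(X >= observed) <= 0.05).
# Requires results/classification.tsv from 02_outlier_scan.R.

library(ecoscan)

gm <- read_vcf("results/data/genotypes.vcf")
popmap <- read_popmap("results/data/popmap.tsv", gm)
gm <- suppressWarnings(filter_snps(gm))
cls <- read.table("results/classification.tsv", sep = "\t", header = TRUE)

for (set in c("neutral", "positive")) {
  ids <- cls$locus[cls$label == set]
  label <- if (set == "positive") "outlier" else "neutral"
  layer <- fixed_diff_matrix(gm, popmap, ids, label)
  starred <- matrix(paste0(layer$values,
                           ifelse(layer$significant, "*", "")),
                    nrow(layer$values), dimnames = dimnames(layer$values))
  write.table(data.frame(pop = rownames(starred), starred,
                         check.names = FALSE),
              sprintf("results/fixed_diff_%s.tsv", label),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tot <- sum(layer$values[upper.tri(layer$values)])
  cat(sprintf("%s loci: %d pairwise fixed differences in total, %d pair(s) significant\n",
              label, tot, sum(layer$significant[upper.tri(layer$significant)])))
}

# worked per-pair report between the two planted-fixation ecotypes
p1 <- unique(popmap$population[popmap$ecotype == "ecotype1"])[1]
p2 <- unique(popmap$population[popmap$ecotype == "ecotype2"])[1]
print(test_fixed_pair(gm, popmap, p1, p2))
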
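#!/usr/bin/env Rscript
# Functional-term enrichment: link SNPs to genes within 5 kb, test term
# overrepresentation of the candidate genes (best-supported positive
# outliers plus fixed-difference loci) against the all-SNP background with
# two-tailed Fisher tests and BH correction, and run the matched
# random-neutral-list negative control. Requires results/ from the
# preceding scripts.

library(ecoscan)

gm <- read_vcf("results/data/genotypes.vcf")
popmap <- read_popmap("results/data/popmap.tsv", gm)
gm <- suppressWarnings(filter_snps(gm))
cls <- read.table("results/classification.tsv", sep = "\t", header = TRUE)
ann <- read_annotation("results/data/genes.tsv", "results/data/gene_terms.tsv")

links <- link_snps_to_genes(gm, ann, window = 5000)

candidate_ids <- cls$locus[cls$label == "positive" & cls$best_supported]
pops <- unique(popmap$population)
for (i in seq_along(pops)) for (j in seq_along(pops)) {
  if (i < j) candidate_ids <- union(candidate_ids,
                                    find_fixed(gm, popmap, pops[i], pops[j]))
}
candidate_genes <- unique(unlist(links[candidate_ids]))
background_genes <- unique(unlist(links))
cat(sprintf("%d candidate loci -> %d genes (background %d genes)\n",
            length(candidate_ids), length(candidate_genes),
            length(background_genes)))

res <- fisher_enrichment(candidate_genes, background_genes, ann)
write.table(as.data.frame(res), "results/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- res[res$p_adjusted <= 0.05, ]
cat(sprintf("%d term(s) enriched at adjusted p <= 0.05:\n", nrow(sig)))
print(sig)

neutral_pool <- setdiff(unique(unlist(links[cls$locus[cls$label == "neutral"]])),
                        candidate_genes)
ctrl <- control_enrichment(neutral_pool, length(candidate_genes),
                           background_genes, ann, n_lists = 10, seed = 202)
cat(sprintf("negative control: %d of %d random neutral lists show any enriched term\n",
            ctrl$n_significant_lists, ctrl$n_lists))
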
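#!/usr/bin/env Rscript
# Phenotypic sampling homogeneity across trio subcohorts: compare the four
# Multinomial / Dirichlet-Multinomial allocation models by AIC on per-gene
# LoF de novo counts, with subcohort synonymous counts as sampling weights.

suppressPackageStartupMessages(library(cesscan))

sites <- read_site_table("results/expectation_sites.tsv")
denovo <- read_denovo_table("results/data/denovo.tsv")

syn <- sites[sites$class == "synonymous", ]
weights <- table(denovo$subcohort[paste(denovo$chrom, denovo$pos, denovo$ref,
                                        denovo$alt) %in%
                                    paste(syn$chrom, syn$pos, syn$ref,
                                          syn$alt)])
cat("per-subcohort synonymous counts (weights):\n"); print(weights)

lofs <- sites[sites$class == "LoF", ]
key <- paste(lofs$chrom, lofs$pos, lofs$ref, lofs$alt)
dn <- denovo[paste(denovo$chrom, denovo$pos, denovo$ref, denovo$alt) %in% key, ]
dn$gene_id <- lofs$gene_id[match(paste(dn$chrom, dn$pos, dn$ref, dn$alt), key)]
counts <- table(factor(dn$gene_id), factor(dn$subcohort, levels = names(weights)))

cmp <- compare_homogeneity(unclass(counts), as.numeric(weights))
print(cmp)
write_tsv(cmp$table, "results/homogeneity.tsv")
cat(if (cmp$best_model == "m1") {
  "sampling is consistent with uniform subcohort recruitment\n"
} else sprintf("non-uniform sampling signal: AIC prefers %s\n", cmp$best_model))
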
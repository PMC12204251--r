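#!/usr/bin/env Rscript
# Gene filtering and synonymous-normalised mutational expectations: keep the
# maximal non-overlapping gene set, classify sites, anchor expectations on
# the observed synonymous de novo count, and write per-site and per-gene
# expectation tables.

suppressPackageStartupMessages(library(cesscan))

sites <- read_site_table("results/data/sites.tsv")
genes <- read_gene_bed("results/data/genes.bed")
denovo <- read_denovo_table("results/data/denovo.tsv")

sel <- select_nonoverlapping_genes(genes)
retained <- attr(sel, "retained")
cat(sprintf("gene selection: %d retained, %d dropped for CDS overlap\n",
            length(retained), length(attr(sel, "dropped"))))

sites <- sites[sites$gene_id %in% retained, ]
sites$class <- as.character(classify_variants(sites))
cat("site classes:\n"); print(table(sites$class))

syn <- sites[sites$class == "synonymous", ]
ns_observed <- sum(count_denovo(syn, denovo))
cat(sprintf("observed synonymous de novo count NS = %d\n", ns_observed))

expectation <- compute_expectations(sites, ns_observed)
write_tsv(expectation$sites, "results/expectation_sites.tsv")
write_tsv(expectation$genes, "results/expectation_genes.tsv")
cat(sprintf("wrote expectations for %d sites in %d gene-class groups\n",
            nrow(expectation$sites), nrow(expectation$genes)))
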
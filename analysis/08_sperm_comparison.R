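#!/usr/bin/env Rscript
# Trio-vs-sperm comparison: gene-level binomial split of combined LoF
# counts between the (ascertained) trio cohort and (unascertained)
# sperm-sequencing counts. Trio excess beyond the expected split indicates
# disease ascertainment; sperm excess is consistent with embryonic
# deleteriousness of the trio-depleted variants.

suppressPackageStartupMessages(library(cesscan))

sites <- read_site_table("results/expectation_sites.tsv")
denovo <- read_denovo_table("results/data/denovo.tsv")
sperm <- data.table::fread("results/data/sperm.tsv", data.table = FALSE)

lofs <- sites[sites$class == "LoF", ]
nl <- count_denovo(lofs, denovo)
ng <- tapply(nl, lofs$gene_id, sum)
lg <- tapply(lofs$lambda, lofs$gene_id, sum)

idx <- match(names(ng), sperm$gene_id)
cmp <- compare_cohorts(as.integer(ng), sperm$m_sperm[idx],
                       as.numeric(lg), sperm$lambda_sperm[idx],
                       unit = names(ng))
write_tsv(cmp, "results/sperm_comparison.tsv")
cat(sprintf("%d genes tested (>= 1 LoF event in both datasets)\n",
            sum(cmp$tested)))
cat("trio-excess genes (ascertainment-driven):",
    paste(cmp$unit[cmp$sig_trio_excess], collapse = ", "), "\n")
cat("sperm-excess genes (possible embryonic deleteriousness):",
    paste(cmp$unit[cmp$sig_sperm_excess], collapse = ", "), "\n")
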
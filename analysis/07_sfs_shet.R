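#!/usr/bin/env Rscript
# SFS-based selection estimation: fit the neutral multinomial SFS on
# synonymous-like sites, fit per-bin selection coefficients on LoF sites
# with the sqrt(shet) covariate, then re-estimate shet per gene. CES genes
# (rate inflated beyond the model's covariate) should be dragged toward
# lower shet than their priors.

suppressPackageStartupMessages(library(cesscan))

set.seed(20260929L)
n_bins <- length(sfs_bin_boundaries()) - 1L
beta_mu <- 0.05 * exp(-0.25 * (0:(n_bins - 2)))
beta_s <- 4 + 0.05 * seq_len(n_bins - 1)

# neutral sites: broad rate range, no selection
mu_neu <- runif(4e4, 1, 30)
neu_sites <- gen_sfs_sites(mu_neu, beta_mu)
neutral <- fit_neutral_sfs(neu_sites$k, neu_sites$mu)
print(neutral)

# LoF training sites across genes with known prior shet
n_genes <- 400L
shet_prior <- runif(n_genes, 0.01, 0.6)
gene <- rep(seq_len(n_genes), each = 50)
mu_lof <- runif(length(gene), 1, 30)
lof_sites <- gen_sfs_sites(mu_lof, beta_mu, beta_s, shet = shet_prior[gene])
selection <- fit_selection_sfs(lof_sites$k, lof_sites$mu, shet_prior[gene],
                               neutral)
print(selection)
write_tsv(data.frame(bin = seq_len(n_bins - 1), beta_mu = neutral$beta_mu,
                     beta_s = selection$beta_s),
          "results/sfs_coefficients.tsv")

# per-gene re-estimation: 30 ordinary genes at shet = 0.2 and 10 CES-like
# genes with the same shet but a hidden 17x rate inflation
genes <- data.frame(gene_id = sprintf("S%03d", 1:40),
                    kappa = rep(c(1, 17), c(30, 10)), true_shet = 0.2)
per_gene <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
  mu <- runif(50, 15, 40)
  d <- gen_sfs_sites(mu, beta_mu, beta_s, shet = genes$true_shet[i],
                     kappa = genes$kappa[i])
  e <- estimate_gene_shet(d$k, d$mu, neutral, selection)
  data.frame(gene_id = genes$gene_id[i], kappa = genes$kappa[i],
             true_shet = genes$true_shet[i], shet_hat = e$shet)
}))
write_tsv(per_gene, "results/shet_estimates.tsv")
cat(sprintf("mean shet-hat: %.3f (kappa = 1) vs %.3f (kappa = 17)\n",
            mean(per_gene$shet_hat[per_gene$kappa == 1]),
            mean(per_gene$shet_hat[per_gene$kappa == 17])))
cat("rate-inflated genes are pulled below their true selection strength,\n")
cat("the signature used to corroborate CES candidates\n")
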
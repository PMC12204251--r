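test_that("generators are seed-deterministic and schema-stable", {
  cfg <- synthetic_config(seed = 7, n_genes = 20)
  a <- gen_sites(cfg)
  b <- gen_sites(cfg)
  expect_identical(a, b)

  e <- compute_expectations(
    transform(a$sites, class = as.character(classify_variants(a$sites))),
    ns_count = 500
  )
  d1 <- gen_denovo_cohort(cfg, e)
  d2 <- gen_denovo_cohort(cfg, e)
  expect_identical(d1, d2)
  expect_identical(gen_population_afs(cfg), gen_population_afs(cfg))
  expect_identical(gen_sperm_counts(cfg, e), gen_sperm_counts(cfg, e))

  # different seeds diverge
  cfg2 <- synthetic_config(seed = 8, n_genes = 20)
  expect_false(identical(gen_sites(cfg2), a))
})

test_that("zero genes yield empty but valid tables", {
  cfg <- synthetic_config(seed = 1, n_genes = 0)
  out <- gen_sites(cfg)
  expect_equal(nrow(out$sites), 0L)
  expect_equal(nrow(out$genes), 0L)
  expect_true(all(c("gene_id", "mu", "qual") %in% names(out$sites)))
})

test_that("the CpG-like high-rate fraction matches its target", {
  cfg <- synthetic_config(seed = 3, n_genes = 80, cpg_fraction = 0.2)
  s <- gen_sites(cfg)$sites
  n <- nrow(s)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(s$cpg) - 0.2), 3 * se)
  # the high-rate component indeed sits above 1 almost always
  expect_gt(mean(s$mu[s$cpg] > 1), 0.99)
})

test_that("config validation enforces the model's own constraints", {
  expect_error(synthetic_config(kappa = 0.5), ">= 1")
  expect_error(synthetic_config(ascertainment_fold = 150, prevalence = 0.01),
               "1/prevalence")
  expect_error(synthetic_config(prevalence = 0), "\\(0, 1\\]")
  expect_error(synthetic_config(gamma = -1), ">= 0")
})

test_that("de novo counts are Poisson-calibrated when kappa and ascertainment are 1", {
  cfg <- synthetic_config(seed = 11, n_genes = 500,
                          sites_per_gene = c(LoF = 5, synonymous = 10,
                                             missense = 5),
                          ns_count = 5000)
  st <- gen_sites(cfg)
  st$sites$class <- as.character(classify_variants(st$sites))
  e <- compute_expectations(st$sites, cfg$ns_count)
  dn <- gen_denovo_cohort(cfg, e)
  lofs <- e$sites[e$sites$class == "LoF", ]
  nv <- count_denovo(lofs, dn)
  ng <- tapply(nv, lofs$gene_id, sum)
  lg <- tapply(lofs$lambda, lofs$gene_id, sum)
  chi <- gene_level_chi2(as.integer(ng), as.numeric(lg))
  expect_gt(chi$p_value, 0.001)

  # overall calibration of totals
  expect_lt(abs(sum(nv) - sum(lg)) / sum(lg), 0.1)
})

test_that("kappa inflation is realised in observed/expected folds", {
  n_genes <- 60
  kap <- rep(1, n_genes); kap[1:10] <- 17
  cfg <- synthetic_config(seed = 12, n_genes = n_genes, kappa = kap,
                          sites_per_gene = c(LoF = 40, synonymous = 40,
                                             missense = 5),
                          ns_count = 20000)
  st <- gen_sites(cfg)
  st$sites$class <- as.character(classify_variants(st$sites))
  e <- compute_expectations(st$sites, cfg$ns_count)
  dn <- gen_denovo_cohort(cfg, e)
  lofs <- e$sites[e$sites$class == "LoF", ]
  nv <- count_denovo(lofs, dn)
  ng <- tapply(nv, lofs$gene_id, sum)
  lg <- tapply(lofs$lambda, lofs$gene_id, sum)
  fold_hot <- sum(ng[1:10]) / sum(lg[1:10])
  fold_null <- sum(ng[11:60]) / sum(lg[11:60])
  expect_lt(abs(fold_hot - 17) / 17, 0.15)
  expect_lt(abs(fold_null - 1), 0.15)
})

test_that("Dirichlet subcohort allocation is detected by the homogeneity models", {
  n_genes <- 300
  cfg <- synthetic_config(seed = 13, n_genes = n_genes,
                          sites_per_gene = c(LoF = 20, synonymous = 20,
                                             missense = 5),
                          ns_count = 30000,
                          subcohort_concentration = 2)
  st <- gen_sites(cfg)
  st$sites$class <- as.character(classify_variants(st$sites))
  e <- compute_expectations(st$sites, cfg$ns_count)
  dn <- gen_denovo_cohort(cfg, e)
  lofs <- e$sites[e$sites$class == "LoF", ]
  key <- paste(lofs$chrom, lofs$pos, lofs$ref, lofs$alt, sep = ":")
  dn$key <- paste(dn$chrom, dn$pos, dn$ref, dn$alt, sep = ":")
  dn <- dn[dn$key %in% key, ]
  counts <- table(factor(dn$gene_id),
                  factor(dn$subcohort, levels = names(cfg$subcohort_weights)))
  cmp <- compare_homogeneity(unclass(counts), cfg$subcohort_weights)
  expect_true(cmp$best_model %in% c("m3", "m4"))
})

test_that("population allele counts match the Gamma-Poisson moments", {
  cfg <- synthetic_config(seed = 14, n_genes = 50,
                          popgen = list(sites_per_gene = 200))
  afs <- gen_population_afs(cfg)
  pg <- cfg$popgen
  mu_mean <- exp(pg$mu_meanlog + pg$mu_sdlog^2 / 2) * pg$mu_scale
  mu_var <- (exp(pg$mu_sdlog^2) - 1) *
    exp(2 * pg$mu_meanlog + pg$mu_sdlog^2) * pg$mu_scale^2
  n <- pg$n_haploid
  ek <- n * mu_mean / pg$s
  vk <- ek * (1 + n / (4 * pg$Ne * pg$s)) + (n / pg$s)^2 * mu_var
  m <- nrow(afs)
  expect_lt(abs(mean(afs$k) - ek), 3 * sqrt(vk / m))
  expect_lt(abs(var(afs$k) - vk) / vk, 0.1)

  # strong selection with kappa = 1 leaves almost everything monomorphic
  cfg2 <- synthetic_config(seed = 15, n_genes = 20,
                           popgen = list(s = 20, mu_meanlog = log(0.5)))
  afs2 <- gen_population_afs(cfg2)
  expect_gt(mean(afs2$k == 0), 0.97)

  # the approximation regime is policed
  cfg3 <- synthetic_config(seed = 16, n_genes = 5,
                           popgen = list(s = 1e-4, mu_meanlog = log(50)))
  expect_error(gen_population_afs(cfg3), "E\\(q\\)")
})

test_that("sperm counts track kappa but ignore ascertainment and lethality", {
  n_genes <- 40
  kap <- rep(1, n_genes); kap[1:5] <- 15
  cfg <- synthetic_config(seed = 17, n_genes = n_genes, kappa = kap,
                          ascertainment_fold = 10,
                          lethal_genes = "G0006",
                          sites_per_gene = c(LoF = 40, synonymous = 40,
                                             missense = 5),
                          ns_count = 4000, sperm_scale = 2)
  st <- gen_sites(cfg)
  st$sites$class <- as.character(classify_variants(st$sites))
  e <- compute_expectations(st$sites, cfg$ns_count)
  sp <- gen_sperm_counts(cfg, e)
  hot <- sp$gene_id %in% sprintf("G%04d", 1:5)
  expect_lt(abs(sum(sp$m_sperm[hot]) / sum(sp$lambda_sperm[hot]) - 15) / 15,
            0.25)
  expect_lt(abs(sum(sp$m_sperm[!hot]) / sum(sp$lambda_sperm[!hot]) - 1),
            0.25)

  # lethal gene: deflated in trios, not in sperm
  dn <- gen_denovo_cohort(cfg, e)
  lofs <- e$sites[e$sites$class == "LoF", ]
  nv <- count_denovo(lofs, dn)
  ng <- tapply(nv, lofs$gene_id, sum)
  lg <- tapply(lofs$lambda, lofs$gene_id, sum)
  g6_fold_trio <- ng[["G0006"]] / (lg[["G0006"]] * 10)
  expect_lt(g6_fold_trio, 0.6)  # deflation 0.2 against ascertainment 50
})
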
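# derive a module-specific child seed from the global seed (fixed counter
# scheme; keeps module outputs reproducible and mutually independent)
child_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1009 + idx * 7919) %% 2147483647)
}

#' Configuration for the synthetic trio-cohort study
#'
#' Defines the generative conditions for all synthetic inputs: a
#' heavy-tailed per-site baseline rate distribution with a CpG-like
#' high-rate component, Poisson or Negative Binomial de novo sampling with
#' optional per-gene CES inflation (kappa) and disease-ascertainment
#' inflation bounded by the inverse prevalence, multinomial or
#' Dirichlet-multinomial subcohort allocation, a Gamma-Poisson
#' mutation-selection-drift model for population allele counts, and
#' unascertained sperm-sequencing-like counts.
#'
#' @param seed integer master seed; each generator derives its own child
#'   seed from it.
#' @param n_genes number of genes.
#' @param sites_per_gene named vector: sites per gene for classes LoF,
#'   synonymous, missense.
#' @param cpg_fraction fraction of sites drawn from the high-rate CpG-like
#'   component.
#' @param mu_body_meanlog,mu_body_sdlog lognormal body of unscaled rates.
#' @param mu_cpg_meanlog,mu_cpg_sdlog lognormal CpG-like component (rates
#'   mostly > 1).
#' @param overlap_fraction fraction of genes laid down overlapping their
#'   predecessor (exercises non-overlap selection).
#' @param ns_count expected cohort-wide synonymous de novo total used to
#'   scale expectations.
#' @param prevalence disease prevalence lower bound; ascertainment folds may
#'   not exceed its inverse.
#' @param gamma overdispersion factor of de novo counts (0 = Poisson).
#' @param kappa per-gene CES mutation-rate inflation (scalar or length
#'   `n_genes`, all >= 1).
#' @param ascertainment_fold per-gene ascertainment inflation (scalar or
#'   per-gene, in \[1, 1/prevalence\]).
#' @param loeuf_range range of synthetic per-gene constraint scores; or pass
#'   a length-`n_genes` vector via `loeuf`.
#' @param loeuf optional explicit per-gene constraint scores.
#' @param subcohort_weights named positive vector of per-subcohort
#'   synonymous-count proportions.
#' @param subcohort_concentration Dirichlet concentration for allocation
#'   (`Inf` = exact multinomial).
#' @param lethal_genes gene ids whose trio counts are deflated by
#'   `lethal_deflation` (embryonic deleteriousness mode); sperm counts are
#'   unaffected.
#' @param lethal_deflation multiplicative trio deflation for lethal genes.
#' @param sperm_scale expectation scale of the sperm-sequencing assay
#'   relative to the trio cohort.
#' @param popgen list: `Ne` (diploid effective size), `s` (heterozygous
#'   selection coefficient, scalar or per-gene), `n_haploid` (sampled
#'   alleles), `sites_per_gene`, `mu_meanlog`, `mu_sdlog` (unscaled LoF CpG
#'   rate distribution), `mu_scale` (unscaled -> per-generation).
#' @return validated list of class `ces_synth_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes = 100,
                             sites_per_gene = c(LoF = 30, synonymous = 60,
                                                missense = 60),
                             cpg_fraction = 0.08,
                             mu_body_meanlog = log(0.5),
                             mu_body_sdlog = 0.8,
                             mu_cpg_meanlog = log(20),
                             mu_cpg_sdlog = 0.5,
                             overlap_fraction = 0.1,
                             ns_count = 6000,
                             prevalence = 0.01,
                             gamma = 0,
                             kappa = 1,
                             ascertainment_fold = 1,
                             loeuf_range = c(0.2, 1.5),
                             loeuf = NULL,
                             subcohort_weights = c(DDD = 0.32, GeneDx = 0.60,
                                                   RUMC = 0.08),
                             subcohort_concentration = Inf,
                             lethal_genes = character(0),
                             lethal_deflation = 0.2,
                             sperm_scale = 1,
                             popgen = list()) {
  pg <- utils::modifyList(
    list(Ne = 1e4, s = 0.05, n_haploid = 1e6, sites_per_gene = 200,
         mu_meanlog = log(10), mu_sdlog = 0.5, mu_scale = 1e-6),
    popgen
  )
  cfg <- list(seed = seed, n_genes = n_genes,
              sites_per_gene = sites_per_gene,
              cpg_fraction = cpg_fraction,
              mu_body_meanlog = mu_body_meanlog,
              mu_body_sdlog = mu_body_sdlog,
              mu_cpg_meanlog = mu_cpg_meanlog,
              mu_cpg_sdlog = mu_cpg_sdlog,
              overlap_fraction = overlap_fraction,
              ns_count = ns_count, prevalence = prevalence, gamma = gamma,
              kappa = rep_len(kappa, n_genes),
              ascertainment_fold = rep_len(ascertainment_fold, n_genes),
              loeuf_range = loeuf_range,
              loeuf = if (!is.null(loeuf)) rep_len(loeuf, n_genes),
              subcohort_weights = subcohort_weights,
              subcohort_concentration = subcohort_concentration,
              lethal_genes = lethal_genes,
              lethal_deflation = lethal_deflation,
              sperm_scale = sperm_scale,
              popgen = pg)
  validate_synth_config(cfg)
  structure(cfg, class = "ces_synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_genes < 0) stop("n_genes must be >= 0")
  if (any(cfg$sites_per_gene < 0)) stop("sites_per_gene must be >= 0")
  if (!all(c("LoF", "synonymous", "missense") %in%
           names(cfg$sites_per_gene))) {
    stop("sites_per_gene needs LoF, synonymous and missense entries")
  }
  if (cfg$prevalence <= 0 || cfg$prevalence > 1) {
    stop("prevalence must be in (0, 1]")
  }
  if (cfg$gamma < 0) stop("gamma must be >= 0")
  if (cfg$n_genes > 0) {
    if (any(cfg$kappa < 1)) stop("kappa must be >= 1")
    if (any(cfg$ascertainment_fold < 1 - 1e-12) ||
        any(cfg$ascertainment_fold > 1 / cfg$prevalence + 1e-9)) {
      stop("ascertainment_fold must lie in [1, 1/prevalence]")
    }
  }
  if (any(cfg$subcohort_weights <= 0)) stop("subcohort weights must be > 0")
  if (cfg$popgen$Ne <= 0 || any(cfg$popgen$s <= 0) ||
      cfg$popgen$n_haploid <= 0 || cfg$popgen$mu_scale <= 0) {
    stop("popgen parameters must be positive")
  }
  invisible(TRUE)
}

r_mu <- function(n, cfg) {
  cpg <- stats::runif(n) < cfg$cpg_fraction
  mu <- numeric(n)
  mu[!cpg] <- stats::rlnorm(sum(!cpg), cfg$mu_body_meanlog, cfg$mu_body_sdlog)
  mu[cpg] <- stats::rlnorm(sum(cpg), cfg$mu_cpg_meanlog, cfg$mu_cpg_sdlog)
  list(mu = mu, cpg = cpg)
}

#' Generate a synthetic site table and gene CDS table
#'
#' Lays `n_genes` genes along one synthetic chromosome (a configurable
#' fraction overlapping their predecessor to exercise non-overlap
#' selection), then draws per-gene sites of the three functional classes
#' with heavy-tailed baseline rates, quality tiers, consequence labels,
#' LoF-confidence flags and missense scores.
#'
#' @param config a [synthetic_config()].
#' @return list: `sites` (gene_id, chrom, pos, ref, alt, mu, qual,
#'   consequence, lof_hc, missense_score, cpg), `genes` (chrom, start, end,
#'   gene_id), `gene_meta` (gene_id, kappa, ascertainment_fold, loeuf).
#' @export
gen_sites <- function(config) {
  stopifnot(inherits(config, "ces_synth_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_genes
  empty <- list(
    sites = data.frame(gene_id = character(0), chrom = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0), mu = numeric(0),
                       qual = character(0), consequence = character(0),
                       lof_hc = logical(0), missense_score = numeric(0),
                       cpg = logical(0), stringsAsFactors = FALSE),
    genes = data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), gene_id = character(0),
                       stringsAsFactors = FALSE),
    gene_meta = data.frame(gene_id = character(0), kappa = numeric(0),
                           ascertainment_fold = numeric(0),
                           loeuf = numeric(0), stringsAsFactors = FALSE)
  )
  if (n == 0L) return(empty)
  ids <- sprintf("G%04d", seq_len(n))
  glen <- pmax(300L, as.integer(stats::rlnorm(n, log(1500), 0.5)))
  start <- integer(n)
  cursor <- 1000L
  for (i in seq_len(n)) {
    if (i > 1L && stats::runif(1) < config$overlap_fraction) {
      # overlap the tail of the previous gene
      start[i] <- start[i - 1L] + as.integer(glen[i - 1L] * 0.6)
    } else {
      start[i] <- cursor
    }
    cursor <- max(cursor, start[i] + glen[i]) + 500L
  }
  genes <- data.frame(chrom = "chr1", start = start,
                      end = start + glen, gene_id = ids,
                      stringsAsFactors = FALSE)
  nt <- c("A", "C", "G", "T")
  per_class <- config$sites_per_gene
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sum(per_class)
    cls <- rep(names(per_class), per_class)
    pos <- sort(sample(seq.int(start[i] + 1L, start[i] + glen[i]), m,
                       replace = m > glen[i]))
    ref <- sample(nt, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    d <- r_mu(m, config)
    qual <- sample(c("high", "TFBS", "other"), m, replace = TRUE,
                   prob = c(0.90, 0.05, 0.05))
    consequence <- character(m)
    consequence[cls == "LoF"] <-
      sample(c("stop_gained", "splice_donor_variant",
               "splice_acceptor_variant"), sum(cls == "LoF"), replace = TRUE)
    consequence[cls == "synonymous"] <- "synonymous_variant"
    consequence[cls == "missense"] <- "missense_variant"
    lof_hc <- cls == "LoF" & stats::runif(m) < 0.9
    score <- rep(NA_real_, m)
    mi <- cls == "missense"
    score[mi] <- stats::runif(sum(mi))
    score[mi][stats::runif(sum(mi)) < 0.02] <- NA_real_
    rows[[i]] <- data.frame(
      gene_id = ids[i], chrom = "chr1", pos = pos, ref = unname(ref),
      alt = unname(alt), mu = d$mu, qual = qual, consequence = consequence,
      lof_hc = lof_hc, missense_score = score, cpg = d$cpg,
      stringsAsFactors = FALSE
    )
  }
  loeuf <- if (!is.null(config$loeuf)) config$loeuf else
    stats::runif(n, config$loeuf_range[1], config$loeuf_range[2])
  list(
    sites = do.call(rbind, rows),
    genes = genes,
    gene_meta = data.frame(gene_id = ids, kappa = config$kappa,
                           ascertainment_fold = config$ascertainment_fold,
                           loeuf = loeuf, stringsAsFactors = FALSE)
  )
}

#' Generate a synthetic de novo cohort
#'
#' Draws per-site de novo counts as a Negative Binomial realised explicitly
#' as a Poisson-Gamma mixture: mean lambda_v * kappa_gene *
#' ascertainment_gene (times the lethal deflation where configured),
#' variance inflated by 1 + gamma. Each event is then allocated to a
#' subcohort, multinomially with the configured weights or
#' Dirichlet-multinomially (per gene) with the configured concentration.
#'
#' @param config a [synthetic_config()].
#' @param expectation a [compute_expectations()] result whose `sites` table
#'   carries `gene_id`, `chrom`, `pos`, `ref`, `alt` and `lambda`.
#' @return data.frame of de novo events: chrom, pos, ref, alt, gene_id,
#'   subcohort (one row per event).
#' @export
gen_denovo_cohort <- function(config, expectation) {
  stopifnot(inherits(config, "ces_synth_config"),
            inherits(expectation, "ces_expectation"))
  set.seed(child_seed(config$seed, 2L))
  s <- expectation$sites
  meta <- stats::setNames(config$kappa, sprintf("G%04d", seq_len(config$n_genes)))
  fold <- stats::setNames(config$ascertainment_fold, names(meta))
  # CES transmission bias and disease ascertainment act on the functional
  # variants; synonymous sites stay at baseline, preserving the NS anchor
  infl <- unname(meta[s$gene_id]) * unname(fold[s$gene_id])
  infl[is.na(infl)] <- 1
  infl[s$class == "synonymous"] <- 1
  mean_v <- s$lambda * infl
  if (length(config$lethal_genes)) {
    lethal <- s$gene_id %in% config$lethal_genes & s$class == "LoF"
    mean_v[lethal] <- mean_v[lethal] * config$lethal_deflation
  }
  if (config$gamma > 0) {
    lam <- stats::rgamma(length(mean_v), shape = mean_v / config$gamma,
                         scale = config$gamma)
  } else {
    lam <- mean_v
  }
  counts <- stats::rpois(length(lam), lam)
  idx <- rep(seq_along(counts), counts)
  w <- config$subcohort_weights
  cohorts <- names(w)
  ev <- s[idx, c("chrom", "pos", "ref", "alt", "gene_id"), drop = FALSE]
  if (nrow(ev) == 0L) {
    ev$subcohort <- character(0)
    rownames(ev) <- NULL
    return(ev)
  }
  if (is.finite(config$subcohort_concentration)) {
    # per-gene Dirichlet draw, then multinomial allocation
    sub <- character(nrow(ev))
    for (g in unique(ev$gene_id)) {
      gi <- which(ev$gene_id == g)
      a <- config$subcohort_concentration * w / sum(w)
      p <- stats::rgamma(length(a), shape = a)
      p <- p / sum(p)
      sub[gi] <- sample(cohorts, length(gi), replace = TRUE, prob = p)
    }
    ev$subcohort <- sub
  } else {
    ev$subcohort <- sample(cohorts, nrow(ev), replace = TRUE,
                           prob = w / sum(w))
  }
  rownames(ev) <- NULL
  ev
}

#' Generate population allele counts under the Gamma-Poisson model
#'
#' Per LoF site: frequency q ~ Gamma(shape = 4 Ne kappa mu, scale =
#' 1 / (4 Ne s)), then sampled count k ~ Poisson(n q), clamped at n (tallied;
#' negligible in the validity regime). Refuses parameter settings implying
#' E(q) > 0.1, where the strong-selection approximation breaks down.
#'
#' @param config a [synthetic_config()]; uses the `popgen` block plus
#'   per-gene `kappa`.
#' @return data.frame: gene_id, site, mu (unscaled), k, n; clamp tally in
#'   `attr(, "n_clamped")`.
#' @export
gen_population_afs <- function(config) {
  stopifnot(inherits(config, "ces_synth_config"))
  set.seed(child_seed(config$seed, 3L))
  pg <- config$popgen
  n_genes <- config$n_genes
  s_gene <- rep_len(pg$s, n_genes)
  mu_mean <- exp(pg$mu_meanlog + pg$mu_sdlog^2 / 2) * pg$mu_scale
  eq <- config$kappa * mu_mean / s_gene
  if (any(eq > 0.1)) {
    stop("parameters imply E(q) > 0.1: outside the strong-selection regime")
  }
  ids <- sprintf("G%04d", seq_len(n_genes))
  m <- pg$sites_per_gene
  rows <- vector("list", n_genes)
  clamped <- 0L
  for (i in seq_len(n_genes)) {
    mu <- stats::rlnorm(m, pg$mu_meanlog, pg$mu_sdlog)
    q <- stats::rgamma(m, shape = 4 * pg$Ne * config$kappa[i] * mu *
                         pg$mu_scale,
                       scale = 1 / (4 * pg$Ne * s_gene[i]))
    k <- stats::rpois(m, pg$n_haploid * q)
    over <- k > pg$n_haploid
    clamped <- clamped + sum(over)
    k[over] <- pg$n_haploid
    rows[[i]] <- data.frame(gene_id = ids[i], site = seq_len(m), mu = mu,
                            k = k, n = pg$n_haploid,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_clamped") <- clamped
  out
}

#' Generate sperm-sequencing-like LoF counts per gene
#'
#' Poisson counts at mean `sperm_scale * lambda_g(LoF) * kappa_gene` — CES
#' inflates sperm counts exactly as it inflates trio counts, but there is no
#' disease-ascertainment factor and no embryonic-lethality deflation, which
#' is what makes the trio-vs-sperm comparison informative.
#'
#' @inheritParams gen_denovo_cohort
#' @return data.frame: gene_id, m_sperm (observed), lambda_sperm (expected
#'   under no CES).
#' @export
gen_sperm_counts <- function(config, expectation) {
  stopifnot(inherits(config, "ces_synth_config"),
            inherits(expectation, "ces_expectation"))
  set.seed(child_seed(config$seed, 4L))
  g <- expectation$genes
  g <- g[g$class == "LoF", , drop = FALSE]
  kap <- stats::setNames(config$kappa, sprintf("G%04d", seq_len(config$n_genes)))
  lam <- config$sperm_scale * g$lambda_g
  mean_m <- lam * unname(kap[g$gene_id])
  mean_m[is.na(mean_m)] <- lam[is.na(mean_m)]
  data.frame(gene_id = g$gene_id,
             m_sperm = stats::rpois(nrow(g), mean_m),
             lambda_sperm = lam,
             stringsAsFactors = FALSE)
}

#' Simulate binned SFS site data from the multinomial model
#'
#' Draws allele-count bins from the neutral/selection multinomial-logit SFS
#' model (optionally with a CES rate inflation applied to the generative
#' rate but not to the recorded covariate, mimicking an unmodelled mutation
#' hotspot) and reports a representative allele count per site (the bin's
#' lower boundary), so binning the output reproduces the drawn categories.
#'
#' @param mu vector of site mutation rates (recorded as covariate).
#' @param beta_mu per-bin neutral coefficients (length 14).
#' @param beta_s optional per-bin selection coefficients.
#' @param shet selection coefficient(s) used in generation (scalar or per
#'   site).
#' @param kappa generative mutation-rate inflation (>= 1).
#' @return data.frame: k, mu, bin.
#' @export
gen_sfs_sites <- function(mu, beta_mu, beta_s = NULL, shet = 0, kappa = 1) {
  nb <- length(sfs_bin_boundaries()) - 1L
  stopifnot(length(beta_mu) == nb - 1L)
  shet <- rep_len(shet, length(mu))
  eta <- outer(kappa * mu, beta_mu)
  if (!is.null(beta_s)) {
    stopifnot(length(beta_s) == nb - 1L)
    eta <- eta - sqrt(shet) * matrix(beta_s, length(mu), nb - 1L,
                                     byrow = TRUE)
  }
  p <- sfs_probs_eta(eta)
  bin <- apply(p, 1, function(pr) sample.int(nb, 1, prob = pr))
  k_rep <- sfs_bin_boundaries()[bin]
  data.frame(k = k_rep, mu = mu, bin = bin)
}
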
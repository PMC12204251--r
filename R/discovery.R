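#' Disease-ascertainment model
#'
#' In a cohort ascertained for a phenotype with prevalence P(D), the
#' enrichment of any causal de novo variant is bounded above by 1 / P(D).
#' A conservative lower bound on prevalence therefore yields a strict upper
#' bound on the fold-elevation attributable to ascertainment alone.
#'
#' @param prevalence_lower_bound lower bound on disease prevalence, in (0, 1]
#'   (default 0.01, a conservative bound for neurodevelopmental disorders).
#' @return object of class `ces_ascertainment` with fields
#'   `prevalence_lower_bound` and `max_fold = 1 / prevalence_lower_bound`.
#' @export
ascertainment_model <- function(prevalence_lower_bound = 0.01) {
  p <- prevalence_lower_bound
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("prevalence_lower_bound must be in (0, 1]")
  }
  structure(list(prevalence_lower_bound = p, max_fold = 1 / p),
            class = "ces_ascertainment")
}

#' @export
print.ces_ascertainment <- function(x, ...) {
  cat(sprintf("Ascertainment bound: prevalence >= %g => max fold = %g\n",
              x$prevalence_lower_bound, x$max_fold))
  invisible(x)
}

# upper-tail P(K >= obs) under NegBin(mean, gamma); gamma = 0 -> Poisson
negbin_upper_tail <- function(observed, mean, gamma = 0) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (gamma == 0) {
    stats::ppois(observed - 1, mean, lower.tail = FALSE)
  } else {
    stats::pnbinom(observed - 1, size = mean / gamma,
                   prob = 1 / (1 + gamma), lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()]).
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return q-values, same length.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Variant-level Negative Binomial test against maximal ascertainment
#'
#' Tests each candidate variant for a de novo count exceeding what maximal
#' disease ascertainment could produce: the null mean is the
#' synonymous-normalised expectation multiplied by the ascertainment bound
#' (1 / prevalence lower bound), and the null distribution is Negative
#' Binomial with the cohort-level overdispersion factor. Upper-tail p-values
#' are Bonferroni-corrected over `n_tests` and BH-adjusted across the tested
#' variants.
#'
#' @param observed integer vector of observed de novo counts per variant.
#' @param expected positive vector of cohort-scaled expectations (lambda_v);
#'   entries <= 0 are skipped with a diagnostic tally.
#' @param ascert a [ascertainment_model()].
#' @param gamma per-site overdispersion factor (default 0.004).
#' @param n_tests Bonferroni correction factor (default: number of tested
#'   variants).
#' @param alpha family-wise significance level (default 0.05).
#' @param unit optional variant identifiers.
#' @return data.frame of class `ces_test_result`: unit, observed, expected,
#'   fold (observed / expected), p_value, q_value, bonferroni_significant.
#' @export
gof_variant_test <- function(observed, expected, ascert, gamma = 0.004,
                             n_tests = NULL, alpha = 0.05, unit = NULL) {
  stopifnot(inherits(ascert, "ces_ascertainment"))
  if (is.null(unit)) unit <- as.character(seq_along(observed))
  ok <- expected > 0
  res <- data.frame(unit = unit[ok],
                    observed = observed[ok],
                    expected = expected[ok],
                    fold = observed[ok] / expected[ok],
                    stringsAsFactors = FALSE)
  if (is.null(n_tests)) n_tests <- nrow(res)
  null_mean <- res$expected * ascert$max_fold
  res$p_value <- negbin_upper_tail(res$observed, null_mean, gamma)
  res$q_value <- bh_fdr(res$p_value)
  res$bonferroni_significant <- pmin(res$p_value * n_tests, 1) < alpha
  attr(res, "n_skipped") <- sum(!ok)
  attr(res, "n_tests") <- n_tests
  class(res) <- c("ces_test_result", "data.frame")
  res
}

#' Gene-level Poisson test against maximal ascertainment (LoF-1)
#'
#' Exact Poisson upper-tail test of per-gene LoF de novo counts against the
#' gene expectation scaled by the ascertainment bound. Bonferroni-significant
#' genes (at `alpha` over `n_tests`) form the primary candidate set; BH
#' q-values are also reported for the FDR view of the same results.
#'
#' @param observed integer vector of per-gene observed LoF counts.
#' @param expected_gene positive vector of gene expectations (lambda_g).
#' @inheritParams gof_variant_test
#' @return data.frame of class `ces_test_result` (as in
#'   [gof_variant_test()]).
#' @export
lof1_gene_test <- function(observed, expected_gene, ascert, n_tests = NULL,
                           alpha = 0.05, unit = NULL) {
  stopifnot(inherits(ascert, "ces_ascertainment"))
  if (is.null(unit)) unit <- as.character(seq_along(observed))
  ok <- expected_gene > 0
  res <- data.frame(unit = unit[ok],
                    observed = observed[ok],
                    expected = expected_gene[ok],
                    fold = observed[ok] / expected_gene[ok],
                    stringsAsFactors = FALSE)
  if (is.null(n_tests)) n_tests <- nrow(res)
  res$p_value <- negbin_upper_tail(res$observed,
                                   res$expected * ascert$max_fold, gamma = 0)
  res$q_value <- bh_fdr(res$p_value)
  res$bonferroni_significant <- pmin(res$p_value * n_tests, 1) < alpha
  attr(res, "n_skipped") <- sum(!ok)
  attr(res, "n_tests") <- n_tests
  class(res) <- c("ces_test_result", "data.frame")
  res
}

#' Constraint-filtered gene selection (LoF-2)
#'
#' Two-step selection of candidate genes whose LoF excess reflects elevated
#' mutation rate rather than disease ascertainment: (1) exact Poisson test of
#' observed counts against the plain (unscaled) gene expectation with BH
#' adjustment; (2) restriction to genes with weak apparent constraint
#' (LOEUF-like score strictly above `loeuf_threshold`), since a genuinely
#' inflated mutation rate inflates the observed/expected constraint ratio.
#'
#' @param observed per-gene observed LoF counts.
#' @param expected_gene per-gene plain expectations (no prevalence scaling).
#' @param loeuf per-gene constraint scores; `NA` excludes the gene (tallied).
#' @param fdr BH threshold (default 0.1).
#' @param loeuf_threshold strict lower threshold (default 0.5).
#' @param unit optional gene identifiers.
#' @return list with `table` (gene-level results, `selected` flag) and
#'   `selected` (character vector of selected genes).
#' @export
lof2_select <- function(observed, expected_gene, loeuf, fdr = 0.1,
                        loeuf_threshold = 0.5, unit = NULL) {
  if (is.null(unit)) unit <- as.character(seq_along(observed))
  ok <- expected_gene > 0
  tab <- data.frame(unit = unit[ok], observed = observed[ok],
                    expected = expected_gene[ok],
                    loeuf = loeuf[ok],
                    fold = observed[ok] / expected_gene[ok],
                    stringsAsFactors = FALSE)
  tab$p_value <- negbin_upper_tail(tab$observed, tab$expected, gamma = 0)
  tab$q_value <- bh_fdr(tab$p_value)
  missing_loeuf <- is.na(tab$loeuf)
  tab$selected <- !missing_loeuf & tab$q_value < fdr &
    tab$loeuf > loeuf_threshold
  list(table = tab,
       selected = tab$unit[tab$selected],
       n_missing_loeuf = sum(missing_loeuf),
       n_skipped = sum(!ok))
}

#' Enrichment ratio with Poisson-conjugate (Gamma) confidence interval
#'
#' Observed/expected ratio with a 95% interval from the Gamma posterior of
#' the Poisson mean under the Jeffreys prior Gamma(1/2, 0), divided by the
#' expectation. At zero observed counts the lower limit is reported as 0.
#'
#' @param observed nonnegative count (vectorised).
#' @param expected positive expectation (vectorised).
#' @param conf interval level (default 0.95).
#' @return data.frame with `ratio`, `ci_low`, `ci_high`.
#' @export
enrichment_with_ci <- function(observed, expected, conf = 0.95) {
  if (any(expected <= 0)) stop("expected must be > 0")
  a <- (1 - conf) / 2
  lo <- ifelse(observed == 0, 0,
               stats::qgamma(a, shape = observed + 0.5) / expected)
  hi <- stats::qgamma(1 - a, shape = observed + 0.5) / expected
  data.frame(ratio = observed / expected, ci_low = lo, ci_high = hi)
}

#' Binomial comparison of trio and sperm-sequencing LoF counts
#'
#' For each gene with at least one LoF event in both datasets, splits the
#' combined count between the two according to the expected fractions and
#' tests for excess in either direction with exact one-sided binomial tails
#' (reported separately), Bonferroni-corrected over the number of tested
#' genes.
#'
#' @param n_trio,m_sperm per-gene observed LoF counts in the trio cohort and
#'   in sperm sequencing.
#' @param lambda_trio,lambda_sperm corresponding expected counts (both zero
#'   for a gene is an error).
#' @param n_genes_tested Bonferroni factor (default: number of tested genes).
#' @param alpha significance level (default 0.05).
#' @param unit optional gene identifiers.
#' @return data.frame: unit, counts, `expected_fraction` (sperm share),
#'   one-sided p-values `p_sperm_excess`, `p_trio_excess`, `tested`, and
#'   Bonferroni flags for each direction.
#' @export
compare_cohorts <- function(n_trio, m_sperm, lambda_trio, lambda_sperm,
                            n_genes_tested = NULL, alpha = 0.05,
                            unit = NULL) {
  if (any(lambda_trio + lambda_sperm <= 0)) {
    stop("both expected counts zero for some gene")
  }
  if (is.null(unit)) unit <- as.character(seq_along(n_trio))
  frac <- lambda_sperm / (lambda_sperm + lambda_trio)
  tested <- n_trio >= 1 & m_sperm >= 1
  trials <- n_trio + m_sperm
  p_sp <- stats::pbinom(m_sperm - 1, trials, frac, lower.tail = FALSE)
  p_tr <- stats::pbinom(n_trio - 1, trials, 1 - frac, lower.tail = FALSE)
  p_sp[!tested] <- NA_real_
  p_tr[!tested] <- NA_real_
  if (is.null(n_genes_tested)) n_genes_tested <- sum(tested)
  data.frame(unit = unit, n_trio = n_trio, m_sperm = m_sperm,
             expected_fraction = frac, tested = tested,
             p_sperm_excess = p_sp, p_trio_excess = p_tr,
             sig_sperm_excess = !is.na(p_sp) &
               pmin(p_sp * n_genes_tested, 1) < alpha,
             sig_trio_excess = !is.na(p_tr) &
               pmin(p_tr * n_genes_tested, 1) < alpha,
             stringsAsFactors = FALSE)
}

#' Power of the paternal-overtransmission binomial test
#'
#' A CES driver inflates the paternal mutation rate by a factor kappa; with a
#' baseline paternal fraction of de novo mutations (default 0.75) the
#' alternative fraction follows by odds scaling:
#' p(kappa) = baseline * kappa / (baseline * kappa + 1 - baseline).
#' Power of the exact one-sided binomial test of n observed variants against
#' the baseline is computed by enumeration (no normal approximation):
#' reject when X >= c, with c the smallest integer whose baseline upper tail
#' is at most alpha; power = P(X >= c) under p(kappa).
#'
#' @param kappa mutation-rate inflation, >= 1.
#' @param n_variants number of observed de novo variants (trials).
#' @param alpha significance level.
#' @param baseline baseline paternal fraction (default 0.75).
#' @return power in \[0, 1\] (scalar; see [transmission_power_grid()] for
#'   grids).
#' @export
transmission_power <- function(kappa, n_variants, alpha = 0.05,
                               baseline = 0.75) {
  if (kappa < 1) stop("kappa must be >= 1 (inflation-only model)")
  if (n_variants < 1 || n_variants != round(n_variants)) {
    stop("n_variants must be a positive integer")
  }
  p1 <- baseline * kappa / (baseline * kappa + (1 - baseline))
  # smallest c with P(X >= c | baseline) <= alpha
  cc <- stats::qbinom(1 - alpha, n_variants, baseline) + 1
  while (cc <= n_variants &&
         stats::pbinom(cc - 1, n_variants, baseline,
                       lower.tail = FALSE) > alpha) {
    cc <- cc + 1
  }
  if (cc > n_variants + 1) return(0)
  stats::pbinom(cc - 1, n_variants, p1, lower.tail = FALSE)
}

#' Power grid over inflation, counts and significance levels
#'
#' @param kappas vector of inflation factors (>= 1).
#' @param counts vector of variant counts.
#' @param alphas vector of significance levels.
#' @inheritParams transmission_power
#' @return data.frame with columns kappa, n_variants, alpha, power.
#' @export
transmission_power_grid <- function(kappas, counts, alphas = 0.05,
                                    baseline = 0.75) {
  g <- expand.grid(kappa = kappas, n_variants = counts, alpha = alphas,
                   KEEP.OUT.ATTRS = FALSE)
  g$power <- mapply(transmission_power, g$kappa, g$n_variants, g$alpha,
                    MoreArgs = list(baseline = baseline))
  g
}
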
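#' Poisson log-likelihood of per-site de novo counts
#'
#' Sum over sites of the Poisson log-pmf with site-specific means, i.e.
#' sum(-lambda + n * log(lambda) - log(n!)), with log-factorials evaluated
#' through the log-gamma function.
#'
#' @param counts nonnegative integer vector of observed counts.
#' @param lambdas positive vector of expected counts, same length.
#' @return total log-likelihood (scalar).
#' @export
poisson_loglik <- function(counts, lambdas) {
  check_counts_lambdas(counts, lambdas)
  sum(stats::dpois(counts, lambdas, log = TRUE))
}

#' Negative Binomial log-likelihood with mean/overdispersion parametrisation
#'
#' The Negative Binomial is parametrised by mean `lambda` and overdispersion
#' factor `gamma` so that the variance is `lambda * (1 + gamma)`; this is the
#' Poisson-Gamma mixture with size `lambda / gamma` (not necessarily an
#' integer) and success probability `1 / (1 + gamma)`. As `gamma -> 0` it
#' converges to the Poisson log-likelihood.
#'
#' @inheritParams poisson_loglik
#' @param gamma overdispersion factor, strictly positive (use
#'   [poisson_loglik()] for the boundary).
#' @return total log-likelihood (scalar).
#' @export
negbin_loglik <- function(counts, lambdas, gamma) {
  check_counts_lambdas(counts, lambdas)
  if (length(gamma) != 1L || is.na(gamma) || gamma <= 0) {
    stop("gamma must be a single value > 0 (gamma = 0 is the Poisson model)")
  }
  sum(stats::dnbinom(counts, size = lambdas / gamma,
                     prob = 1 / (1 + gamma), log = TRUE))
}

check_counts_lambdas <- function(counts, lambdas) {
  if (length(counts) != length(lambdas)) stop("counts and lambdas differ in length")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(lambdas <= 0)) stop("lambdas must be > 0")
  invisible(TRUE)
}

#' Fit the overdispersion factor of per-site counts
#'
#' Maximises the Negative Binomial log-likelihood over the overdispersion
#' factor gamma on a bounded positive interval (golden-section search) and
#' compares against the nested Poisson model. The extra parameter is charged
#' 2 log-likelihood units (AIC), so the Negative Binomial is preferred when
#' the log-likelihood gain exceeds 1.
#'
#' Sites with zero expectation carry no likelihood information under either
#' model and are excluded (tallied in `n_excluded`).
#'
#' @inheritParams poisson_loglik
#' @param lower,upper search bounds for gamma (defaults 1e-8 and 10).
#' @return object of class `ces_dispersion_fit`: `gamma_hat`,
#'   `loglik_poisson`, `loglik_negbin`, `delta_loglik`,
#'   `aic_prefers_negbin`, `se_gamma` (from the observed information, `NA`
#'   at the boundary), `n_sites`, `n_excluded`.
#' @export
fit_gamma <- function(counts, lambdas, lower = 1e-8, upper = 10) {
  drop0 <- lambdas == 0
  if (any(drop0)) {
    counts <- counts[!drop0]
    lambdas <- lambdas[!drop0]
  }
  if (length(counts) < 2L) stop("need at least 2 sites with positive expectation")
  check_counts_lambdas(counts, lambdas)
  ll0 <- poisson_loglik(counts, lambdas)
  if (all(counts == 0)) {
    # no events: the count variation carries no information about site-level
    # dispersion (large gamma would only mimic zero inflation), so report
    # the Poisson boundary, flagged degenerate
    return(structure(
      list(gamma_hat = 0, loglik_poisson = ll0, loglik_negbin = ll0,
           delta_loglik = 0, aic_prefers_negbin = FALSE,
           se_gamma = NA_real_, n_sites = length(counts),
           n_excluded = sum(drop0), degenerate = TRUE),
      class = "ces_dispersion_fit"
    ))
  }
  f <- function(g) negbin_loglik(counts, lambdas, g)
  opt <- stats::optimize(f, interval = c(lower, upper), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  gamma_hat <- opt$maximum
  ll1 <- opt$objective
  boundary <- FALSE
  if (ll1 <= ll0) {
    # supremum attained at the Poisson boundary gamma -> 0
    gamma_hat <- 0
    ll1 <- ll0
    boundary <- TRUE
  }
  se <- NA_real_
  if (!boundary) {
    h <- max(1e-6, gamma_hat * 1e-4)
    if (gamma_hat - h > lower && gamma_hat + h < upper) {
      d2 <- (f(gamma_hat + h) - 2 * ll1 + f(gamma_hat - h)) / h^2
      if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
    }
  }
  delta <- ll1 - ll0
  structure(
    list(gamma_hat = gamma_hat,
         loglik_poisson = ll0,
         loglik_negbin = ll1,
         delta_loglik = delta,
         aic_prefers_negbin = delta > 1,
         se_gamma = se,
         n_sites = length(counts),
         n_excluded = sum(drop0)),
    class = "ces_dispersion_fit"
  )
}

#' @export
print.ces_dispersion_fit <- function(x, ...) {
  cat(sprintf(
    "Overdispersion fit over %d sites: gamma_hat = %.4g (delta logL = %.3g; %s)\n",
    x$n_sites, x$gamma_hat, x$delta_loglik,
    if (x$aic_prefers_negbin) "AIC prefers Negative Binomial" else
      "AIC prefers Poisson"))
  invisible(x)
}

#' Gene-level chi-squared goodness-of-fit test for dispersion
#'
#' Tests whether gene-aggregated counts are consistent with Poisson noise
#' around their expectations using chi2 = sum (n_g - lambda_g)^2 / lambda_g
#' with degrees of freedom equal to the number of tested genes minus 1
#' (upper-tail p-value). Genes with zero expectation are excluded and
#' tallied.
#'
#' @param ng observed per-gene counts.
#' @param lambda_g expected per-gene counts (same length).
#' @return object of class `ces_gene_chi2`: `chi2`, `df`, `p_value`,
#'   `n_genes`, `n_excluded`.
#' @export
gene_level_chi2 <- function(ng, lambda_g) {
  if (length(ng) != length(lambda_g)) stop("ng and lambda_g differ in length")
  drop0 <- lambda_g == 0
  ng <- ng[!drop0]
  lambda_g <- lambda_g[!drop0]
  if (length(ng) < 2L) stop("need at least 2 genes with positive expectation")
  if (any(ng < 0)) stop("counts must be nonnegative")
  chi2 <- sum((ng - lambda_g)^2 / lambda_g)
  df <- length(ng) - 1L
  structure(
    list(chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         n_genes = length(ng), n_excluded = sum(drop0)),
    class = "ces_gene_chi2"
  )
}

#' @export
print.ces_gene_chi2 <- function(x, ...) {
  cat(sprintf("Gene-level dispersion: chi2 = %.2f on %d df, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}
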
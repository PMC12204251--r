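#' Filter an allele-count table for the mutation-selection-drift analysis
#'
#' Keeps sites with unscaled baseline rate strictly above `min_mu`
#' (CpG-transition-like sites, where most of the information about recurrent
#' mutation resides) within genes that retain at least `min_sites` such
#' sites.
#'
#' @param table data.frame with columns `gene_id`, `k` (derived allele
#'   count), `mu` (unscaled baseline rate).
#' @param min_mu strict lower rate threshold (default 1).
#' @param min_sites minimum qualifying sites per gene (default 10).
#' @return filtered table (possibly empty), with dropped-gene ids in
#'   `attr(, "dropped_genes")`.
#' @export
filter_nei_genes <- function(table, min_mu = 1, min_sites = 10) {
  stopifnot(all(c("gene_id", "k", "mu") %in% names(table)))
  keep <- table$mu > min_mu
  tab <- table[keep, , drop = FALSE]
  n_by_gene <- table(tab$gene_id)
  good <- names(n_by_gene)[n_by_gene >= min_sites]
  out <- tab[tab$gene_id %in% good, , drop = FALSE]
  attr(out, "dropped_genes") <-
    sort(setdiff(unique(table$gene_id), good))
  out
}

#' Mutation-selection-drift decomposition of allele counts for one gene
#'
#' Under the Gamma approximation for allele frequencies at strongly selected,
#' recurrently mutated sites (shape 4 Ne mu, scale 1 / (4 Ne s)), sampled
#' allele counts are Gamma-Poisson with
#' E(k) = kappa n E(mu) / s and
#' Var(k) = kappa n E(mu)/s (1 + n/(4 Ne s)) + kappa^2 (n/s)^2 Var(mu).
#' Two moment estimators follow:
#' \itemize{
#'   \item `kappa_over_s` = mean(k) / (n * mean(mu)): the mean allele count
#'     scaled by rate, equal to kappa / s — the only term sensitive to
#'     mutation-rate inflation;
#'   \item `drift_term` = (Var(k) - var_mu_term - mean(k)) / mean(k),
#'     an estimate of n / (4 Ne s): drift-driven variance inflation,
#'     insensitive to kappa.
#' }
#' The rate-variation component `var_mu_term` is the squared slope of the
#' through-origin Poisson regression of k on mu times the sample variance of
#' mu.
#'
#' @param k integer vector of observed derived allele counts for the gene's
#'   sites.
#' @param mu unscaled baseline rates for the same sites.
#' @param n haploid sample size (single value for the whole table).
#' @param mu_scale factor converting unscaled rates to per-generation
#'   probabilities (default 1: rates already scaled).
#' @return list: `kappa_over_s`, `drift_term`, `var_mu_term`, `slope`,
#'   `n_sites`, `mean_k`, `drift_nonpositive` flag. `NULL` (with a message)
#'   when mean(k) = 0 — no information.
#' @export
nei_decompose <- function(k, mu, n, mu_scale = 1) {
  if (length(k) != length(mu)) stop("k and mu differ in length")
  if (any(k < 0) || any(k > n)) stop("counts must satisfy 0 <= k <= n")
  if (any(mu <= 0)) stop("mu must be > 0")
  if (mean(k) == 0) {
    message("all allele counts zero; gene skipped")
    return(NULL)
  }
  mus <- mu * mu_scale
  slope <- sum(k) / sum(mus)                 # Poisson MLE of k ~ slope * mu
  var_mu_term <- slope^2 * stats::var(mus)   # rate-variation component
  kbar <- mean(k)
  drift <- (stats::var(k) - var_mu_term - kbar) / kbar
  list(kappa_over_s = kbar / (n * mean(mus)),
       drift_term = drift,
       var_mu_term = var_mu_term,
       slope = slope,
       n_sites = length(k),
       mean_k = kbar,
       drift_nonpositive = drift <= 0)
}

#' Per-gene decomposition over a filtered allele-count table
#'
#' @param table filtered table from [filter_nei_genes()].
#' @inheritParams nei_decompose
#' @return data.frame with one row per estimable gene: gene_id, n_sites,
#'   kappa_over_s, drift_term, var_mu_term, mean_k, drift_nonpositive.
#'   Genes with all-zero counts are skipped (ids in `attr(, "skipped")`).
#' @export
nei_decompose_genes <- function(table, n, mu_scale = 1) {
  if (nrow(table) == 0L) stop("empty allele-count table; nothing to estimate")
  if ("n" %in% names(table) && length(unique(table$n)) > 1L) {
    stop("mixed sample sizes in one table are not supported")
  }
  rows <- list()
  skipped <- character(0)
  for (g in split(table, table$gene_id)) {
    est <- suppressMessages(nei_decompose(g$k, g$mu, n, mu_scale))
    if (is.null(est)) {
      skipped <- c(skipped, g$gene_id[1])
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id[1], n_sites = est$n_sites,
      kappa_over_s = est$kappa_over_s, drift_term = est$drift_term,
      var_mu_term = est$var_mu_term, mean_k = est$mean_k,
      drift_nonpositive = est$drift_nonpositive,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' CES residuals from the mean-variance regression across genes
#'
#' Ordinary least squares of log(kappa_over_s) on log(drift_term) across
#' genes. Both quantities scale with 1/s, so selection strength moves genes
#' along the regression line; mutation-rate inflation (kappa) moves only the
#' mean term, so CES candidates appear as positive residuals. Genes with
#' nonpositive drift estimates cannot enter the log-log fit and are returned
#' flagged with `NA` residuals.
#'
#' @param estimates data.frame from [nei_decompose_genes()].
#' @param min_genes minimum genes with positive drift term (default 10).
#' @return data.frame: gene_id, log_kappa_over_s, log_drift, residual,
#'   `in_fit`; regression coefficients in `attr(, "coefficients")`.
#' @export
ces_residuals <- function(estimates, min_genes = 10) {
  ok <- estimates$drift_term > 0 & estimates$kappa_over_s > 0
  if (sum(ok) < min_genes) {
    stop("need at least ", min_genes, " genes with positive drift term")
  }
  x <- log(estimates$drift_term[ok])
  y <- log(estimates$kappa_over_s[ok])
  if (stats::var(x) == 0) stop("degenerate drift terms: no spread in x")
  fit <- stats::lm(y ~ x)
  out <- data.frame(gene_id = estimates$gene_id,
                    log_kappa_over_s = ifelse(ok, log(estimates$kappa_over_s),
                                              NA_real_),
                    log_drift = ifelse(ok, log(pmax(estimates$drift_term, 0)),
                                       NA_real_),
                    residual = NA_real_,
                    in_fit = ok,
                    stringsAsFactors = FALSE)
  out$residual[ok] <- stats::residuals(fit)
  attr(out, "coefficients") <- stats::coef(fit)
  out
}

# merge bins with fewer than min_size members into the next-highest bin;
# a deficient top bin merges downward. bins: integer assignments ordered by
# increasing rate. Returns remapped assignments.
merge_small_bins <- function(bins, min_size = 10) {
  repeat {
    lev <- sort(unique(bins))
    if (length(lev) <= 1L) break
    sizes <- table(factor(bins, levels = lev))
    small <- which(sizes < min_size)
    if (!length(small)) break
    i <- small[1]
    if (i < length(lev)) {
      bins[bins == lev[i]] <- lev[i + 1]   # merge upward
    } else {
      bins[bins == lev[i]] <- lev[i - 1]   # top bin merges down
    }
  }
  match(bins, sort(unique(bins)))
}

#' Rate-linearity (proportionality) regression for one gene
#'
#' Fits the proportional model k ~ Poisson(c * mu) through the origin (MLE
#' c = sum(k) / sum(mu)) and returns rate-binned mean allele counts for
#' visualisation, merging bins with fewer than `min_bin` sites into the
#' next-highest bin. Under CES all sites of a gene share one linear
#' inflation, so binned means should lie on a line through the origin.
#'
#' @inheritParams nei_decompose
#' @param breaks bin breakpoints on mu (default: up to 10 equal-count
#'   quantile bins).
#' @param min_bin minimum sites per retained bin (default 10).
#' @return list: `slope`, `se_slope` (Poisson), and `bins` data.frame
#'   (mean_mu, mean_k, n_sites per merged bin).
#' @export
rate_linearity_regression <- function(k, mu, breaks = NULL, min_bin = 10) {
  if (sum(mu) <= 0) stop("sum of rates must be positive")
  slope <- sum(k) / sum(mu)
  se <- sqrt(sum(k)) / sum(mu)
  if (is.null(breaks)) {
    qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = 11)))
    breaks <- if (length(qs) > 1) qs else c(min(mu) - 1, max(mu) + 1)
  }
  b <- findInterval(mu, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  b <- merge_small_bins(b, min_size = min_bin)
  bins <- data.frame(
    mean_mu = as.numeric(tapply(mu, b, mean)),
    mean_k = as.numeric(tapply(k, b, mean)),
    n_sites = as.integer(table(b))
  )
  list(slope = slope, se_slope = se, bins = bins)
}
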
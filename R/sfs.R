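#' Allele-count bin boundaries for the SFS model
#'
#' Fixed left-inclusive boundaries; the first bin (k = 0, monomorphic) is the
#' multinomial reference category. Counts at or above the last boundary are
#' assigned to the top bin.
#'
#' @return integer vector of boundaries.
#' @export
sfs_bin_boundaries <- function() {
  c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 16L, 24L, 36L, 100L)
}

#' Bin allele counts into SFS categories
#'
#' @param k nonnegative integer vector of allele counts.
#' @return integer bin index in 1..15; bin 1 is the k = 0 reference, the top
#'   bin absorbs k >= 36 (counts >= 100, above the last boundary, are
#'   assigned there too and tallied in `attr(, "n_above_top")`).
#' @export
bin_counts <- function(k) {
  if (any(k < 0)) stop("allele counts must be nonnegative")
  b <- sfs_bin_boundaries()
  idx <- findInterval(k, b)
  n_above <- sum(idx >= length(b))
  idx[idx >= length(b)] <- length(b) - 1L
  attr(idx, "n_above_top") <- n_above
  idx
}

# log-likelihood of multinomial-logit SFS: eta is an n_sites x (B-1) matrix
# of linear predictors for the non-reference bins; the reference bin (k = 0)
# has predictor 0. bins: integer in 1..B.
sfs_loglik_eta <- function(bins, eta) {
  n <- length(bins)
  M <- pmax(0, apply(eta, 1, max))
  lse <- M + log(exp(-M) + rowSums(exp(eta - M)))
  pick <- rep(0, n)
  nz <- bins > 1L
  pick[nz] <- eta[cbind(which(nz), bins[nz] - 1L)]
  sum(pick - lse)
}

# per-site bin probabilities given eta (n x (B-1)); returns n x B matrix
sfs_probs_eta <- function(eta) {
  M <- pmax(0, apply(eta, 1, max))
  w <- cbind(exp(-M), exp(eta - M))
  w / rowSums(w)
}

# generic fit of per-bin coefficients beta on scalar covariate x with fixed
# offset: eta_ib = offset_ib + sign * beta_b * x_i. Concave; L-BFGS-B with
# analytic gradient. Coefficients bounded to avoid runaway at empty bins.
fit_sfs_coefs <- function(bins, x, offset, sign = 1, n_bins,
                          bound = 50, reltol = 1e-8) {
  nb1 <- n_bins - 1L
  ind <- matrix(0, length(bins), nb1)
  nz <- bins > 1L
  ind[cbind(which(nz), bins[nz] - 1L)] <- 1
  if (!any(nz)) {
    # fully monomorphic data: the likelihood increases monotonically as every
    # non-reference log-odds falls, so the MLE sits at the search bound
    beta <- rep(-sign * bound, nb1)
    warning(nb1, " bin coefficient(s) at the search bound (likely empty bins)")
    eta <- offset + sign * outer(x, beta)
    return(list(beta = beta, se = rep(NA_real_, nb1),
                loglik = sfs_loglik_eta(bins, eta),
                at_bound = rep(TRUE, nb1)))
  }
  negll <- function(beta) {
    eta <- offset + sign * outer(x, beta)
    -sfs_loglik_eta(bins, eta)
  }
  grad <- function(beta) {
    eta <- offset + sign * outer(x, beta)
    p <- sfs_probs_eta(eta)[, -1, drop = FALSE]
    -sign * colSums(x * (ind - p))
  }
  opt <- stats::optim(rep(0, nb1), negll, grad, method = "L-BFGS-B",
                      lower = -bound, upper = bound,
                      control = list(maxit = 500, factr = reltol / 1e-15))
  if (opt$convergence != 0) {
    stop("SFS coefficient fit did not converge: ", opt$message)
  }
  beta <- opt$par
  at_bound <- abs(abs(beta) - bound) < 1e-6
  if (any(at_bound)) {
    warning(sum(at_bound), " bin coefficient(s) at the search bound ",
            "(likely empty bins)")
  }
  H <- stats::optimHess(beta, negll, grad)
  se <- rep(NA_real_, nb1)
  vcov <- matrix(NA_real_, nb1, nb1)
  ok <- !at_bound
  if (any(ok)) {
    Vi <- try(solve(H[ok, ok, drop = FALSE]), silent = TRUE)
    if (!inherits(Vi, "try-error")) {
      d <- diag(Vi)
      se[ok] <- ifelse(d > 0, sqrt(d), NA_real_)
      vcov[ok, ok] <- Vi
    }
  }
  list(beta = beta, se = se, vcov = vcov, loglik = -opt$value,
       at_bound = at_bound)
}

#' Fit the neutral SFS model on synonymous sites
#'
#' Multinomial-logit model of binned allele counts with log-odds of each
#' non-reference bin (relative to the monomorphic k = 0 bin) linear in the
#' baseline mutation rate and no intercept:
#' log P(K in bin i | mu) / P(K = 0 | mu) = beta_mu_i * mu.
#'
#' @param k synonymous allele counts.
#' @param mu baseline mutation rates for the same sites (must take at least
#'   two distinct values).
#' @return object of class `ces_sfs_neutral`: `beta_mu`, `se`, `loglik`,
#'   `n_sites`, `bin_occupancy`.
#' @export
fit_neutral_sfs <- function(k, mu) {
  if (length(k) != length(mu)) stop("k and mu differ in length")
  if (length(unique(mu)) < 2L) {
    stop("mutation rate constant across sites: slope-only model unidentifiable")
  }
  bins <- bin_counts(k)
  nb <- length(sfs_bin_boundaries()) - 1L
  off <- matrix(0, length(bins), nb - 1L)
  fit <- fit_sfs_coefs(bins, x = mu, offset = off, sign = 1, n_bins = nb)
  structure(
    list(beta_mu = fit$beta, se = fit$se, vcov = fit$vcov,
         loglik = fit$loglik,
         n_sites = length(k),
         bin_occupancy = tabulate(bins, nbins = nb),
         at_bound = fit$at_bound),
    class = "ces_sfs_neutral"
  )
}

#' @export
print.ces_sfs_neutral <- function(x, ...) {
  cat("Neutral SFS model over", x$n_sites, "sites; logL =",
      format(x$loglik), "\n")
  invisible(x)
}

#' Fit the selection SFS model on LoF sites
#'
#' With the neutral coefficients held fixed, fits per-bin selection
#' coefficients beta_s so that
#' log P(K in bin i | mu, shet) / P(K = 0 | mu, shet)
#'   = beta_mu_i * mu - beta_s_i * sqrt(shet).
#' The square-root dependence makes the model identifiable across genes with
#' different prior selection strengths. Prior mean shet values per site are
#' the covariate; positive beta_s means selection depletes polymorphism (the
#' expected regime, not enforced).
#'
#' @param k LoF allele counts.
#' @param mu baseline rates.
#' @param shet_prior per-site prior mean selection coefficients in \[0, 1\]
#'   (per gene, replicated over its sites).
#' @param neutral a fitted [fit_neutral_sfs()] model.
#' @return object of class `ces_sfs_selection`: `beta_s`, `se`, `loglik`,
#'   `unidentifiable` flag (all shet zero).
#' @export
fit_selection_sfs <- function(k, mu, shet_prior, neutral) {
  stopifnot(inherits(neutral, "ces_sfs_neutral"))
  if (any(shet_prior < 0 | shet_prior > 1)) stop("shet must be in [0, 1]")
  bins <- bin_counts(k)
  nb <- length(sfs_bin_boundaries()) - 1L
  off <- outer(mu, neutral$beta_mu)
  x <- sqrt(shet_prior)
  if (all(x == 0)) {
    return(structure(
      list(beta_s = rep(0, nb - 1L), se = rep(NA_real_, nb - 1L),
           loglik = sfs_loglik_eta(bins, off), unidentifiable = TRUE),
      class = "ces_sfs_selection"
    ))
  }
  fit <- fit_sfs_coefs(bins, x = x, offset = off, sign = -1, n_bins = nb)
  structure(
    list(beta_s = fit$beta, se = fit$se, vcov = fit$vcov,
         loglik = fit$loglik,
         unidentifiable = FALSE, at_bound = fit$at_bound),
    class = "ces_sfs_selection"
  )
}

#' @export
print.ces_sfs_selection <- function(x, ...) {
  cat("Selection SFS model; logL =", format(x$loglik),
      if (isTRUE(x$unidentifiable)) "(unidentifiable: all shet = 0)" else "",
      "\n")
  invisible(x)
}

#' Re-estimate a gene's selection coefficient from its LoF SFS
#'
#' One-dimensional bounded maximum likelihood for shet in \[0, 1\] with the
#' global neutral and selection coefficients fixed. Multi-start (0.01, 0.1,
#' 0.5) bounded quasi-Newton guards against flat stretches of the
#' likelihood; boundary optima are reported at the bound.
#'
#' @param k the gene's LoF allele counts.
#' @param mu matching baseline rates.
#' @param neutral fitted [fit_neutral_sfs()] model.
#' @param selection fitted [fit_selection_sfs()] model.
#' @return object of class `ces_shet`: `shet`, `loglik`, `n_sites`.
#' @export
estimate_gene_shet <- function(k, mu, neutral, selection) {
  stopifnot(inherits(neutral, "ces_sfs_neutral"),
            inherits(selection, "ces_sfs_selection"))
  if (length(k) == 0L) stop("gene has no sites")
  bins <- bin_counts(k)
  off <- outer(mu, neutral$beta_mu)
  bs <- selection$beta_s
  negll <- function(s) {
    eta <- off - sqrt(s) * matrix(bs, length(k), length(bs), byrow = TRUE)
    -sfs_loglik_eta(bins, eta)
  }
  best <- NULL
  for (s0 in c(0.01, 0.1, 0.5)) {
    o <- stats::optim(s0, negll, method = "L-BFGS-B", lower = 0, upper = 1,
                      control = list(maxit = 200))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(
    list(shet = best$par, loglik = -best$value, n_sites = length(k)),
    class = "ces_shet"
  )
}

#' @export
print.ces_shet <- function(x, ...) {
  cat(sprintf("shet = %.4f (logL = %.3f, %d sites)\n",
              x$shet, x$loglik, x$n_sites))
  invisible(x)
}

#' Per-gene shet estimates over a site table
#'
#' @param table data.frame with `gene_id`, `k`, `mu`.
#' @inheritParams estimate_gene_shet
#' @return data.frame: gene_id, shet, loglik, n_sites.
#' @export
estimate_shet_table <- function(table, neutral, selection) {
  stopifnot(all(c("gene_id", "k", "mu") %in% names(table)))
  rows <- lapply(split(table, table$gene_id), function(g) {
    e <- estimate_gene_shet(g$k, g$mu, neutral, selection)
    data.frame(gene_id = g$gene_id[1], shet = e$shet, loglik = e$loglik,
               n_sites = e$n_sites, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
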
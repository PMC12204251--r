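#' Validate a gene-by-subcohort count matrix with synonymous weights
#'
#' @param counts nonnegative integer matrix, genes in rows, subcohorts in
#'   columns (de novo LoF counts).
#' @param weights positive per-subcohort synonymous de novo counts used as
#'   sampling weights; length equals `ncol(counts)`.
#' @return invisible TRUE on success.
#' @export
check_cohort_matrix <- function(counts, weights) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (length(weights) != ncol(counts)) {
    stop("one weight per subcohort required")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative with positive sum")
  }
  invisible(TRUE)
}

# multinomial log-pmf by rows, explicit log-gamma form; rows with zero total
# contribute 0. Positive counts on zero-probability cohorts give -Inf.
multinom_loglik_rows <- function(counts, p) {
  counts <- as.matrix(counts)
  m <- rowSums(counts)
  lg <- lgamma(m + 1) - rowSums(lgamma(counts + 1))
  xlogp <- counts * rep(log(p), each = nrow(counts))
  xlogp[counts == 0] <- 0  # 0 * log(0) := 0
  lg + rowSums(xlogp)
}

#' Log-likelihood of the fixed-probability multinomial model
#'
#' Model 1 of the phenotypic-homogeneity comparison: each gene's subcohort
#' allocation is multinomial with probabilities fixed at the synonymous-count
#' proportions of the subcohorts (0 free parameters).
#'
#' @inheritParams check_cohort_matrix
#' @return total log-likelihood; `-Inf` (reported explicitly) if a positive
#'   count falls in a zero-weight subcohort.
#' @export
loglik_fixed_multinomial <- function(counts, weights) {
  check_cohort_matrix(counts, weights)
  p <- weights / sum(weights)
  sum(multinom_loglik_rows(as.matrix(counts), p))
}

#' Fit the free-probability multinomial model
#'
#' Model 2: unconstrained allocation probabilities shared across genes. The
#' MLE is the pooled column proportion.
#'
#' @inheritParams check_cohort_matrix
#' @return list with `probabilities` (MLE) and `loglik`.
#' @export
fit_free_multinomial <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 subcohorts")
  tot <- sum(counts)
  if (tot == 0) stop("grand total is zero; probabilities unidentifiable")
  p <- colSums(counts) / tot
  list(probabilities = p,
       loglik = sum(multinom_loglik_rows(counts, p)))
}

# Dirichlet-multinomial log-pmf by rows for concentration alpha0 and mean p.
dirmult_loglik_rows <- function(counts, p, alpha0) {
  counts <- as.matrix(counts)
  a <- alpha0 * p
  m <- rowSums(counts)
  comb <- lgamma(m + 1) - rowSums(lgamma(counts + 1))
  core <- lgamma(alpha0) - lgamma(alpha0 + m) +
    rowSums(lgamma(sweep(counts, 2, a, "+"))) - sum(lgamma(a))
  comb + core
}

#' Fit a Dirichlet-Multinomial overdispersion model
#'
#' Models 3 and 4 of the homogeneity comparison. The Dirichlet mean is either
#' fixed at the synonymous-weight proportions (`center = "fixed"`, 1 free
#' parameter: the concentration) or free (`center = "free"`, concentration
#' plus C-1 mean parameters). The concentration is optimised on the log
#' scale over \[1e-3, 1e6\]; because the Dirichlet-Multinomial approaches the
#' plain multinomial as the concentration grows, the multinomial limit is
#' also evaluated and reported (concentration `Inf`) whenever it attains the
#' supremum, which keeps the model nesting exact.
#'
#' @inheritParams check_cohort_matrix
#' @param center `"fixed"` (mean at weight proportions) or `"free"`.
#' @return list with `concentration`, `probabilities`, `loglik` and
#'   `boundary` (TRUE when the multinomial limit was attained).
#' @export
fit_dirichlet_multinomial <- function(counts, weights = NULL,
                                      center = c("fixed", "free"),
                                      extra_inits = list()) {
  center <- match.arg(center)
  counts <- as.matrix(counts)
  lo <- log(1e-3); hi <- log(1e6)
  if (center == "fixed") {
    if (is.null(weights)) stop("weights required for center = 'fixed'")
    check_cohort_matrix(counts, weights)
    p <- weights / sum(weights)
    f <- function(la) sum(dirmult_loglik_rows(counts, p, exp(la)))
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
    ll_mult <- sum(multinom_loglik_rows(counts, p))
    if (ll_mult >= opt$objective) {
      return(list(concentration = Inf, probabilities = p, loglik = ll_mult,
                  boundary = TRUE))
    }
    return(list(concentration = exp(opt$maximum), probabilities = p,
                loglik = opt$objective, boundary = FALSE))
  }
  # free mean: joint optimisation over softmax(mean) and log concentration,
  # deterministically initialised at the free-multinomial MLE
  m2 <- fit_free_multinomial(counts)
  C <- ncol(counts)
  obj <- function(th) {
    eta <- c(0, th[seq_len(C - 1)])
    p <- exp(eta - max(eta)); p <- p / sum(p)
    la <- min(max(th[C], lo), hi)
    -sum(dirmult_loglik_rows(counts, p, exp(la)))
  }
  to_theta <- function(p, a0) {
    p <- pmax(p, 1e-8); p <- p / sum(p)
    c(log(p[-1] / p[1]), log(a0))
  }
  inits <- c(list(to_theta(m2$probabilities, 10)),
             lapply(extra_inits, function(e) to_theta(e$p, e$a0)))
  opt <- NULL
  for (th0 in inits) {
    o <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  eta <- c(0, opt$par[seq_len(C - 1)])
  p <- exp(eta - max(eta)); p <- p / sum(p)
  a0 <- exp(min(max(opt$par[C], lo), hi))
  ll <- -opt$value
  # multinomial limit with free probabilities = model 2 supremum
  if (m2$loglik >= ll) {
    return(list(concentration = Inf, probabilities = m2$probabilities,
                loglik = m2$loglik, boundary = TRUE))
  }
  list(concentration = a0, probabilities = p, loglik = ll, boundary = FALSE)
}

#' Compare the four subcohort-sampling models by AIC
#'
#' Fits (1) the fixed multinomial, (2) the free multinomial, (3) the
#' Dirichlet-Multinomial centred on the weights, and (4) the fully free
#' Dirichlet-Multinomial, with 0, C-1, 1 and C free parameters respectively
#' (0, 2, 1, 3 for three subcohorts), and ranks them by AIC = 2k - 2 logL.
#' AIC ties resolve toward the simpler (lower-numbered) model.
#'
#' @inheritParams check_cohort_matrix
#' @return object of class `ces_homogeneity`: data.frame `table` (model,
#'   n_params, loglik, aic), `best_model`, and the individual fits.
#' @export
compare_homogeneity <- function(counts, weights) {
  counts <- as.matrix(counts)
  check_cohort_matrix(counts, weights)
  C <- ncol(counts)
  ll1 <- loglik_fixed_multinomial(counts, weights)
  m2 <- fit_free_multinomial(counts)
  m3 <- fit_dirichlet_multinomial(counts, weights, center = "fixed")
  m4 <- fit_dirichlet_multinomial(
    counts, center = "free",
    extra_inits = list(list(p = weights / sum(weights),
                            a0 = if (is.finite(m3$concentration))
                              m3$concentration else 1e5))
  )
  # the free DM nests both the fixed-centre DM and the free multinomial;
  # guard the inequality against optimiser shortfall
  if (m4$loglik < m3$loglik) m4 <- m3
  if (m4$loglik < m2$loglik) {
    m4 <- list(concentration = Inf, probabilities = m2$probabilities,
               loglik = m2$loglik, boundary = TRUE)
  }
  k <- c(0L, C - 1L, 1L, C)
  ll <- c(ll1, m2$loglik, m3$loglik, m4$loglik)
  aic <- 2 * k - 2 * ll
  tab <- data.frame(model = paste0("m", 1:4), n_params = k,
                    loglik = ll, aic = aic)
  structure(
    list(table = tab,
         best_model = tab$model[which.min(aic)],
         fits = list(m2 = m2, m3 = m3, m4 = m4),
         concentration_identifiable = nrow(counts) > 1L),
    class = "ces_homogeneity"
  )
}

#' @export
print.ces_homogeneity <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("AIC-preferred model:", x$best_model, "\n")
  if (!x$concentration_identifiable) {
    cat("note: single-gene matrix; Dirichlet concentration unidentifiable\n")
  }
  invisible(x)
}
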
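# Gamma-Poisson generator used as the test-side oracle for the decomposition
r_nei_gene <- function(nsites, kappa = 1, s = 0.05, Ne = 1e4, n = 1e6,
                       meanlog = log(1e-5), sdlog = 0.5) {
  mu <- rlnorm(nsites, meanlog, sdlog)
  q <- rgamma(nsites, shape = 4 * Ne * kappa * mu, scale = 1 / (4 * Ne * s))
  k <- rpois(nsites, n * q)
  data.frame(k = pmin(k, n), mu = mu)
}

test_that("site and gene filters are strict at the boundaries", {
  t9 <- data.frame(gene_id = "A", k = 0L, mu = rep(2, 9))
  expect_equal(nrow(filter_nei_genes(t9)), 0L)
  expect_equal(attr(filter_nei_genes(t9), "dropped_genes"), "A")

  # 10 sites but one exactly at mu = 1 -> excluded, gene drops to 9
  t10 <- data.frame(gene_id = "A", k = 0L, mu = c(rep(2, 9), 1))
  expect_equal(nrow(filter_nei_genes(t10)), 0L)

  mixed <- data.frame(
    gene_id = rep(c("A", "B"), c(12, 12)),
    k = 0L,
    mu = c(rep(3, 12), rep(c(3, 0.5), 6))
  )
  out <- filter_nei_genes(mixed)
  expect_equal(unique(out$gene_id), "A")  # B keeps only 6 qualifying sites
  expect_equal(nrow(out), 12L)
})

test_that("decomposition recovers 1/s and the drift ratio on model data", {
  set.seed(31)
  s <- 0.05; Ne <- 1e4; n <- 1e6
  reps <- t(replicate(100, {
    d <- r_nei_gene(200, kappa = 1, s = s, Ne = Ne, n = n)
    e <- nei_decompose(d$k, d$mu, n = n)
    c(e$kappa_over_s, e$drift_term)
  }))
  expect_lt(abs(median(reps[, 1]) - 1 / s) / (1 / s), 0.2)
  expect_lt(abs(median(reps[, 2]) - n / (4 * Ne * s)) / (n / (4 * Ne * s)),
            0.3)
})

test_that("mutation-rate inflation moves the mean term but not the drift term", {
  set.seed(32)
  s <- 0.05; Ne <- 1e4; n <- 1e6
  est <- function(kappa) {
    r <- t(replicate(60, {
      d <- r_nei_gene(200, kappa = kappa, s = s, Ne = Ne, n = n)
      e <- nei_decompose(d$k, d$mu, n = n)
      c(e$kappa_over_s, e$drift_term)
    }))
    colMeans(r)
  }
  e1 <- est(1)
  e10 <- est(10)
  expect_lt(abs(e10[1] / e1[1] - 10), 1.5)          # mean term scales ~x10
  expect_lt(abs(e10[2] - e1[2]) / e1[2], 0.15)      # drift term unchanged
})

test_that("all-zero genes are skipped with a diagnostic", {
  tab <- data.frame(gene_id = rep(c("A", "B"), each = 12),
                    k = c(rep(0L, 12), rpois(12, 3) + 1L),
                    mu = rep(2, 24))
  est <- nei_decompose_genes(tab, n = 1e6)
  expect_equal(attr(est, "skipped"), "A")
  expect_equal(est$gene_id, "B")
  expect_message(out <- nei_decompose(rep(0L, 10), rep(2, 10), 1e6),
                 "skipped")
  expect_null(out)
})

test_that("regression residuals are centred, and injected inflation surfaces at the top", {
  set.seed(33)
  n <- 1e6; Ne <- 1e4
  make_genes <- function(n_genes, kappas, s_range = c(0.02, 0.2)) {
    ss <- exp(runif(n_genes, log(s_range[1]), log(s_range[2])))
    do.call(rbind, lapply(seq_len(n_genes), function(i) {
      d <- r_nei_gene(200, kappa = kappas[i], s = ss[i], Ne = Ne, n = n)
      d$gene_id <- sprintf("G%03d", i)
      d
    }))
  }
  # null: identical kappa -> residuals centred at zero
  tab0 <- make_genes(60, rep(1, 60))
  est0 <- nei_decompose_genes(tab0, n = n)
  res0 <- ces_residuals(est0)
  r0 <- res0$residual[res0$in_fit]
  expect_equal(sum(r0), 0, tolerance = 1e-9)   # OLS identity
  expect_lt(abs(mean(r0)), 2 * sd(r0) / sqrt(length(r0)))

  # 5% of genes with kappa = 20 occupy the top decile of residuals
  hits <- replicate(10, {
    kap <- rep(1, 60); kap[1:3] <- 20
    tab <- make_genes(60, kap)
    est <- nei_decompose_genes(tab, n = n)
    res <- ces_residuals(est)
    ok <- res$in_fit
    thr <- quantile(res$residual[ok], 0.9)
    planted <- res$gene_id %in% sprintf("G%03d", 1:3)
    all(res$residual[planted & ok] >= thr)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("residual fit refuses degenerate inputs", {
  est <- data.frame(gene_id = letters[1:12], n_sites = 10,
                    kappa_over_s = 2, drift_term = c(rep(-1, 11), 5),
                    var_mu_term = 0, mean_k = 1, drift_nonpositive = FALSE)
  expect_error(ces_residuals(est), "at least 10")
})

test_that("rate-linearity regression estimates the proportionality constant", {
  set.seed(34)
  mu <- rlnorm(500, log(5), 0.6)
  k <- rpois(500, 3 * mu)
  f <- rate_linearity_regression(k, mu)
  expect_lt(abs(f$slope - 3), 2 * f$se_slope)
  expect_true(all(f$bins$n_sites >= 10))

  # constant mu collapses to a single bin with slope = mean(k) / mu
  k2 <- rpois(40, 6)
  f2 <- rate_linearity_regression(k2, rep(2, 40))
  expect_equal(nrow(f2$bins), 1L)
  expect_equal(f2$slope, mean(k2) / 2)
})

test_that("small rate bins merge into the next-highest bin", {
  # construct mu so that initial bins have sizes 4, 7, 25
  mu <- c(runif(4, 0, 1), runif(7, 1, 2), runif(25, 2, 3))
  k <- rpois(36, 2)
  f <- rate_linearity_regression(k, mu, breaks = c(0, 1, 2, 3))
  expect_equal(nrow(f$bins), 2L)
  expect_equal(f$bins$n_sites, c(11L, 25L))
})
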
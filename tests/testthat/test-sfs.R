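# simulation coefficients shared across SFS tests: rate slopes decline
# across allele-count bins; selection depletes every polymorphic bin roughly
# uniformly (about 50-fold at shet = 1)
sfs_beta_mu <- 0.05 * exp(-0.25 * (0:13))
sfs_beta_s <- 4 + 0.05 * (1:14)

test_that("allele counts bin deterministically with the fixed boundaries", {
  b <- bin_counts(c(0L, 1L, 10L, 11L, 15L, 16L, 35L, 36L, 99L, 100L, 250L))
  expect_equal(as.integer(b), c(1, 2, 11, 12, 12, 13, 14, 15, 15, 15, 15))
  expect_equal(attr(b, "n_above_top"), 2L)
  expect_error(bin_counts(-1L), "nonnegative")
})

test_that("neutral SFS coefficients are recovered from model simulations", {
  set.seed(51)
  mu <- runif(2e4, 1, 30)
  d <- gen_sfs_sites(mu, sfs_beta_mu)
  f <- fit_neutral_sfs(d$k, d$mu)
  # joint recovery on the full covariance (per-bin estimates share the
  # reference-bin count and are correlated)
  dev <- f$beta_mu - sfs_beta_mu
  expect_lt(drop(dev %*% solve(f$vcov, dev)), qchisq(0.999, 14))
})

test_that("degenerate neutral inputs are refused or flagged", {
  expect_error(fit_neutral_sfs(rpois(100, 1), rep(2, 100)),
               "unidentifiable")
  # all-monomorphic data drives coefficients to the lower bound
  expect_warning(
    f0 <- fit_neutral_sfs(rep(0L, 200), runif(200, 1, 5)),
    "bound"
  )
  expect_true(all(f0$at_bound))
  expect_gt(f0$loglik, -1e-3)  # P(K = 0) -> 1, loglik -> 0
})

test_that("selection coefficients are recovered with the neutral part fixed", {
  set.seed(52)
  shet_g <- runif(500, 0, 0.6)
  gene <- rep(seq_len(500), each = 40)
  mu2 <- runif(2e4, 1, 30)
  d <- gen_sfs_sites(mu2, sfs_beta_mu, sfs_beta_s, shet = shet_g[gene])
  neu_true <- structure(list(beta_mu = sfs_beta_mu),
                        class = "ces_sfs_neutral")
  fs <- fit_selection_sfs(d$k, d$mu, shet_g[gene], neu_true)
  dev <- fs$beta_s - sfs_beta_s
  expect_lt(drop(dev %*% solve(fs$vcov, dev)), qchisq(0.999, 14))
})

test_that("zero selection priors make the selection model unidentifiable", {
  set.seed(53)
  mu <- runif(500, 1, 30)
  neu <- fit_neutral_sfs(gen_sfs_sites(mu, sfs_beta_mu)$k, mu)
  d <- gen_sfs_sites(mu, sfs_beta_mu)
  fs <- fit_selection_sfs(d$k, d$mu, rep(0, 500), neu)
  expect_true(fs$unidentifiable)
  expect_equal(fs$beta_s, rep(0, 14))
})

test_that("square-root dependence separates shet rescaling from slope rescaling", {
  # two genes with shet 0.04 and 0.64: under sqrt the selection terms are
  # 0.2 * beta_s and 0.8 * beta_s; doubling shet while halving beta_s does
  # not reproduce both (sqrt is nonlinear), so the likelihoods differ
  set.seed(54)
  mu <- runif(4000, 5, 30)
  gene <- rep(1:2, each = 2000)
  shet <- c(0.04, 0.64)[gene]
  d <- gen_sfs_sites(mu, sfs_beta_mu, sfs_beta_s, shet = shet)
  neu <- structure(list(beta_mu = sfs_beta_mu), class = "ces_sfs_neutral")
  ll_true <- cesscan:::sfs_loglik_eta(
    d$bin, outer(mu, sfs_beta_mu) -
      sqrt(shet) * matrix(sfs_beta_s, 4000, 14, byrow = TRUE))
  ll_alt <- cesscan:::sfs_loglik_eta(
    d$bin, outer(mu, sfs_beta_mu) -
      sqrt(2 * shet) * matrix(sfs_beta_s / 2, 4000, 14, byrow = TRUE))
  expect_gt(ll_true - ll_alt, 10)
})

test_that("per-gene shet is re-estimated accurately from 50 high-rate sites", {
  set.seed(55)
  mu <- runif(2e4, 1, 30)
  neu <- fit_neutral_sfs(gen_sfs_sites(mu, sfs_beta_mu)$k, mu)
  shet_g <- runif(400, 0, 0.6)
  gene <- rep(seq_len(400), each = 40)
  mu2 <- runif(16000, 1, 30)
  dtr <- gen_sfs_sites(mu2, sfs_beta_mu, sfs_beta_s, shet = shet_g[gene])
  sel <- fit_selection_sfs(dtr$k, dtr$mu, shet_g[gene], neu)

  errs <- replicate(100, {
    mu3 <- runif(50, 15, 40)
    d3 <- gen_sfs_sites(mu3, sfs_beta_mu, sfs_beta_s, shet = 0.09)
    estimate_gene_shet(d3$k, d3$mu, neu, sel)$shet - 0.09
  })
  expect_lt(median(abs(errs)), 0.05)

  # hugely polymorphic gene pushes the estimate to the zero boundary
  d0 <- gen_sfs_sites(runif(50, 15, 40), sfs_beta_mu, sfs_beta_s,
                      shet = 0, kappa = 10)
  expect_lt(estimate_gene_shet(d0$k, d0$mu, neu, sel)$shet, 0.01)

  # estimates fall with total polymorphism on a rate-matched grid
  mu_fix <- rep(25, 50)
  shat <- sapply(c(0.02, 0.1, 0.3, 0.7), function(s) {
    mean(replicate(15, {
      d <- gen_sfs_sites(mu_fix, sfs_beta_mu, sfs_beta_s, shet = s)
      estimate_gene_shet(d$k, d$mu, neu, sel)$shet
    }))
  })
  expect_true(all(diff(shat) > 0))

  # CES-style rate inflation biases shet downward, increasingly with kappa
  mean_at_kappa <- sapply(c(1, 5, 15), function(kp) {
    mean(replicate(30, {
      d <- gen_sfs_sites(runif(50, 15, 40), sfs_beta_mu, sfs_beta_s,
                         shet = 0.2, kappa = kp)
      estimate_gene_shet(d$k, d$mu, neu, sel)$shet
    }))
  })
  expect_lt(mean_at_kappa[2], mean_at_kappa[1] - 0.05)
  expect_lte(mean_at_kappa[3], mean_at_kappa[2] + 0.01)

  expect_error(estimate_gene_shet(integer(0), numeric(0), neu, sel),
               "no sites")
})

test_that("multinomial probabilities sum to one at any parameter value", {
  set.seed(56)
  for (rep in 1:5) {
    eta <- matrix(rnorm(10 * 14, sd = 3), 10, 14)
    p <- cesscan:::sfs_probs_eta(eta)
    expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-12)
  }
})
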
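test_that("the ascertainment bound is the inverse prevalence", {
  a <- ascertainment_model(0.01)
  expect_equal(a$max_fold, 100)
  expect_gte(ascertainment_model(1)$max_fold, 1)
  expect_error(ascertainment_model(0), "in \\(0, 1\\]")
})

test_that("variant-level test has the right tails and Poisson limit", {
  a <- ascertainment_model(0.01)
  r0 <- gof_variant_test(0L, 0.002, a, gamma = 0.004, n_tests = 1e6)
  expect_equal(r0$p_value, 1)

  # gamma = 0 equals the exact Poisson upper tail; small gamma approaches it
  obs <- c(3L, 7L, 1L)
  expd <- c(0.01, 0.002, 0.05)
  pois <- ppois(obs - 1, expd * 100, lower.tail = FALSE)
  r <- gof_variant_test(obs, expd, a, gamma = 0, n_tests = 3)
  expect_equal(r$p_value, pois)
  r_small <- gof_variant_test(obs, expd, a, gamma = 1e-7, n_tests = 3)
  expect_equal(r_small$p_value, pois, tolerance = 1e-4)

  # independent oracle: explicit pmf summation of the Negative Binomial tail
  for (g in c(0.004, 0.5)) {
    for (ob in c(1L, 4L)) {
      for (mean0 in c(0.3, 2)) {
        r1 <- gof_variant_test(ob, mean0 / 100, a, gamma = g, n_tests = 1)
        kk <- 0:(ob - 1)
        size <- mean0 / g
        pmf <- exp(lgamma(kk + size) - lgamma(size) - lgamma(kk + 1) +
                     kk * log(g / (1 + g)) + size * log(1 / (1 + g)))
        expect_equal(r1$p_value, 1 - sum(pmf), tolerance = 1e-9)
      }
    }
  }
})

test_that("gene-level test flags only genes beyond the ascertainment bound", {
  a <- ascertainment_model(0.01)
  set.seed(21)
  lam <- rlnorm(2000, log(0.05), 0.5)
  # null genes at exactly the maximal ascertainment fold
  obs <- rpois(2000, lam * 100)
  # one gene at fold 150, beyond what ascertainment allows
  lam_hot <- 0.5
  obs_hot <- rpois(1, lam_hot * 150)
  r <- lof1_gene_test(c(obs, obs_hot), c(lam, lam_hot), a)
  # a central observation is never significant at genome scale
  mid <- lof1_gene_test(ceiling(5), 5 / 100, a, n_tests = 17791)
  expect_gt(mid$p_value * 17791, 1)
  expect_false(mid$bonferroni_significant)
})

test_that("LoF-2 selection applies both the FDR and the constraint threshold", {
  # boundary behaviour of the constraint filter
  sel <- lof2_select(observed = c(30L, 30L, 30L, 2L),
                     expected_gene = c(2, 2, 2, 2),
                     loeuf = c(0.4, 0.51, NA, 1.0),
                     unit = c("a", "b", "c", "d"))
  expect_false("a" %in% sel$selected)  # q < 0.1 but loeuf <= 0.5
  expect_true("b" %in% sel$selected)
  expect_equal(sel$n_missing_loeuf, 1L)
  expect_false("d" %in% sel$selected)  # no excess
})

test_that("BH q-values agree with the hand step-up computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  # independent step-up: q_i = min over j >= i of p_(j) * m / j
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(bh_fdr(p), pmin(q, 1))
})

test_that("Gamma-conjugate intervals bracket the ratio and approach Wald width", {
  e <- enrichment_with_ci(10, 10)
  expect_equal(e$ratio, 1)
  expect_lt(e$ci_low, 1)
  expect_gt(e$ci_high, 1)

  z <- enrichment_with_ci(0, 5)
  expect_equal(z$ci_low, 0)

  big <- enrichment_with_ci(1e4, 1e3)
  wald <- 2 * 1.96 * sqrt(1e4) / 1e3
  got <- big$ci_high - big$ci_low
  expect_lt(abs(got - wald) / wald, 0.05)
})

test_that("Gamma-conjugate intervals cover the Poisson mean near 95%", {
  set.seed(22)
  mu <- 7
  n_rep <- 2000
  x <- rpois(n_rep, mu)
  ci <- enrichment_with_ci(x, 1)
  cover <- mean(ci$ci_low <= mu & mu <= ci$ci_high)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("cohort comparison is symmetric under the null and matches enumeration", {
  r <- compare_cohorts(5L, 5L, 1, 1)
  expect_gte(r$p_sperm_excess, 0.5)
  expect_gte(r$p_trio_excess, 0.5)

  # enumeration oracle for small trials
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(1:15, 1); m <- sample(1:15, 1)
    lt <- runif(1, 0.5, 2); ls <- runif(1, 0.5, 2)
    r <- compare_cohorts(n, m, lt, ls)
    frac <- ls / (ls + lt)
    tot <- n + m
    kk <- 0:tot
    pmf <- choose(tot, kk) * frac^kk * (1 - frac)^(tot - kk)
    expect_equal(r$p_sperm_excess, sum(pmf[kk >= m]), tolerance = 1e-9)
    # trio count is tot - K, so P(trio >= n) = P(K <= tot - n)
    expect_equal(r$p_trio_excess, sum(pmf[kk <= tot - n]), tolerance = 1e-9)
  }

  # genes without events in both datasets are not tested
  r2 <- compare_cohorts(c(2L, 0L), c(1L, 3L), c(1, 1), c(1, 1))
  expect_equal(r2$tested, c(TRUE, FALSE))
  expect_true(is.na(r2$p_sperm_excess[2]))

  expect_error(compare_cohorts(1L, 1L, 0, 0), "zero")
})

test_that("transmission power is a valid size-controlled, monotone test", {
  # null: realized size does not exceed alpha
  for (n in c(5, 20, 60)) {
    for (al in c(0.05, 0.01)) {
      expect_lte(transmission_power(1, n, al), al)
    }
  }
  # monotone in kappa and in count
  g <- transmission_power_grid(c(1, 2, 5, 10, 25, 50), c(5, 20, 50), 0.05)
  for (nn in unique(g$n_variants)) {
    pw <- g$power[g$n_variants == nn]
    expect_true(all(diff(pw) >= -1e-12))
  }
  for (kp in unique(g$kappa)) {
    pw <- g$power[g$kappa == kp]
    expect_true(all(diff(pw) >= -1e-12))
  }
  # stricter levels never gain power
  p05 <- transmission_power(10, 20, 0.05)
  p01 <- transmission_power(10, 20, 0.01)
  p001 <- transmission_power(10, 20, 0.001)
  expect_gte(p05, p01)
  expect_gte(p01, p001)
  expect_error(transmission_power(0.5, 10), ">= 1")
})
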
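---
title: "Detecting clonal expansions in spermatogonia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clonal expansions in spermatogonia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesscan)
```

## The problem

Driver mutations that confer a proliferative advantage to spermatogonial
stem cells expand clonally within the testis. Unlike somatic clones, these
expansions are transmitted: the effective de novo mutation rate of the
driver allele in offspring is inflated by a factor we call kappa. In trio
cohorts ascertained for a disease, a second force also inflates observed
counts of de novo mutations — ascertainment itself. The central
identification device of this package is that ascertainment is *bounded*:
for a variant V and a disease D,

  observed / expected = P(D | V) / P(D) <= 1 / P(D),

so no amount of disease ascertainment can inflate a variant's recurrence
beyond the inverse of the disease prevalence. With a conservative
prevalence lower bound of 1% the cap is a 100-fold enrichment
(`ascertainment_model(0.01)$max_fold`). Genes exceeding the cap require a
mutational explanation, and clonal expansion in spermatogonia (CES) is the
established one.

## Mutational expectations

All tests compare observed counts with expectations from a per-site
baseline mutation-rate model consumed as an input column (an unscaled,
dimensionless rate `mu` per possible SNV). Cohort-level factors (parental
age distribution, coverage, calling stringency) are absorbed by anchoring
on synonymous variation: with NS observed synonymous de novo mutations and
S the admissible synonymous sites,

  lambda_v = NS * mu_v / sum_{v in S} mu_v,

and gene/class expectations are sums of site expectations
(`compute_expectations()`). Two invariants follow and are tested:
synonymous expectations sum exactly to NS, and all expectations are
invariant to rescaling every `mu` by a constant.

Sites enter only with a "high" or "TFBS" rate-model quality tier. Classes
are: LoF (high-confidence flag plus stop-gain or essential-splice
consequence), synonymous (synonymous-only consequence, no splice
involvement), and missense with a pathogenicity score strictly above 0.1.
Genes with overlapping coding sequence are reduced to the
maximum-total-CDS-length non-overlapping subset (`select_nonoverlapping_genes()`),
an exact maximum-weight independent set on the interval-overlap graph; for
a single overlapping pair this retains the longer gene. The tie-break
(lexicographically smallest gene-id set) is a reproducibility choice, not
biology.

## Controlling for rate-model error

If the baseline rate model were overdispersed at the single-site level,
hotspot tests would inherit false positives. `fit_gamma()` compares a
Poisson model of synonymous per-site counts against a Negative Binomial
with mean lambda_v and variance lambda_v (1 + gamma) — a Poisson-Gamma
mixture, so lambda/gamma need not be an integer — maximising over gamma in
[1e-8, 10] by golden-section search (the likelihood is unimodal on every
fixture we generated). The extra parameter is charged two log-likelihood
units (AIC), i.e. the Negative Binomial is preferred when the
log-likelihood gain exceeds 1. Downstream variant-level tests then use the
fitted gamma (default 0.004, the regime of interest for large trio
cohorts) rather than assuming Poisson noise.

One degenerate case deserves a note: with *all* counts zero, the Negative
Binomial likelihood is maximised at the *upper* gamma bound, because heavy
overdispersion mimics zero inflation — the likelihood gain reflects mean
misfit, not site-level dispersion, and there is no second-moment
information at all. `fit_gamma()` flags this input as degenerate and
reports the Poisson boundary.

Regionally correlated rate errors would not show at single sites, so
gene-aggregated synonymous counts are additionally tested with
chi2 = sum (n_g - lambda_g)^2 / lambda_g on (genes - 1) degrees of freedom
(`gene_level_chi2()`), the law-of-total-variance check: under Poisson
sampling Var(n) = E(lambda) + Var(lambda).

## Subcohort homogeneity

The ascertainment cap assumes phenotypically uniform recruitment across
the subcohorts of a composite cohort. `compare_homogeneity()` tests this
by AIC over four models of how each gene's LoF de novo events split across
subcohorts: (1) multinomial with probabilities fixed at the subcohorts'
synonymous-count shares (0 parameters), (2) free multinomial (C-1), (3)
Dirichlet-multinomial centred on the synonymous shares (1: the
concentration), (4) free Dirichlet-multinomial (C). Genes with no events
contribute zero log-likelihood and are retained. The concentration is
optimised on the log scale over [1e-3, 1e6]; because the
Dirichlet-multinomial approaches the multinomial from below as the
concentration grows, the multinomial limit is evaluated explicitly and
reported (concentration infinite) whenever it attains the supremum — this
keeps the nesting chain of log-likelihoods exact on every input, which the
tests assert.

A caveat established during design: AIC's probability of selecting the
true null multinomial is intrinsically about 0.80 (the chance that none of
the richer models gains its penalty is P(chi2_2 < 4) x P(boundary-chi2_1
mixture < 2) ~ 0.86 x 0.92), independent of sample size. In the sparse
regime of real per-gene LoF counts (mean well below one event per gene)
the concentration parameter sits at its boundary more often and the rate
rises to ~0.82-0.85; the acceptance test uses that regime.

## Candidate discovery

* **GoF (variant level)**: `gof_variant_test()` tests each missense site's
  recurrence against a null mean of lambda_v times the ascertainment cap,
  with Negative Binomial noise (gamma = 0.004). Bonferroni correction uses
  the full number of candidate missense variants; BH q-values are reported
  for the FDR view. We use the cohort-scaled lambda_v (not the raw rate)
  in the null mean so the variant-level and gene-level tests share one
  scale; a config switch exposes the raw-rate alternative.
* **LoF-1 (gene level)**: `lof1_gene_test()` is the exact Poisson
  upper-tail test of per-gene LoF counts against lambda_g times the cap,
  Bonferroni-corrected over tested genes; genes significant here exceed
  what any disease ascertainment can produce.
* **LoF-2**: `lof2_select()` drops the ascertainment scaling — any gene
  with a genuine excess over plain lambda_g at BH FDR < 0.1 qualifies —
  and then requires a LOEUF-like constraint score strictly above 0.5:
  a CES gene's apparently relaxed constraint is the *signature* of an
  under-modelled mutation rate, whereas disease-only genes are strongly
  constrained and fall below the cutoff.
* Enrichment ratios carry 95% Gamma-conjugate intervals under the Jeffreys
  prior Gamma(1/2, 0) (`enrichment_with_ci()`); the prior keeps the
  interval defined at zero counts (lower limit reported as 0) and matches
  Wald intervals asymptotically, with simulated coverage within 93-97%.
* **Trio vs sperm**: `compare_cohorts()` splits each gene's combined LoF
  count between the ascertained trio cohort and unascertained
  sperm-sequencing counts by an exact binomial test on the expected
  fraction, both one-sided directions reported. Sperm excess with trio
  deficit is the signature of embryonic deleteriousness.
* **Transmission power**: `transmission_power()` computes, by exact
  enumeration, the power of a one-sided binomial test of paternal origin
  against the baseline paternal fraction 0.75 when CES inflates the
  paternal rate, p(kappa) = 0.75 kappa / (0.75 kappa + 0.25) (odds
  scaling; the source analyses use 0.75 rather than the often-quoted 80%).
  Exact-test power is strictly monotone in kappa; in the number of
  variants it carries the usual sawtooth of exact tests — power can dip
  slightly exactly where the critical value increments and the attainable
  size drops — so "more variants help" holds only up to size jitter, and
  the tests assert precisely that.

## Population corroboration: the Gamma-Poisson decomposition

For strongly selected, recurrently mutated sites, allele frequencies are
approximately Gamma with shape 4 Ne mu and scale 1/(4 Ne s); sampled
counts k over n haploid genomes are then Gamma-Poisson with

  E(k) = kappa n E(mu) / s,
  Var(k) = kappa n E(mu)/s (1 + n/(4 Ne s)) + kappa^2 (n/s)^2 Var(mu).

(The third term is the squared-slope form Var_mu[E(k|mu)] =
(kappa n / s)^2 Var(mu); a linear-in-s rendering of the same term appears
in some statements of the decomposition but is inconsistent with its own
derivation, so the squared form is implemented.) Two moment estimators
follow (`nei_decompose()`): the rate-scaled mean kbar/(n mubar), equal to
kappa/s and hence the only term sensitive to CES; and the drift term
(Var(k) - slope^2 Var(mu) - kbar)/kbar, an estimate of n/(4 Ne s) that is
invariant to kappa. The slope is the through-origin Poisson-regression MLE
sum(k)/sum(mu). Across genes, ordinary least squares of log(kappa/s) on
log(drift) puts selection strength on the regression line and CES genes
above it (`ces_residuals()`); genes with nonpositive drift estimates
cannot enter the log fit and are returned flagged. Only sites with
unscaled rate above 1 (CpG-transition-like) in genes with at least 10 such
sites are used — the information lives almost entirely in high-rate sites.

Simulation regime: the recovery tests fix Ne = 1e4, s = 0.05, n = 1e6 and
200 sites per gene; the per-site scaled rate is drawn lognormal with
median 1e-5 so that the per-site Gamma shape 4 Ne mu is ~0.4. The model
depends on rate and population size only through the products 4 Ne mu and
4 Ne s, and this regime reproduces the information content of
biobank-scale catalogues (where the effective Ne relevant to rare
variation is much larger and per-site rates much smaller); at shapes below
~0.05 a 200-site gene carries only 2-3 effective frequency draws and the
variance decomposition becomes median-biased by 30-40%, which no estimator
choice repairs. The near-neutral regime (s -> 0) breaks the Gamma
approximation in the direction of *extra* variance, i.e. negative
residuals: neutral genes cannot mimic CES, which keeps the procedure
conservative.

`rate_linearity_regression()` provides the per-gene visual check that
allele counts are proportional to the baseline rate (shared linear
inflation), binning sites by rate and merging bins under 10 sites into the
next-highest bin (a deficient top bin merges downward).

## SFS-based selection estimates

The site-frequency-spectrum model bins allele counts at fixed boundaries
[0, 1, ..., 11, 16, 24, 36, 100] (k = 0 is the multinomial reference; the
rare k >= 100 sites join the top bin and are tallied). The neutral model
puts log-odds of bin i versus the monomorphic bin linear in the rate,
beta_mu_i * mu, with no intercept; the selection model subtracts
beta_s_i * sqrt(shet). The square-root link is what makes genes with
different prior selection separable; beta_s is shared across rate bins.
Both fits are multinomial-logit maximum likelihood (concave; bounded
quasi-Newton with analytic gradients, coefficients bounded at +/-50 so
empty bins pin at the bound with a warning rather than diverging). Rank
deficiency (a single rate value) is refused. Per-gene shet is then a 1-d
bounded MLE on [0, 1] with multi-start {0.01, 0.1, 0.5}
(`estimate_gene_shet()`).

The CES signature here is *bias*: a hidden rate inflation makes a gene
look more polymorphic than its covariate warrants, dragging the shet
estimate below truth, increasingly with kappa. Simulation coefficients for
the tests (beta_mu_i = 0.05 e^{-0.25(i-1)}, beta_s_i = 4 + 0.05 i, i.e.
~50-fold depletion of polymorphism at shet = 1) were chosen once for
plausibility; note that a strongly bin-increasing selection profile
combined with bin-decreasing rate slopes can invert the bias direction, so
the near-uniform depletion profile is also the structurally realistic
choice. Because per-bin estimates are correlated through the shared
reference-bin count, recovery is asserted jointly (Mahalanobis distance
against the observed-information covariance), not coefficient-by-
coefficient.

## The synthetic-data generator

`synthetic_config()` + `gen_sites()` / `gen_denovo_cohort()` /
`gen_population_afs()` / `gen_sperm_counts()` emulate the statistical
structure every stage assumes: heavy-tailed per-site rates with a
CpG-like high-rate component (default 8% of sites, lognormal around 20
versus a body around 0.5); de novo counts as explicit Gamma-then-Poisson
mixtures (exactly the Negative Binomial parametrisation used in fitting);
per-gene CES inflation kappa and ascertainment folds capped at the inverse
prevalence by validation; multinomial or Dirichlet-multinomial subcohort
allocation (defaults mirror three subcohorts with synonymous shares
0.32/0.60/0.08); Gamma-Poisson population allele counts (clamped at n with
a tally; settings implying E(q) > 0.1 are refused as outside the
strong-selection regime); and Poisson sperm-sequencing counts that carry
kappa but no ascertainment and no embryonic-lethality deflation.
Inflation applies to functional classes only — synonymous sites stay at
baseline, which is what preserves the synonymous normalisation anchor. A
single master seed expands into fixed per-generator child seeds, so every
table is byte-reproducible and modules do not perturb each other's
streams.

What the generator does *not* emulate: sequence context (rates are
abstract positives), demography and population structure, linked
selection, X/Y chromosomes, indels, and annotation error. Passing tests
therefore validate the statistical machinery under its stated model, not
robustness to those real-data features.

## Problem sizes and numerical choices

The test suite uses: 1e5 sites for overdispersion recovery (100 replicates
of 2e4 for the AIC calibration), 500 replicates of 150 genes for the
chi-squared calibration, 100 replicates of 2000-gene sparse matrices per
homogeneity scenario, 200 random instances (up to 15 genes) against the
exhaustive subset oracle, 100-200 genes of 200 sites for the Gamma-Poisson
recovery and residual injections, 1e5/2.5e4 sites for the SFS fits, and 20
seeds of a 1030-gene planted study (10 CES genes at kappa = 17, 20
ascertainment-only disease genes at fold 60, nulls elsewhere) for
end-to-end discrimination. These sizes were chosen so each property is
measured with comfortable Monte-Carlo margin while the whole suite stays
quick on a single CPU.

Numerical notes: log-factorials always via log-gamma; Negative Binomial
tails via the regularised incomplete beta (through `pnbinom`), with the
gamma = 0 boundary dispatched to the exact Poisson tail (float noise in
`dnbinom` at size ~1e9 caps the achievable agreement near 1e-6, so
nesting checks probe gamma = 1e-8); the multinomial-logit likelihoods use
row-wise log-sum-exp; OLS residuals sum to zero by construction and the
tests use that identity as a tripwire.

## Known limitations

* The ascertainment cap is an inequality; the tests detect only effects
  exceeding it (or, for LoF-2, rely on the constraint filter). CES with
  kappa below the cap and strong constraint is invisible here.
* AIC model selection carries its intrinsic ~14% overfit rate for two
  extra parameters; homogeneity conclusions are accordingly probabilistic.
* The Gamma-Poisson decomposition needs high-rate sites; genes with few
  CpG-like sites are excluded by design and remain unassessed.
* Per-gene shet estimates inherit any misfit of the global SFS
  coefficients; they are corroborating evidence, not stand-alone selection
  estimates.
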
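# cesscan

Detecting clonal expansions in spermatogonia (CES) from hotspots of human
de novo mutation.

## The problem

Driver mutations that give spermatogonial stem cells a proliferative
advantage expand clonally in the testis and — unlike somatic clones — are
transmitted to offspring, inflating the effective de novo mutation rate of
the driver allele by a factor κ. In disease-ascertained trio cohorts a
second force inflates observed de novo counts: ascertainment itself. The
package is built around the fact that ascertainment is bounded,

```
obs / exp = P(D | V) / P(D) ≤ 1 / P(D),
```

so with a conservative disease-prevalence lower bound P*(D) = 0.01 no
variant can be enriched more than 100-fold by ascertainment alone. Genes
and variants that exceed the cap need a mutational explanation — CES.
Candidates below the cap are corroborated through population variation:
a CES gene looks *weakly constrained* (high LOEUF) because its mutation
rate is under-modelled, its allele counts stay linear in the baseline rate,
the Gamma-Poisson (Nei) decomposition of allele-count mean and variance
shows an elevated rate-scaled mean at unchanged drift variance, and
SFS-based selection estimates are dragged below their priors.

The package implements, as tested R functions behind a numbered analysis
workflow:

* synonymous-normalised mutational expectations
  (λ_v = NS·μ_v / Σ_S μ_v) with maximal non-overlapping gene selection
  and three-way variant classification;
* Poisson vs Negative Binomial overdispersion control for the rate model
  (single-site γ̂ by bounded MLE, gene-level χ² test);
* four-model Multinomial / Dirichlet-Multinomial AIC comparison of
  subcohort sampling homogeneity;
* the GoF (variant-level Negative Binomial), LoF-1 (gene-level Poisson vs
  the ascertainment cap) and LoF-2 (plain-expectation FDR + constraint
  filter) candidate tests, Gamma-conjugate enrichment intervals, exact
  trio-vs-sperm binomial comparison, and enumeration-exact
  paternal-transmission power;
* the Gamma-Poisson mutation–selection–drift decomposition with per-gene
  CES residuals and the rate-linearity regression;
* a data-driven multinomial SFS model (fixed allele-count bins, log-odds
  linear in μ minus β_s·√s_het) with per-gene bounded s_het re-estimation;
* a seed-deterministic synthetic-data generator for all of the above, so
  the entire pipeline is testable without external data.

## Worked example

```r
library(cesscan)

ascertainment_model(0.01)
#> Ascertainment bound: prevalence >= 0.01 => max fold = 100

# a recurrent missense site: 15 de novo events at expectation 0.004 --
# 3750-fold, far beyond the 100-fold cap even after correcting for
# ~5e7 candidate missense sites
r <- gof_variant_test(observed = 15L, expected = 0.004,
                      ascertainment_model(0.01), gamma = 0.004,
                      n_tests = 49686008)
r$p_value                  #> 1.46e-18
r$bonferroni_significant   #> TRUE

# a gene with 42 LoF de novo events at expectation 2.5 (16.8-fold)
enrichment_with_ci(observed = 42, expected = 2.5)
#>   ratio ci_low ci_high
#> 1  16.8  12.28   22.48

# power of the paternal-overtransmission follow-up at kappa = 17
transmission_power(kappa = 17, n_variants = 50, alpha = 0.05)
#> 1
```

The full synthetic study lives in `analysis/`:

```sh
Rscript analysis/01_simulate.R      # planted CES + disease + null genes
Rscript analysis/02_expectation.R   # gene selection, classes, lambda
Rscript analysis/03_dispersion.R    # gamma-hat, gene-level chi-squared
Rscript analysis/04_homogeneity.R   # four-model AIC comparison
Rscript analysis/05_discovery.R     # GoF / LoF-1 / LoF-2, CIs, power grid
Rscript analysis/06_popgen_nei.R    # Nei decomposition, CES residuals
Rscript analysis/07_sfs_shet.R      # SFS fits, per-gene shet
Rscript analysis/08_sperm_comparison.R
```

Each script prints what it found and writes its tables under `results/`.
On the default simulated study (seed fixed in `01_simulate.R`: 400 genes,
10 CES genes at κ = 17 with 30-fold ascertainment, 20 disease genes at
60-fold ascertainment) the workflow retains 360 non-overlapping genes,
anchors on NS = 5358 synonymous events, finds no rate-model
overdispersion (γ̂ ≈ 0.001, ΔlogL ≈ 0.01; gene-level χ² p = 0.21), prefers
the uniform-sampling model m1, flags 8 of the 10 CES genes in LoF-1 while
excluding all ascertainment-only disease genes, recovers the CES genes in
LoF-2 (~518-fold pooled enrichment, 95% CI 512–525), and places the CES
genes in the top decile of Nei residuals with shet estimates collapsed
toward 0 for κ-inflated genes.

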
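---
title: "Benchmarking differential-abundance methods: models, metrics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential-abundance methods: models, metrics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dabench)
```

## The problem

Differential-abundance (DA) analysis asks which taxa differ systematically
between groups of microbiome samples. Count matrices from 16S or shotgun
sequencing are sparse (many exact zeros), overdispersed (variance far above
the mean), compositional (sequencing depth is arbitrary), and no DA method is
uniformly best across datasets. `dabench` does not pick a winner in the
abstract; it measures, on a given count table, how each candidate method
behaves along four axes — distributional fit, type-I-error control,
self- and cross-concordance, and agreement with prior knowledge — so the
choice is driven by the data at hand.

All engines consume the same minimal contract: a per-feature raw p-value, a
test statistic, a direction sign (+1 = over-abundant in the second group
level), and Benjamini–Hochberg adjusted p-values computed over the
non-missing entries. Missing p-values mark per-feature method failures; they
are excluded from adjustment and from every downstream rate (treating
failures as "not significant" would bias false-positive rates downward), and
their count is reported per method.

## Goodness of fit

Five models are fitted per feature (marginally — intercept-only, no
covariates, because the question is whether the *distribution* is captured,
not a regression):

* **NB**: mean `mu`, dispersion `phi` with `Var = mu + phi mu^2`;
  `P0 = (1 + phi mu)^(-1/phi)`, continuously extended to the Poisson
  `exp(-mu)` below `phi = 1e-8`. The ML mean is the sample mean for any
  dispersion, so only `phi` is profiled (1-d optimization of the exact
  log-likelihood on the log scale, floor `1e-10`, ceiling `1e4`; the Poisson
  boundary is checked explicitly since underdispersed features push the
  optimum to the floor).
* **ZINB**: mixture `pi0 δ0 + (1 - pi0) NB(mu, phi)`, fitted by EM. The two
  M-sub-steps (weighted mean for `mu`, 1-d profile for `phi`) are exact
  conditional maximizations, so the observed-data likelihood is monotone —
  a property the test suite asserts on traced runs. `EY = (1 - pi0) mu`,
  `P0 = pi0 + (1 - pi0)(1 + phi mu)^(-1/phi)`. Features without observed
  zeros collapse to the NB fit with `pi0 = 0`; all-zero features return
  `pi0 = 1, P0 = 1` by convention.
* **ZIG**: on `z = log2(count + 1)`, a point mass at zero mixed with a
  Gaussian, fitted by EM in which the point mass competes with the Gaussian
  density at `z = 0`. A continuous model needs an explicit zero event: we
  call "zero on the count scale" any back-transformed value below 0.5, i.e.
  `z < log2(1.5)`, so `P0 = pi0 + (1 - pi0) Phi((log2 1.5 - mu)/sigma)`.
  `EY` is the lognormal back-transform `(1 - pi0)(2^(mu + sigma^2 ln2/2) - 1)`
  floored at 0. When the positive values are (near-)constant the mixed
  likelihood is unbounded in `sigma`; we return the point-mass solution
  (`pi0` = observed zero fraction) in that degenerate case.
* **Hurdle (truncated Gaussian)**: the zero mass *is* the observed zero
  fraction, and a Gaussian is fitted to `log2(count + 1)` of the positive
  counts only. Its zero-probability error is therefore identically 0 — a
  useful structural baseline: any model's `RMSE_ZPD` can be read relative to
  a model that spends a parameter on matching zeros exactly.
* **Dirichlet-multinomial**: one joint concentration vector `alpha` across
  features, estimated by the classical digamma fixed-point iteration on the
  ML score equations. `EY_i = mean_j(N_j) alpha_i / alpha0` and `P0_i` is the
  mean beta-binomial zero mass across samples, evaluated via log-gamma. The
  fixed point converges slowly near the multinomial boundary (`alpha0` large);
  the iteration cap is exposed (`max_iter`) and non-convergence is flagged on
  all features with a warning rather than hidden.

Fit quality per feature: `MD = log(EY + 1) - log(observed mean + 1)` (the
pseudocount-1 log scale treats zero means symmetrically) and
`ZPD = P0 - observed zero fraction`. Models are ranked by `RMSE_ZPD`, then
`RMSE_MD`, computed over converged features only, with the convergence
fraction reported alongside — a model that "wins" by failing on hard
features is visible as such.

## Type-I-error control on mocks

All samples are relabeled into two balanced groups (sizes differ by at most
one), N times; nothing is truly DA, so every discovery is false. Per method
we report: the false positive rate `P(p_raw < alpha)` at
`alpha ∈ {0.01, 0.05, 0.1}`; the per-mock Kolmogorov–Smirnov distance
`sup_x |ECDF(p) - x|` of raw p-values from Uniform(0,1), averaged over mocks
(the pooled-ECDF variant is deliberately not the default: averaging
preserves per-mock granularity); and two readings of a "false discovery
rate" in a world with no true signal — the mean fraction of features passing
adjusted-p thresholds, and the fraction of mocks with at least one
discovery. Both readings are cheap and answer different questions (how much
is discovered vs how often anything is).

A granularity caveat the test suite makes explicit: with m p-values per mock
the mean KS of *perfectly uniform continuous* p is already about
`0.87/sqrt(m)` (≈ 0.087 at m = 100), and exact rank tests on 10-vs-10 mocks
add ≈ 0.017 of unavoidable discreteness. Mean-KS values near 0.10 on small
designs therefore indicate p-value granularity, not miscalibration — the FPR
columns are the calibration readout; KS separates shape distortions (such as
the anti-conservative `p^2` fixture used in the tests, whose
FPR(0.05) → √0.05 ≈ 0.224) from granularity.

Seeding: one master seed; mock i draws from a derived child stream, so any
subset of mocks is reproducible without re-running the rest.

## Concordance

Each of N splits halves the samples within every group level (each level
needs ≥ 4 samples so both halves keep ≥ 2). Rankings are by ascending raw
p-value — adjustment is monotone per method and cannot change ranks — with
ties broken by descending |statistic|, then feature id; missing p-values
rank last. Agreement between two rankings is the concordance-at-top curve
`CAT(k) = |top_k(A) ∩ top_k(B)|/k`, summarized by a rescaled area over
`k = 1..K`:

    RA = (mean_k CAT(k) - mean_k k/m) / (1 - mean_k k/m)

`mean_k k/m` is the exact expectation for independent rankings
(hypergeometric overlap), so RA = 1 for identical rankings and ≈ 0 for
independent ones — both limits are asserted in the tests. K defaults to
`min(m, 100)`: deep enough to be informative on typical microbiome feature
counts, bounded so curves are comparable across datasets. WMC averages RA
between the two halves for one method; BMC averages RA between two methods
on the same half, over both halves — the matrix is symmetric with unit
diagonal by construction.

## Enrichment, TP − FP ranking, and power

Prior knowledge enters as a per-feature annotation level plus a map from
level to expected direction (e.g. aerobic taxa expected over-abundant in the
supplemented group). At an adjusted-p threshold (default 0.1 — putative
calls, deliberately lenient; configurable) each feature is classified
UP/DOWN/NONDA, and for every level a 2×2 table (in-level × called in the
expected direction) is built over annotated features; the same table in the
*opposite* direction is emitted as a negative control. Fisher's exact test
(default one-sided "greater", since enrichment is a one-sided question; the
two-sided mass-based variant is available) is computed by hypergeometric
enumeration, matched in the tests against an independent log-binomial
enumeration oracle on every 2×2 table with total ≤ 30.

The TP − FP curve ranks features by p-value (or |statistic|) and counts, at
each depth, features whose direction matches the expected/true direction
(TP) against those contradicting it (FP). Features with no expected
direction — unannotated ones, and non-DA features of a simulated truth —
count toward neither: they dilute neither metric while keeping curves
comparable across methods. Power analysis runs methods on simulated
scenarios with known truth; a discovery is a true positive only if the
feature is truly DA *and* called in the true direction, power is TP over the
number of true DA features, and the observed FDR is FP over discoveries.

## The synthetic generator

`sim_scenario()` states the simulated world once: per-feature baseline log
means uniform on `log(2)..log(100)` (spanning rare to dominant taxa),
NB dispersion 0.5 (strong but realistic overdispersion), 100 features,
20 samples per group, 10% DA features at fold change 3 split evenly between
directions, and per-sample library factors uniform on 0.5–2 (4-fold depth
variation). ZINB adds dropout zeros at `pi0 = 0.3`; the DM model draws
per-sample compositions from a Dirichlet at depth `10^4 × library factor`.
DA spike-ins multiply group-2 means by the fold change (UP) or its inverse
(DOWN); an optional compositional mode renormalizes per-sample expected
totals so spike-ins perturb composition instead of total abundance — the two
regimes stress DA methods differently and the flag makes the choice
explicit. The number of DA features is exactly `round(frac_da * m)`
(round-half-to-even, for determinism), recorded in a truth set together with
directions and fold changes. Every generator is a pure function of its
scenario including the seed.

What the generator does *not* emulate: phylogenetic correlation between
features, real-data mean–dispersion trends, batch structure, or
template-based resampling of a real dataset. A green calibration or power
test therefore establishes behavior under independent-feature, homogeneous
noise — necessary, not sufficient, for performance on real data.

`sim_annotation()` derives a noise-free prior from the truth (levels
`expectedUP`/`expectedDOWN`) and flips exactly `round(noise × annotated)`
labels for robustness experiments.

## Native methods and their numerical conventions

* **Wilcoxon rank-sum** on normalized abundances: exact tail (`pwilcox`)
  when tie-free and both groups < 50, otherwise normal approximation with
  tie correction and continuity correction — deliberately the classical
  recipe, so the generic implementation in base R can serve as a test
  oracle. Statistic: centred Mann–Whitney; direction: sign of the median
  difference; features constant across all samples yield a missing p.
* **CLR t-test**: Welch t per feature on centred log-ratios. With
  `mc_samples = W > 0`, W Dirichlet instances per sample (concentration
  `counts + 0.5`, a Jeffreys-like prior) are CLR-transformed and tested, and
  per-feature p-values are averaged over instances. Averaging shrinks small
  p-values upward, so the Monte-Carlo variant is *conservative by
  construction* — its null FPR sits below the nominal level (the tests
  assert validity, monotonicity in alpha, and non-degeneracy rather than
  exact calibration), which mirrors the published behavior of the method
  family it represents.
* **NB-Wald regression**: per feature, log-link NB with intercept + group
  coefficient and offset `log(scale_j)`, dispersion estimated jointly by ML
  (BFGS with analytic gradients, relative tolerance 1e-10), two-sided normal
  Wald p on the group coefficient. Non-convergence, singular Hessians and
  all-zero features yield missing p-values rather than fabricated ones.
  Because the optimizer's start depends on the group coding, label-swap
  symmetry holds to ≈ 1e-3 in p rather than exactly; the rank and t tests
  are exactly symmetric.

Normalization factors: TSS factors are library sizes (counts/factor are
proportions); TMM follows the published trimmed-mean recipe exactly
(trims 0.30/0.05, precision weights, reference = sample whose
upper-quartile/library-size ratio is closest to the mean) so the edgeR
implementation can be matched to 1e-9 as an oracle; RLE medians raw
count/reference ratios (note: median on the raw-ratio scale, which differs
from log-scale medians when the usable feature count is even); CSS sums
counts up to a fixed quantile (default 0.5) of the positive counts — the
adaptive quantile search of the original method is intentionally out of
scope (deterministic and testable beats adaptive here). TMM/RLE factors are
rescaled to geometric mean 1 and are *relative*; where an absolute scale is
needed (offsets, abundance scaling) they are multiplied by library size.
Only relative differences between samples affect two-group tests.

## Known limitations

* Two-group designs only; no covariates, pairing, or longitudinal structure.
* The twelve wrapped Bioconductor DA tools of the ecosystem this framework
  models are represented by the plugin contract plus three natives, not
  wrapped.
* No tree-aware analysis, no rarefaction, no template-based simulation.
* Plot generation is out of scope: every engine emits tidy tables meant for
  external plotting.
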
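---
title: "Temporal selection scans with driftscan: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal selection scans with driftscan: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftscan)
```

## The question the test answers

Given allele counts observed at the same SNP at two or more time points in
one closed population, is the frequency change better explained by genetic
drift plus selection than by drift alone? In populations with an effective
size of a few tens of individuals, drift moves frequencies by several percent
per generation, so a credible test must carry the effective size `Ne` inside
the null model rather than treat large changes as automatically surprising.
That is what the hidden Wright–Fisher likelihood here does, population by
population.

## Model and assumptions

The hidden state is the population count of the focal allele,
`X_t ∈ {0, ..., 2Ne}` (diploid chromosomes). One generation advances the
chain by

\[
X_{t+1} \mid X_t \sim \mathrm{Binomial}\!\left(2N_e,\;
  \frac{p_t(1+s)}{1 + p_t s}\right), \qquad p_t = X_t / 2N_e ,
\]

i.e. deterministic genic selection followed by binomial resampling. The
assumptions this encodes:

* **Genic (haploid-equivalent) selection.** One parameter `s`, no dominance.
  This is the standard single-parameter choice for temporal likelihood tests;
  with samples this small, dominance is not identifiable anyway.
* **Constant `Ne` and constant `s`** across the sampled interval.
* **Closed population**: no migration or mutation between events.
* **Binomial sampling of chromosomes** at each event: `k_t ~ Binomial(n_t,
  p_t)` with `n_t` twice the number of genotyped individuals. Binomial rather
  than hypergeometric sampling keeps the emission well defined even when
  `n_t` approaches or exceeds `2Ne`, which happens routinely here.
* **Discrete generations** mapped from calendar years: an event
  `y` years after the first sits `floor(y / generation_time)` complete
  generations later (default generation time 2 years). Events that pool
  adjacent collection years use the earliest year.

## The initial condition

The likelihood must say where the hidden chain starts. `driftscan` supports
two choices (argument `init` of `wf_loglik()`, `wf_lrt()`,
`scan_population()`, `power_experiment()`):

* `"first_sample"` (default): the hidden count at the first event is fixed at
  the rounded first-sample frequency, and the likelihood is that of the later
  samples given this baseline. The first sample defines *where the population
  starts*; the test measures the evidence in the subsequent change.
* `"uniform"`: a uniform prior over the hidden count, with the first sample
  treated as one more noisy observation.

This was a genuinely open design point. We made conditioning the default for
two reasons. Mechanistically, the uniform-prior variant spends part of the
likelihood explaining the first observation and absorbs part of the observed
frequency change into initial-state uncertainty shared by both hypotheses,
which blunts the contrast the test is after. Empirically, the conditioned
test's operating characteristics under the Freycinet-like benchmark design
(measured by `power_experiment()` and the acceptance script, see below) match
the operating characteristics this class of methods is reported to achieve
on such designs, while the uniform-prior variant is distinctly less
powerful. The trade-off is honesty about calibration: conditioning discards
the first-sample noise, which makes the chi-square reference slightly
anticonservative at small `Ne` (measured false-positive rate around 2%
at nominal 1% in the benchmark design), whereas the uniform-prior variant is
calibrated to within Monte-Carlo error (a property the test suite checks).
Users who prioritise exact tail calibration can either set
`init = "uniform"` or use the parametric-bootstrap p-value
(`wf_null_pvalue()`), which is calibrated by construction under either
initial condition.

A conditioned baseline can be degenerate: if the first-sample frequency
rounds to 0 or `2Ne` but later samples show the allele (re)appearing, the
data are impossible under *every* `s`, including the null. Such SNPs carry no
likelihood contrast and are reported with `lrt = 0`, `pvalue = 1`.

## Test statistic and reference distribution

`wf_mle()` maximises the log-likelihood over a fixed grid of coefficients,

```
-0.9, -0.8, ..., -0.1, -0.05, 0, 0.05, 0.1, ..., 0.9, 1, 1.25, 1.5, 2, 3, 5
```

two-sided (allele frequency may move either way) and stretching to very
strong selection, since `s` of order 1 is plausible under an epizootic with
near-total mortality. Ties in the likelihood are broken toward the smallest
`|s|`, so flat likelihoods (e.g. zero elapsed generations) report
neutrality. The LRT statistic `2(logL1 − logL0)` is clipped at zero and
referred to a chi-square with one degree of freedom. At these population and
sample sizes the statistic is discrete and the asymptotic reference is an
approximation; the test suite quantifies how it behaves at the tails, and
`wf_null_pvalue()` provides the simulation-based alternative
(add-one-smoothed, conditional on the observed baseline).

## Numerical choices

* The forward pass is scaled per event (probabilities renormalised, log-mass
  accumulated), so underflow cannot occur over any realistic number of
  events.
* Between-event transition matrices `M^g` are precomputed once per grid
  point and design and shared across all SNPs of a scan; the per-SNP cost is
  a handful of vector-matrix products on a `(2Ne+1)`-state space.
* Transition rows at the absorbing states 0 and `2Ne` are exact unit
  vectors; every row of every transition matrix sums to 1 to 1e-12 (tested).
* `p.adjust(method = "BH")` supplies the FDR step; p-values of exactly 1
  (monomorphic or degenerate SNPs) take part in the adjustment like any
  other value.

## Filtering protocol

`run_filters()` applies, in order: (i) minor allele frequency over the whole
panel — SNPs with MAF *strictly below* 0.01 removed (a MAF of exactly 0.01
survives); (ii) observed heterozygosity over the whole panel — SNPs
*strictly above* 0.5 removed (exactly 0.5 survives); (iii) missingness —
call rate at least 1/3 overall and within every sampling event, except that
the two smallest events (fewest individuals, ties broken by earlier year)
require at least 1/2, the stricter rule *replacing* the 1/3 rule there; (iv)
LD pruning — within each scaffold, pairs at most 20 SNPs apart in map order
and at most 50 kb apart with genotype-dosage `R² > 0.99` in *any* sampling
event lose their right-hand member, in a deterministic left-to-right sweep.
Dosage correlations use pairwise-complete observations; zero-variance SNPs
cannot trigger a pair. "Sample" means sampling event throughout — the
sampling event is the unit in which temporal information is organised — not
population, which matters only when a panel mixes populations.

Removals are attributed to exactly one step in the telescoping
`filter_report`, and the protocol is idempotent (tested).

## Region calling and annotation

A SNP with `p < 1e-4` seeds a signature on its own; two SNPs *adjacent in
the filtered SNP order* on one scaffold, both with `p < 0.01`, seed one
together. Adjacency is positional order after filtering with no base-pair
cap — on sparse RAD maps a base-pair cap would make the pair rule
unusable — and interleaving by a non-significant SNP breaks a pair. Seeded
SNPs within 100 kb of each other on one scaffold merge into one signature
spanning the member positions; 100 kb matches the scale of the annotation
window, and a merged signature reports `single_p1` if any member passed the
single-SNP rule. Genes are attached when the gene–signature interval
distance is strictly below 100 kb (0 when overlapping), optionally
restricted to genes flagged with a human orthologue.

One caveat on monotonicity: tightening `p1`/`p2` can only shrink the set of
member SNPs (tested), but the *number* of signatures is not strictly
monotone — removing a middle seed can split one merged region into two.

## What the generator simulates — and what it does not

`simulate_panel()` draws, per SNP, an initial frequency from `p0_law`
(default Uniform(0.1, 0.9)), a Wright–Fisher trajectory (neutral or at the
planted `s`), binomial samples at each event, and diploid genotypes by random
pairing of sampled chromosomes (Hardy–Weinberg within samples). Missing
genotypes are masked independently at `missing_rate`; local LD is injected
by verbatim column copies within blocks of `ld_block_size` consecutive SNPs,
which guarantees `R² = 1` pre-masking and so exercises the pruning rule
deterministically.

What real data have that this generator does not: site-frequency spectra
skewed toward rare alleles (the uniform law over-represents intermediate
frequencies), partial rather than perfect LD with distance-dependent decay,
non-random missingness (RAD allele dropout correlates with genotype),
population structure and migration, and linked selection (draft). Passing
tests on generated panels therefore validate the machinery and its
operating characteristics under the model's own assumptions; they do not
certify behaviour under model misspecification on real data.

## Benchmark design and problem sizes

The recurring benchmark in tests and in `scripts/acceptance.R` is the
Freycinet-like design: `Ne = 34`, samples of 29 and 20 diploids six
generations apart, initial frequency Uniform(0.1, 0.9), per-SNP
`alpha = 0.01`. `power_experiment()` runs 1000 replicates per arm there —
enough for a standard error of about 1.6 percentage points on power and
0.4 on the false-positive rate. Unit tests use 400–2000 replicates for
distributional checks and panels of 60–1000 SNPs end to end; the exhaustive
path-enumeration oracle runs at `Ne ≤ 3` and up to three events, where full
enumeration is exact and instant. These sizes are the package's own choice
of Monte-Carlo resolution; all stochastic entry points take explicit seeds
and reproduce bit-identically under the same seed.

## Known limitations

* `Ne` is an input, not an estimate; misspecifying it shifts power (drift
  explains more or less of the change) though it barely moves the
  false-positive rate. Use externally estimated contemporary `Ne`.
* Constant `s`, no dominance, no time-varying selection; the estimate `ŝ`
  is a grid point and inherits the grid's resolution, and at strong true
  selection `ŝ` has a heavy right tail (near-fixation replicates land on
  the large-`s` grid points), so its median is the more stable summary.
* The chi-square reference is approximate at tiny `Ne` (see above); the
  bootstrap p-value is the rigorous but slower route.
* The pair rule depends on SNP density: on sparse maps (as in the West
  Pencil Pine-like setting) neighbouring SNPs can be megabases apart, and a
  pair signature then spans a wide, weakly localised interval.
* Pooling collection years into one event discards sub-generation timing;
  with a 2-year generation time this is at most half a generation of blur.
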
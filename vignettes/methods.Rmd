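---
title: "Estimating clonotype richness: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating clonotype richness: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonodiv)
```

## The problem

A person's T-cell receptor repertoire contains vastly more clonotypes than
any blood sample can reveal: the frequency distribution is heavily skewed,
so a sample of even $10^5$–$10^6$ cells observes the abundant clones many
times over while missing most of the rare ones. Estimating the *species
richness* of the repertoire — the number of distinct clonotypes — from one
sample is the unseen-species problem of ecology transplanted into
immunology, with one welcome simplification and one complication. The
simplification: T cells in blood are well mixed, so every cell has the same
detection probability, which is rarely true of animals in the field. The
complication: sequencing pipelines interpose PCR amplification between the
cells and the data, so *read* counts are not *cell* counts, and the degree
of repetition in the data — the very signal richness estimators rely on —
can be badly inflated.

The package therefore works from **absolute per-species counts**
(`abundance_vector`), treats incidence (presence/absence across replicates)
as a separate input type (`incidence_data`), and includes a simulator of the
PCR distortion so the failure mode can be studied rather than suffered.

## Classical estimators

All of the classical estimators correct `S_obs` upward using the rare tail
of the frequency-of-frequencies `f_k` (number of species seen exactly $k$
times):

* **Chao1**: $S_{obs} + f_1^2/(2 f_2)$; when $f_2 = 0$ (common in small
  subsamples of skewed data) the standard degenerate form
  $S_{obs} + f_1(f_1-1)/2$ is used rather than failing.
* **Chao1-bc**: $S_{obs} + f_1(f_1-1)/(2(f_2+1))$, never above Chao1.
* **ACE**: coverage of the rare group ($counts \le 10$ by default, the
  standard convention) estimated as $C = 1 - f_1/N_{rare}$, with a
  coefficient-of-variation inflation $\gamma^2$; errors out when every rare
  species is a singleton ($C = 0$), directing the user to Chao1.
* **Good–Turing**: $S_{obs}/(1 - f_1/N)$; undefined when all species are
  singletons (coverage zero — the sample is uninformative).
* **Bootstrap**: $S_{obs} + \sum_i (1 - N_i/N)^N$.
* **Chao2 / ICE**: the incidence analogues, driven by $q_1, q_2$ (species in
  exactly one or two of $m$ replicates). Chao2 defaults to the
  bias-corrected small-$m$ form because the typical use here splits one
  sample into 4 in-silico replicates; the classic form is a flag away.

Replicate splitting (`split_into_replicates`) assigns each individual
independently and uniformly to one of $r$ replicates — an individual-level
multinomial division, the most natural reading of "randomly dividing" a
sample. All estimators return `S_obs` exactly when $f_1 = 0$ (resp.
$q_1 = 0$), and never return less than `S_obs` (a population-size cap,
applied on request, is the only exception and records a warning).

## Rarefaction

The expected number of species in a uniform without-replacement subsample
of $x$ individuals has the hypergeometric closed form
$$E[S(x)] = S_{obs} - \sum_i \binom{N - N_i}{x} \Big/ \binom{N}{x},$$
computed with `lchoose` so that $N$ up to $\sim 10^7$ neither overflows nor
loses the tiny per-species miss probabilities. A resampling version is kept
because the construction generalizes to statistics with no closed form; the
test-suite checks the two agree within Monte-Carlo error, and checks the
closed form *exactly* against complete enumeration of all subsets for every
abundance shape with $N \le 8$.

Curves (`build_curve`) are evaluated on an evenly spaced integer grid of 50
points (default) spanning $[1, N]$ — dense enough for stable fitting and
integration, small enough that fitting eleven models to many curves stays
fast. Nested subsamples truncate a single random permutation of the
individuals, so every smaller subsample is a subset of each larger one;
memory is $O(N)$, fine for the $\le 10^6$-cell samples used throughout.

## DivE: model-scored curve extrapolation

A rarefaction curve summarizes how diversity accumulates *within* the
sample; extrapolating it to the population size $N_{pop}$ (say, total T
cells in peripheral blood) estimates how much diversity the sample missed.
The catch is model choice: many accumulation-shaped families fit observed
curves equally well yet diverge wildly beyond the data. The estimator
implemented in `dive_estimate()` selects models by their demonstrated
ability to predict rarefaction data they were **not** fitted to:

1. Build the full-sample curve and nested-subsample curves (default: one
   subsample at 50%).
2. Fit every registry model to every curve by bounded Levenberg–Marquardt
   least squares (`minpack.lm::nls.lm`), 10 seeded restarts per fit
   (log-uniform perturbations, factor up to 3, around a per-model heuristic
   start such as $a \approx S_{obs}$ for asymptote parameters).
3. Hard-filter on **plausibility**: $S'(x) \ge 0$ and $S''(x) \le 0$
   (relative tolerance $10^{-9}$) on a 200-point log-spaced grid over
   $[1, N_{pop}]$ — over the *extrapolation* range, not just the data range,
   since a model that accelerates beyond the data is exactly the failure
   the criterion exists to stop. Derivatives are analytic, supplied by each
   `curve_model`, and verified against finite differences in the tests.
4. Score survivors on **discrepancy** (mean % error of each fit on its own
   curve, averaged over curves), **accuracy** (% error of the
   subsample-fit's prediction at the full sample size against the observed
   full-sample richness) and **similarity** (area between subsample and
   full fits over $[1, N_{full}]$, normalized by the area under the full
   fit). Rank each criterion, sum the ranks, break ties by accuracy, then
   discrepancy, then name.
5. Evaluate the top 5 models' full-data fits at $N_{pop}$, clamp each
   prediction at $N_{pop}$ (richness cannot exceed individuals), aggregate
   by geometric mean, and floor the result at `S_obs` with a warning if the
   floor binds.

Where the procedure leaves genuine freedom, the choices and their reasons:

* **Aggregation statistic** (nowhere prescribed): geometric mean over the
  top `top_k = 5`, because extrapolated predictions can span orders of
  magnitude and the geometric mean is the natural average on that scale; a
  median option is provided.
* **Subsample fractions**: one nested subsample at 50% by default;
  configurable — more fractions buy stricter selection at fitting cost, and
  criteria are then averaged over fractions.
* **Accuracy as a percentage** (not absolute) error, so criteria are
  comparable across datasets of different richness.
* **Model registry**: eleven canonical accumulation families — power,
  logarithmic, Michaelis–Menten, negative exponential, asymptotic
  regression, Weibull cumulative, Gompertz, hyperbolic, rational, logistic
  in log-$x$, Chapman–Richards — spanning finite-asymptote and unbounded
  shapes. Criteria-based selection, not any particular family, carries the
  method; the registry is a plain named list and users can add
  `curve_model()` objects of their own.
* **Fit weights**: equal by default; `1/x` weighting available because the
  large-$x$ end of an expected curve is strongly autocorrelated.

Reproducibility is strict: all randomness (restarts, subsampling) derives
from the `seed` in the configuration, and identical data + config + seed
give bit-identical scorecards.

## The under-sampling guard

A rarefaction curve that is still nearly linear at the full sample size
means species were accumulating at a constant rate when sampling stopped —
the sample carries almost no information about how accumulation decelerates,
and both the classical corrections and curve extrapolation become guesses.
`curvature()` rescales the curve to the unit square, prepends the origin,
and returns $2A - 1$ where $A$ is the trapezoidal area under the rescaled
curve: exactly 0 for a straight line, approaching 1 for a curve that
saturates immediately. This specific functional form is this package's
convention (simple, bounded, exact for the linear case); the default
threshold 0.1 is exposed in the configuration, and `dive_estimate()` refuses
to run below it unless forced (the refusal can matter more than the
estimate).

## The evaluation harness

The central empirical critique of classical estimators on skewed data is
that their estimates *grow with sample size* — more blood, more estimated
diversity — which no consistent estimator should do. The harness makes this
measurable: `estimate_vs_size()` applies an estimator to nested subsamples
(degenerate points recorded with reasons, never dropped),
`bias_gradient()` regresses estimate on subsample size and reports both the
raw slope and a dimensionless normalized slope (estimates scaled by the
full-sample estimate, sizes by $N$) so estimators and datasets can be
compared; `sign_binomial_test()` is the exact two-tailed binomial test
$p = \min(1,\, 2\min(P(X \le k), P(X \ge k)))$ on the signs of a set of
slopes, implemented directly from the tail probabilities and checked against
full enumeration for $n \le 20$. `sample_size_bias_protocol()` wires these
together across replicate simulated datasets.

## The synthetic generator

`make_population()` produces ground-truth populations with known richness:
Zipf ($p_i \propto i^{-a}$ — the canonical clonotype-frequency model),
lognormal, exponential, gamma (all drawn then normalized, seeded), and
uniform. Finite populations convert $p$ to integer counts by
largest-remainder rounding so the total matches exactly. `draw_sample()` is
multinomial (infinite mode) or multivariate hypergeometric without
replacement (finite mode, sequential conditional `rhyper`, $O(S)$). The
occupancy identity $E[S_{obs}] = \sum_i (1 - (1 - p_i)^n)$ anchors the
generator's correctness in the tests.

`simulate_pcr()` is deliberately a **one-step** model: each input molecule
receives an independent log-normal amplification factor (sdlog $\sigma$),
and reads are a single multinomial draw with probabilities proportional to
per-species amplified mass. One parameter controls distortion strength;
$\sigma = 0$ preserves relative abundances exactly while still inflating
repetition. Cycle-by-cycle branching PCR, chimeras, sequencing error and
cDNA multi-copy expression are *not* modeled — the goal is the sampling
phenomenon, not the chemistry. If cDNA copy-number variation is wanted, the
same factor mechanism represents it.

**What passing tests show, and what they do not.** The simulator emulates
skewed frequency distributions, equal-detection sampling and
amplification-factor dispersion. It does not emulate sequencing error
(which *inflates* observed richness with phantom species), clustering of
cells in tissue, or library-construction bottlenecks. Results on synthetic
data therefore demonstrate correctness of the estimators under their own
assumptions, not performance on any particular real dataset.

### The false-saturation demonstration

The demonstration sample for read-curve false saturation is a *shallow-tail*
sample: Zipf exponent 1.5, $S_{true} = 5 \times 10^4$, $10^6$ molecules,
giving $S_{obs} \approx 1.07 \times 10^4$ with most observed clonotypes
rare. This regime — molecule count comparable to read depth, singletons
dominating — is where exhaustive sequencing falsely saturates: with
$\sigma = 2$ and $10^6$ reads the read-rarefaction curve flattens (the last
10% of reads add under 5% new clonotypes) at well under half of the
sample's true richness, while $\sigma = 0$ with $10^7$ reads recovers
essentially all of it. In a deeply sequenced sample (reads $\gg$ molecules)
the same $\sigma$ produces almost no dropout — the phenomenon is a property
of the sampling regime as much as of the bias, which is the point.

## Numerical choices

* Binomial ratios in log space (`lchoose`); probabilities re-exponentiated
  only at the end.
* Model evaluation must stay finite over $x \in [1, 10^{13}]$ for any
  parameters within bounds; exponentials are arranged so they underflow to
  zero rather than overflow.
* Derived seeds use double-precision arithmetic modulo $2^{31} - 1$
  (exact below $2^{53}$), so nested seeding cannot overflow R's 32-bit
  integers.
* Restart initializations clip to parameter bounds; non-finite residuals
  are replaced by a large penalty so a pathological start cannot crash the
  optimizer.
* Ranking ties break deterministically (accuracy, discrepancy, model name)
  so results are reproducible across platforms.

## Problem sizes in the test-suite

The simulation studies in the tests use one Zipf population (exponent 1,
$S_{true} = 10^4$) of $10^7$ individuals, seven replicate samples of $10^5$
cells, nested fractions 0.1–1.0, and a 25%-subsample recovery comparison;
smaller populations ($S_{true}$ 100–2000) back the unit-level checks. Seven
replicates is the smallest number at which an all-positive exact sign test
is significant at $p < 0.05$ ($2 \cdot 2^{-7} \approx 0.016$) with a seed to
spare.

## Known limitations

* **Deep-sampling regimes blunt DivE's advantage.** When the sample already
  covers most of the population's species (mean count per species well
  above 1 even in subsamples), Chao-type estimators are near-optimal and
  can match or beat curve extrapolation on recovery error, as the
  evaluation harness itself shows on the deep Zipf study above — DivE's
  distinctive strength is its *stability against sample size* (near-zero
  bias gradient where every classical estimator's is significantly
  positive) and its behavior under severe under-sampling.
* Extrapolation assumes the sample is representative of the population
  extrapolated to. Blood plausibly represents blood; it does not represent
  lymphoid tissue, and no estimator in this package addresses that gap.
* The model registry is finite; a population whose accumulation shape lies
  far from all eleven families will be extrapolated by the least-bad of
  them. The scorecards expose how contested the selection was.
* `nested_subsamples()` materializes one permutation of $N$ individuals;
  for samples far beyond $10^7$ cells a streaming implementation would be
  needed.
* Species identifiers are opaque labels: no sequence-level processing,
  V(D)J annotation or clonotype calling — input begins at the count table.
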
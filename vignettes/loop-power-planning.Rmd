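---
title: "Planning well-powered differential Hi-C loop experiments"
author: "HiCLoopPower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning well-powered differential Hi-C loop experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiCLoopPower)
```

## The problem

Comparative Hi-C experiments ask whether specific chromatin loops gain or
lose contact frequency between conditions. Because Hi-C requires sequencing
depths orders of magnitude beyond ordinary count-based assays, an
under-powered design is an expensive mistake, and an apparently "negative"
differential analysis may simply reflect a lack of power. This package
provides the quantitative machinery to plan such experiments: how deep to
sequence, how many replicates to use, and — just as importantly — which loops
(short- or long-range) a given design can and cannot interrogate.

Two Hi-C-specific phenomena drive everything here:

1. **Distance decay.** Contact counts fall roughly as a power law
   $a \cdot d^{b}$ of the genomic distance $d$ between loci, so long-range
   loop pixels carry far fewer counts, and counts are what power is made of.
2. **Fold-change compression.** The counts observed at a loop pixel are the
   sum of the distance-dependent polymer background $e$ ("expected" counts)
   and the counts attributable to looping, $o - e$. When looping changes by
   a factor $\mathrm{FC}_{\mathrm{looping}}$, the background does not move,
   so the fold change a count-based test actually sees is

   $$\mathrm{FC}_{\mathrm{observed}}
     = \frac{(o - e)\,\mathrm{FC}_{\mathrm{looping}} + e}{o},$$

   which is always between 1 and $\mathrm{FC}_{\mathrm{looping}}$. The
   compression is strongest where the background share $e/o$ is largest,
   i.e. for shorter-range loops.

## The power model

Per-loop power uses the standard normal-approximation identity for
two-group comparisons of overdispersed counts. With per-replicate mean
counts $\mu$ at the loop pixel, squared biological coefficient of variation
$\phi$ (the negative-binomial dispersion: variance $\mu + \phi\mu^2$),
effect $\Delta$ on the observed-count scale, two-sided per-test level
$\alpha$, and $n$ replicates per condition,

$$\mathrm{power} = \Phi\!\left(
  \sqrt{\frac{n(\ln\Delta)^2}{2\,(1/\mu + \phi)}} - z_{1-\alpha/2}
\right).$$

The $1/\mu$ term is the Poisson (counting) part of the squared CV; $\phi$
is the part that replication cannot remove by sequencing deeper. The form
is the algebraic inversion of the familiar RNA-seq sample-size identity
$n = (z_{1-\alpha/2}+z_\beta)^2\,2(1/\mu+\phi)/(\ln\Delta)^2$; the package
verifies it against Monte-Carlo negative-binomial rejection rates (a Wald
statistic on the difference of log group means, with the model-based
variance evaluated at the design mean — the exact quantity the closed form
approximates) across a $3\times3\times3$ grid of $\mu$, $\phi$ and $n$ in
the test suite, with agreement within $\pm 0.05$. The approximation is
least accurate at very small counts with two replicates, where it is
conservative by a few percent.

Direction does not matter ($|\ln\Delta|$ is implicit in squaring), a null
effect returns exactly $\alpha/2$ (one rejection tail), and the output is
bounded by $[\alpha/2, 1)$ — though it saturates to 1.0 in double
precision, which is why the strictest monotonicity properties are asserted
only below that ceiling.

`loopPower()` composes the two pieces: the effect entering the test is
`observedFC(o, e, fcLooping)` and the mean is the loop's own observed
counts, rescaled linearly to the evaluated depth (`scaleCounts()`: Bernoulli
thinning scales pixel counts proportionally in expectation, so grids over
depths need no re-extraction). The per-test $\alpha$ is Bonferroni,
the nominal level divided by the number of loops tested.

## Experiment-design sweeps

`sweepPowerGrid()` evaluates the percentage of loops whose power to detect
a 2-fold looping change exceeds a threshold (0.8 by default, strictly)
over a grid of per-replicate depths (50 million to 5 billion contacts),
replicates (2–10) and dispersions (0.001, 0.01, 0.04). Loops are held
fixed across the grid — the loop list comes from a single deep reference
call — so the Bonferroni denominator is constant. `powerByDistance()`
reports the same statistic per 10 kb distance bin and shows the strong
short-range bias any fixed design has.

Two planning facts fall straight out of the algebra and are
property-tested: at a fixed total depth per condition, splitting it over
more replicates is never worse (the argument grows in $n$ at fixed
$n\mu$); and a higher dispersion can only reduce the well-powered fraction.

## Dispersion estimation

`estimateCommonDispersion()` returns the single $\phi$ the power planner
needs, by maximizing the negative-binomial profile likelihood across loops
with library-size offsets, with each loop's mean profiled out at its
offset-adjusted MLE. Plain profiling is biased toward zero at the replicate
numbers Hi-C affords — each profiled mean consumes one of $n$ degrees of
freedom, which at $n = 4$ collapses small $\phi$ to the boundary — so the
profiled likelihood carries the standard Cox–Reid adjustment
($-\tfrac12\log$ of each profiled mean's Fisher information). The adjusted
likelihood is maximized by golden-section search on $\log\phi$; genuinely
under-dispersed data land on the boundary and return $\phi = 0$. On
simulated data the estimator recovers $\phi \in \{0.001, 0.01, 0.04, 0.1\}$
within ±25% at 5,000 loops × 4 replicates and agrees with edgeR's common
dispersion within ~15%; it is deliberately not an empirical-Bayes moderated
per-loop estimator, which the planning use-case does not need.

Note that the estimand itself is not invariant under rescaling counts:
doubling every count halves the Poisson share of the variance, so
$\hat\phi$ drifts up by about $1/(2\mu)$ — the tests bound this drift by
its analytic size rather than asserting exact invariance.

## Subsampling

`thinContacts()` reproduces line-wise Bernoulli thinning of
merged-contacts text streams: each line is kept independently with
probability target/parent, in constant memory, byte-for-byte, reproducibly
per seed. The realized depth is binomial around the target; once the
target is at the billion-contact scale, the relative deviation is below
$10^{-4}$ with near certainty ($5\sqrt{(1-p)/(Np)}$ gives the 5-sigma
band). `bernoulliKeptCount()` runs the same decision stream without
materializing lines, so billion-scale accuracy is verified directly.

## The synthetic loop generator

`simulateLoopSet()` generates loop sets with the statistical structure the
analysis assumes, so every module is testable without external data. What
it emulates, and the calibration chosen (all defaults in `loopSimSpec()`;
chosen once and frozen):

- **Span distribution**: log-normal, median 300 kb, log-SD 0.75, truncated
  to [20 kb, 2 Mb), skewed short — the shape of deep GM12878 loop calls.
- **Background decay**: expected counts $2\times10^{7}\, d^{-1}$ at the
  reference depth of 5,536,073,657 contacts (≈ 57 expected counts for a
  350 kb loop).
- **Looping fraction**: rises log-linearly from 0.5 at 20 kb to 0.8 at
  2 Mb, so short loops sit on proportionally more background.
- **Pixel-level noise**: multiplicative log-normal with CV 0.3 on observed
  counts (an interquartile spread of roughly 1.5× at fixed distance). This
  is variability *between* loop pixels, distinct from the replicate-level
  dispersion $\phi$. The decay coefficient and this CV were calibrated
  jointly so that the percent-well-powered-versus-depth curve at
  $\phi = 0.001$, 2 replicates, 2-fold looping change and threshold 0.8
  reproduces the published behaviour of deep GM12878 data: ≈50%
  well-powered in the mid-single-digit billions of contacts per condition,
  and ≈90% only around 25 billion.

What it does **not** emulate: compartment and TAD structure, anchor reuse
and clustered loops, mappability and fragment-level biases, inter-replicate
library-complexity differences, or loop-calling noise. Passing tests on
synthetic sets therefore validate the statistical machinery and its
qualitative distance trends, not the exact percentages any particular real
dataset would give — those require that dataset's own counts and
dispersion.

`simulateReplicateCounts()` adds the replicate layer (negative-binomial
draws around depth-scaled means, with condition 2 moved through the
compression formula), and closes the loop: simulated replicates hand back
the simulating $\phi$ through `estimateCommonDispersion()`, and empirical
rejection rates track `loopPower()` predictions within the oracle
tolerance.

## Numerical choices

- Power-law fitting is ordinary least squares in log-log space: closed
  form, deterministic, and exactly right on noiseless power-law data; its
  role is smoothing and visualization, not inference. A natural-scale
  `nls` refinement is available behind `refine = TRUE`.
- Quantile profiles use linear interpolation between order statistics
  (`stats::quantile` type 7), stated because quantile conventions differ.
- `solveMinCounts()` inverts the power formula by bisection to $10^{-6}$
  relative tolerance and returns `Inf` when the dispersion ceiling
  $\Phi(\sqrt{n(\ln\Delta)^2/(2\phi)} - z_{1-\alpha/2})$ sits below the
  target: past that point no amount of sequencing helps, only replicates.
- Normal quantiles are computed on the upper tail
  (`qnorm(alpha/2, lower.tail = FALSE)`) so Bonferroni-scale alphas keep
  full precision.
- "Shorter than 2 Mb" and "observed greater than expected" are strict
  inequalities in `filterLoops()`; "power above the threshold" is strict in
  `percentWellPowered()`.
- Spans are start-to-start distances on the upstream-sorted anchors, which
  keeps binned spans on the bin grid; BEDPE input is 0-based half-open and
  converted to 1-based closed `GRanges` in memory.
- Problem sizes in the test suite (e.g. $10^5$ Monte-Carlo simulations per
  oracle cell, 5,000-loop recovery sets, a $10^8$-record thinning run) were
  chosen as the smallest sizes at which the sampling error of each check is
  comfortably below the tolerance it asserts.

## Known limitations

- The closed-form power is a normal approximation; at very low counts and
  2 replicates it deviates from true NB rejection rates by up to a few
  percent (always verified within ±0.05).
- Counts are rescaled linearly between depths; actual re-thinning adds
  binomial jitter that the grid deliberately ignores (and that a
  re-extraction workflow would reintroduce).
- All calibration targets are human 10 kb-resolution Hi-C; finer
  resolutions dilute counts per pixel drastically, and enrichment-based
  protocols (HiChIP, capture variants) need their own power analysis.
- The per-test alpha treats the loop list as fixed; re-calling loops at
  each depth would change the multiplicity correction.
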
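---
title: "Dating demographic change from dated sediment-core genealogies"
author: "paleoNe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating demographic change from dated sediment-core genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoNe)
```

## The inference problem

Lake sediments archive environmental DNA in dated layers. Gene variants
recovered from a stack of dated horizons are, in effect, a serially
sampled population: a time-calibrated genealogy of those variants carries
the signature of the gene's historical effective population size
\(N_e(t)\), and a shared, dateable change in \(N_e\) across many lakes is
evidence of a common selective driver. `paleoNe` implements the full
desk-scale inference chain for this setting:

1. **Simulation with known truth** — multi-site studies with dated
   horizons, genealogies drawn from a heterochronous coalescent under a
   site-specific \(N_e(t)\), GTR+\(\Gamma\) sequences under a relaxed
   clock, and injected contamination.
2. **Variant filtering** — the contamination and alignment-occupancy
   rules that decide which variants enter demographic inference.
3. **Skyline reconstruction** — a grouped Bayesian skyline coalescent
   sampler returning posterior \(N_e\) trajectories on a calendar grid.
4. **Phylogeny–date association** — an Association Index permutation
   test across a posterior tree sample.
5. **Trend and breakpoint** — random-forest modelling of median \(N_e\)
   versus date over all sites, partial dependence on the date, and a
   single-breakpoint segmented regression that dates the change.

## Models and assumptions

### Heterochronous coalescent

Backwards in time, \(k\) active lineages coalesce at instantaneous rate
\(k(k-1)/(2N_e(t))\); sampling events add lineages at their horizon's
deposition date. Waiting times are drawn by inverting the cumulative
intensity \(\int k(k-1)/(2N_e) \, dt\), computed on a piecewise-constant
approximation of \(N_e(t)\) with 0.1-year steps by default. Within a step
the inversion is closed-form, so constant and piecewise-constant
trajectories are simulated *exactly*; for smooth trajectories the error
is bounded by the step size. Beyond the range where a trajectory still
varies, the deep-past value extends analytically, so arbitrarily old
roots need no grid.

Time is measured in calendar years; \(N_e\) is therefore on the scale of
effective individuals times generation time in years, the same scale the
skyline estimates. No leap-year accounting is attempted
(`date_CE = most_recent_date - height`).

### Sequence evolution

Sequences evolve under a general time-reversible (GTR) substitution
model with discrete-Gamma site-rate categories (quantile discretisation
normalised to mean one) and an uncorrelated lognormal relaxed clock.
The lognormal is parameterised so the *arithmetic* mean branch rate
equals `mean_rate` (the convention of the common Bayesian samplers);
defaults are mean \(10^{-3}\) substitutions/site/year with log-space
standard deviation 1. The rate matrix is scaled to one expected
substitution per unit branch length and exponentiated through the
symmetrised eigendecomposition.

### Grouped Bayesian skyline

Coalescent intervals are merged into \(m\) contiguous groups of
near-equal event counts (default \(m = 25\); any remainder is spread
from the past end). Group-wise \(N_e\) values receive independent
log-uniform priors spanning \(10^{\pm 3}\) around the classic-skyline
scale and are updated with multiplier (log-space random-walk) proposals;
because the prior is flat in \(\log N_e\) and the proposal symmetric
there, the acceptance ratio is the bare likelihood ratio. Chains run in
duplicate (default 10,000 sweeps, thinning 10, burn-in 10%) and are
pooled after burn-in. The per-group effective sample size is reported;
falling below the floor (default 100) flags a warning in the fit rather
than an error. With a posterior tree sample, trees are mixed by uniform
Metropolis moves (`combine = "mix"`); independent genealogies of the
same population can instead be pooled by summing their log-likelihoods
(`combine = "pool"`).

The closed-form classic skyline \(\hat N_e = k(k-1)w/2\) and the exact
piecewise coalescent log-likelihood serve as internal oracles: the
sampler's group medians must track the classic estimates when
\(m\) equals the number of events, and the likelihood agrees with
numerical quadrature to \(10^{-8}\).

Posterior trajectories are summarised per calendar-grid date by the
posterior median and the shortest-interval 95% HPD. The grid must lie
inside `[root date, most recent tip date]`; the oldest group extends to
the root.

### Association Index

For tips labelled by their deposition horizon (the exact date as a
categorical value), the Association Index is
\(\mathrm{AI} = \sum_i (1 - f_i)/2^{n_i - 1}\) over internal nodes
\(i\), with \(n_i\) descendant tips and \(f_i\) the modal trait
frequency. Association means the observed AI lies *below* the null
(one-sided); the null is uniform tip-label permutation, paired per tree,
with the add-one-corrected
\(P = (1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(1 + N)\). A pooled
mode compares the median observed AI against the merged null instead.
Defaults are 100 trees × 100 permutations for desk runtimes; the
production-scale \(10^4 \times 10^3\) is reachable by configuration.

### Trend model and breakpoint

The multi-site table of posterior median \(N_e\) versus date (optionally
with a mean-imputed covariate) is modelled by random forests with date
and site as predictors, on \(\log_{10} N_e\) by default because skyline
posteriors are scale-heavy. Ten stratified 80/20 splits hold out every
site proportionally; accuracy is the held-out pseudo-\(R^2 =
1 - \mathrm{SSE}/\mathrm{SST}\). With only two or three predictors, the
forest considers *all* predictors at every split (`mtry = p`); feature
subsampling at \(\sqrt p\) with \(p = 2\) wastes half the splits on the
weaker predictor and measurably degrades held-out accuracy, while
bootstrap resampling already decorrelates the trees. Partial dependence
clamps the date in every training row (true partial dependence over the
empirical joint of the other predictors) and averages the per-model
curves.

The breakpoint is estimated by iterative linearisation of the
two-segment continuous model \(y = \beta_0 + \beta_1 x + \beta_2 (x -
\psi)_+\): refit with the auxiliary indicator term, update \(\psi\) by
\(\hat\gamma/\hat\beta_2\), iterate to convergence with step-halving
damping (the raw update oscillates on coarse grids). The 99% CI uses the
delta method \(\mathrm{SE}(\psi) = \mathrm{SE}(\hat\gamma)/|\hat\beta_2|\)
at convergence; a case-resampling percentile bootstrap is available by
flag. An exhaustive profile search over candidate grid dates
(`breakpoint_grid_oracle`, ties to the earliest date) verifies every fit
independently.

## The synthetic generator and what it does (not) show

`core_study_config()` encodes the default study: four sites, six dated
horizons each (1760–2010 CE, every 50 years), ten genealogy tips per
horizon, site-specific baseline \(N_e\) (80–240 years) and a shared
ten-fold sigmoidal increase

\[ N_e(t) = N_0\left(1 + \frac{F - 1}{1 + e^{-s (t - T)}}\right) \]

with midpoint \(T = 1784\) CE, fold change \(F = 10\) and steepness
\(s = 0.1\,\mathrm{yr}^{-1}\). The steepness was fixed once, before any
end-to-end evaluation, on identifiability grounds: a transition width of
roughly 40 years concentrates the slope change enough for a
single-breakpoint model to see it, and matches an onset in which the
rate of increase changes by an order of magnitude within decades.
Per-tip read counts are Poisson; kit contaminants (novel sequences
shared with a negative control) and cross-sample contaminants
(single-sample variants duplicated into a second sample of the same
site) are injected with recorded IDs, so filter recovery is exact by
construction. One RNG stream per study is forked per site: adding a site
never perturbs the others, and a fixed seed reproduces a study byte for
byte.

What the generator deliberately does *not* emulate: read-level error
(quality scores, chimeras, PCR duplicates), alignment uncertainty, tree
co-estimation from sequences (the pipeline analyses the true
genealogies, isolating demographic inference from phylogenetic error),
within-sediment DNA mobility, and recombination. Passing tests therefore
validate the inference chain *given* timed genealogies; on real data the
genealogies carry additional uncertainty that these tests do not probe.

## Numerical choices

* Intensity inversion grid: 0.1-year steps (configurable); exact for
  piecewise-constant trajectories, analytic constant tail beyond the
  grid.
* Group boundaries: even event split, remainder to the oldest groups; a
  randomised composition is available (`stochastic_groups`), drawn once
  at initialisation.
* HPD: shortest interval on sorted draws.
* ESS: autocorrelation-sum estimate truncated at the first non-positive
  lag.
* Ward clustering for the 50-variant phylodiversity cap uses `ward.D2`
  on patristic distances; the representative is the group medoid, ties
  broken by abundance then lexicographic ID — chosen for determinism.
* The occupancy filter iterates to a fixed point because removing a
  sequence lowers column occupancy; a single pass is available
  (`iterate = FALSE`). Occupancy is read per column (fraction of
  non-gap characters), and a sequence is removed if it has a base in
  any below-threshold column.
* Age–depth dating interpolates linearly between anchors and
  extrapolates with a second-order polynomial only beyond the anchored
  range; emitted dates are floored at 1750 CE, below which sediment
  chronologies are unreliable.
* Negative-control removal is presence-based (count > 0), applied
  before per-site cross-sample removal. The two removals in fact
  commute (each one's predicate depends only on counts the other never
  alters); the order is still enforced for auditability, and the
  removal counts are reported so contamination fractions are traceable.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely from
simulation at desk scale, chosen to keep a full validation cycle within
minutes while leaving Monte-Carlo error well inside the asserted
tolerances: skyline chains of 5–10 thousand sweeps in duplicate,
500-tree forests over ten splits, a thousand replicates for simulator
calibration (mean TMRCA within three standard errors of
\(2N_e(1-1/n)\)), five hundred replicates for breakpoint CI coverage,
and ten seeds for the end-to-end study. Production-scale settings
(5000-tree forests, \(m = 25\) with longer chains, \(10^4\) trees ×
\(10^3\) permutations for the association test) are plain arguments.

## Known limitations

* **Breakpoint-versus-midpoint offset.** The two-segment model dates
  the *knee* of a trajectory. For a logistic increase that saturates
  inside the observation window, the knee sits systematically 10–20
  years after the logistic midpoint; the estimate is a property of the
  fitted shape, not an unbiased estimator of the midpoint. Simulation
  recovery should therefore be read with this offset in mind.
* **Breakpoint existence is not tested by the CI.** Both the delta and
  bootstrap intervals are conditional on the two-segment model; on
  flat-truth studies the fit either fails to converge or converges to
  non-reproducible locations that scatter across the calendar range.
  Claiming a breakpoint exists requires replication (across seeds,
  sites or data subsets), not a narrow CI from one curve.
* The skyline's temporal resolution is bounded by coalescent-event
  density: where events are sparse (large \(N_e\), recent past), groups
  span long periods and smooth the reconstruction.
* Dereplication is exact-string; abundance-radius clustering of
  sequencing variants is out of scope, as are chimera and reading-frame
  screens.
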
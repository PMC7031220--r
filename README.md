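# paleoNe

Reconstructing the historical demography of gene variants archived in
dated lake-sediment cores, and dating the onset of demographic change.

Sediment layers deposit in datable order, and the environmental DNA they
trap is a serially sampled record of past microbial populations. For a
gene under changing selection — the canonical example being a
detoxification gene responding to industrial-era metal deposition — the
time-calibrated genealogy of its variants encodes the gene's effective
population size through time, N<sub>e</sub>(t). `paleoNe` provides the
complete desk-scale inference chain for researchers working with such
data: a coalescent simulator with known ground truth, the variant
filters that guard demographic inference against contamination, a
Bayesian skyline sampler, a phylogeny–deposition-date association test,
and random-forest + segmented-regression machinery that dates the change
in N<sub>e</sub> across many sites.

## The models in brief

* **Heterochronous coalescent**: backwards in time, *k* lineages
  coalesce at rate *k(k−1)/(2N<sub>e</sub>(t))*; tips enter at their
  horizon's deposition date. Simulation inverts the cumulative intensity
  exactly on a piecewise-constant grid.
* **Grouped Bayesian skyline**: coalescent intervals are merged into
  *m* contiguous groups (default 25); group-wise N<sub>e</sub> is
  sampled by Metropolis–Hastings with multiplier proposals under a
  log-uniform prior, in duplicate chains, and summarised as median and
  95% HPD trajectories on a calendar grid. The classic skyline
  N̂<sub>e</sub> = k(k−1)w/2 is the built-in oracle.
* **Association Index**: AI = Σ<sub>i</sub> (1−f<sub>i</sub>)/2^(n<sub>i</sub>−1)
  over internal nodes; low AI means tips from the same horizon cluster.
  Significance by tip-label permutation across a posterior tree sample.
* **Trend and breakpoint**: random forests (date + site) on
  log<sub>10</sub> median N<sub>e</sub> with stratified 80/20 splits;
  partial dependence on the date; single-breakpoint segmented regression
  y = β₀ + β₁x + β₂(x−ψ)₊ fitted by damped iterative linearisation,
  with a delta-method 99% CI and an exhaustive grid-search oracle.

## Worked example

Simulate a four-site study whose shared truth is a ten-fold sigmoidal
N<sub>e</sub> increase with logistic midpoint 1784 CE, then run the full
chain:

```r
library(paleoNe)
pp <- run_study_pipeline(core_study_config(), seed = 11, rf_trees = 500)
print(pp)
#> Demographic breakpoint pipeline (seed 11)
#> Synthetic core study: 4 sites, 25 samples, 244 variants
#>   shared breakpoint: 1784 CE; 12 kit and 12 cross contaminants
#>   mean RF pseudo-R2: 0.831
#>   estimated breakpoint: 1788.3 CE [1784.1, 1792.5] (true 1784)
```

The printed summary reports the study size, the contaminants planted for
filter validation, the mean held-out pseudo-R² of the ten random-forest
splits, and the segmented-regression breakpoint with its 99% CI. The
estimate dates the *knee* of the reconstructed trajectory; for a
logistic truth this sits slightly after the midpoint (see the methods
vignette). Individual stages are available as plain functions:

```r
st  <- generate_core_study(core_study_config(), seed = 11)
res <- remove_control_variants(st$matrix)   # kit contaminants out
res$report$pct_label                        # "4.9%"
fit <- skyline_fit(st$genealogies$S1, n_groups = 25)
plot(fit)                                   # median + HPD Ne trajectory
```

## Layout

* `R/` — simulator (`ne-trajectory`, `coalescent-sim`, `seqsim`,
  `study`), filters, skyline sampler, association test, trend/breakpoint
  estimators, age–depth and I/O utilities, pipeline driver.
* `tests/testthat/` — unit, property and end-to-end suites.
* `vignettes/demographic-breakpoints.Rmd` — the methods vignette.
* `inst/extdata/site_metadata.tsv` — geomorphological site table.
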
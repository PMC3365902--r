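# polypdemog

Age-based growth and population-dynamics analysis for solitary
scleractinian corals (such as *Leptopsammia pruvoti*) surveyed along a
sea-surface-temperature gradient — plus an individual-based simulator so
the whole pipeline is testable without field data.

## The science

Solitary corals that neither fragment nor fuse can be aged from annual
skeletal density bands (counted on CT scans for a subsample) and, from
the resulting age–length relationship, whole survey populations can be
aged by inverting the growth curve at each polyp's length. The package
implements the full chain:

1. **Growth.** Von Bertalanffy growth, `L_t = L∞ (1 − e^(−Kt))`,
   estimated from band-dated skeletons by the classical Ford–Walford
   plot: regress mean length at age *t*+1 on mean length at age *t*;
   then `L∞ = intercept / (1 − slope)`, `K = −ln(slope)`. The model's
   premise (growth rate decaying with age, `rate(t) = A e^(−Bt)`) is
   testable per site, and an ANCOVA gate decides whether sites may share
   one general curve.
2. **Ageing.** Each polyp's age class is `⌊−ln(1 − L/L∞)/K⌋`
   (completed years); lengths ≥ L∞ are flagged censored, not dropped.
3. **Mortality and stability.** Semi-log catch-curve regression
   `ln N_t = b − Z t` over non-empty age classes: `Z` is the
   instantaneous mortality rate, `N₀ = e^b`, and the regression r² is
   the population-structure stability (exactly 1 at steady state).
4. **Demography.** Observed and theoretical (survivorship-based) % of
   immature individuals, mean age, age at maximum % biomass and mean age
   of biomass, using an allometric length–mass model for biomass.
5. **Environment.** Pearson correlations of every demographic parameter
   with mean annual SST, with a 100 000-resample bootstrap estimate
   (small-*n* safeguard), Kruskal–Wallis on site temperatures, pairwise
   Kolmogorov–Smirnov on age structures, and surface-vs-depth
   temperature agreement.

## Worked example

Simulate the default six-site world (sites matching the reference
survey's SSTs, sample sizes and mortality rates, growth homogeneous at
the general curve truth `L∞ = 15.4` mm, `K = 0.062`/yr) and run the full
analysis:

```r
library(polypdemog)
cfg <- simulation_config(seed = 202)
sim <- simulate_survey(cfg)
res <- run_pipeline(sim$survey,
                    sst = data.frame(site = cfg$site_labels,
                                     sst_mean_c = cfg$sst_means),
                    n_resamples = 10000, seed = 1)
res
#> Coral demography pipeline
#>   6 sites, 879 records (0 rejected on read)
#>   growth pooling: general curve
#>         site n_polyps          Z stability_r2 observed_mean_age ...
#>       Genova      132 0.08456449    0.7962359          7.901515
#>    Calafuria      239 0.29291999    0.8663741          1.891213
#>         Elba       86 0.07724558    0.7707809          7.767442
#>     Palinuro      148 0.15016976    0.8131137          4.513514
#>       Scilla      130 0.07631070    0.7479721          8.353846
#>  Pantelleria      144 0.10803108    0.6995844          3.979167
#> Correlations with SST:
#>                     parameter n    r2      r  r2_BS   r_BS
#>                             Z 6 0.588 -0.767 0.2871 -0.536
#>                  stability_r2 6 0.668 -0.818 0.5565 -0.746
#>  ...
res$pooling$params
#> Von Bertalanffy growth parameters
#>   L_inf = 14.95 mm, K = 0.06603 1/yr
#>   Walford slope = 0.9361, intercept = 0.9550 mm  (n classes = 23, r2 = 0.992)
```

Reading the output: the ANCOVA gate found the six sites' Walford
regressions homogeneous, so all 180 band-dated corals were merged into a
general growth curve (here recovering the generating truth within ~4 %);
every polyp was aged with it; per-site `Z` tracks the generating values
(e.g. the Calafuria-like site, simulated at `Z = 0.427`, is estimated at
0.293 in this single replicate — catch-curve estimates at n ≈ 210 are
noisy); and the bootstrap correlation `r_BS` is attenuated toward zero
relative to `r`, as expected at n = 6 sites.

Published site-level reference values (SST means, `Z`, demographic
parameters of the six populations) ship as `reference_sites()`; the
pooled growth curve as `general_growth_params()`. For example, the
oldest polyp in the reference survey (12.8 mm) ages to

```r
vbgf_age_at_length(general_growth_params(), 12.8, "completed_years")
#> [1] 28
```

A thin command-line wrapper lives at `inst/cli/polypdemog.R`
(`simulate` and `run` subcommands).

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the analysis's headline quantities: the completed-years age of
a 12.8 mm polyp under the general curve; the median Ford–Walford
recovery of `L∞` and `K` from 100 simulated band-dated samples of 175
corals (uniform ages 1–28, 5 % length noise); and the median catch-curve
recovery of a Calafuria-like mortality rate from 500 Poisson age
structures of ~210 individuals. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/coral-demography.Rmd`) describes the
model, every convention and tolerance, what the simulator does and does
not emulate, and the known limitations of the classical estimators at
survey sample sizes.
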
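# paleodisp

Climate-forced population-dispersal modelling driven by human existence
potential (HEP).

## The problem

Archaeological site catalogues tell us *where* and roughly *when* a
prehistoric culture existed; gridded palaeoclimate reconstructions tell us
what conditions it faced. Neither alone supports quantitative statements
about how the population dispersed: how fast settlement fronts advanced,
how large the population was, which corridors carried the flux, and how
stadial/interstadial climate swings drove expansion and retreat.
`paleodisp` couples the two data types in a single mechanistic pipeline,
aimed at palaeodemographers and anyone modelling range dynamics of a
mobile population under a time-varying habitat-suitability field.

## The model

Suitability is organised in three HEP layers:

- **Environment HEP** `Phi_E = 1 / (1 + exp(-q))` with
  `q(P) = 1/2 P'AP + B.P + C`, a quadratic logistic regression on four
  standardized bioclimatic predictors, trained on presence/absence records
  built from sites with spatial blocking, a-priori absence rules (annual
  mean temperature outside [-2, 16] °C, wettest-month precipitation outside
  [30, 250] mm), and configurable pseudo-absence handling. An ensemble of
  refits on random 80 % subsets gives the mean field and its spread,
  validated by held-out Brier skill score and AUC.
- **Accessible HEP** `Phi_Ac = Phi_E · g_ele · g_std · g_wat · g_x`:
  terrain, roughness, water-body and a-priori habitability modifiers.
- **Available HEP** `Phi_Av = (w / w_max) · rho_c`, a Weibull-density
  response in `rho / rho_c` expressing mutual support at low density and
  resource pressure near the carrying capacity `rho_c = rho_c_max ·
  Phi_Ac`.

The population density `rho` then evolves by an
advection–diffusion–logistic equation, split into a conservative upwind
finite-volume transport step and an exact per-cell logistic growth step
with rate `r = r_max · Phi_Av / rho_c_max`; the drift velocity relaxes
toward `alpha · grad(Phi_Av)` with damping `gamma`, and the diffusivity is
a sub-grid closure clipped to 10–100 km² yr⁻¹. A normalized oxygen-isotope
series blends prototypical stadial and interstadial HEP states through
time. Diagnostics include the total population `Lambda = sum(rho · area)`,
the mobility index `M = sum |f|` with flux `f = v rho - D grad(rho)`,
first-arrival-time maps (threshold 0.4 P 100 km⁻²), occupation contours,
site-by-site chronology comparison, and full-factorial perturbed-parameter
ensembles (5 × 5 × 5 = 125 members by default) for uncertainty.

A synthetic-data module generates every input — paired stadial/interstadial
climate, Bernoulli-sampled site catalogues from a known truth model,
periodic isotope series, ridge topography — so the entire pipeline runs and
tests offline. See the methods vignette
(`vignettes/population-dispersal-model.Rmd`) for the science and the
numerical choices.

## Worked example

A fully synthetic study: generate a world and a site catalogue, train the
niche ensemble, assemble the HEP stack, run 1000 years of dispersal under
square-wave stadial/interstadial forcing, and compare the simulated
chronology with the (synthetic) sites.

```r
library(paleodisp)

scenario <- synthetic_scenario(seed = 42)
inputs <- build_synthetic_inputs(scenario, iso_start_ka = 45, iso_end_ka = 42.9)

pa <- build_presence_absence(inputs$sites, inputs$predictors, inputs$grid,
                             option = 3, seed = 42)
pa
#> <pd_pa> 1064 records (150 presence, 192 a-priori absence, 722 pseudo-absence kept), option 3, block 0.5 deg

ens <- train_hep_ensemble(pa, inputs$predictors, n_members = 50, seed = 42)
glance(ens)
#> # A tibble: 1 × 4
#>   n_members   bss mean_auc train_fraction
#>       <dbl> <dbl>    <dbl>          <dbl>
#> 1        50 0.129    0.736            0.8
```

A positive Brier skill score says the ensemble beats the intercept-only
reference on held-out records; AUC 0.74 reflects the deliberately noisy
option-3 labels (pseudo-absence cells get random labels at the observed
presence rate), not the estimator — on clean Bernoulli labels from the
truth model the same fit exceeds AUC 0.9 (see the recovery tests).

```r
stack <- accessible_stack(ens, inputs$predictors, inputs$predictors_gs,
                          inputs$topo)
iso <- normalize_isotope(inputs$iso_series, window = c(45, 44))
run <- run_dispersal(inputs$grid, inputs$topo$land, stack, iso,
                     dispersal_params(), start_ka = 45, end_ka = 44,
                     init = list(center = c(10.25, 33.25), spread_km = 150,
                                 total_population = 5000))
run
#> <pd_run> 45-44 ka, 101 snapshots, final Lambda = 7465 persons

tail(tidy(run), 3)
#> # A tibble: 3 × 3
#>   time_ka lambda mobility
#>     <dbl>  <dbl>    <dbl>
#> 1    44.0  7373.     1.08
#> 2    44.0  7419.     1.01
#> 3    44.0  7465.     1.04

compare_chronology(arrival_time_map(run), head(inputs$sites, 3))
#> # A tibble: 3 × 8
#>   id         lon   lat phase model_mean_ka model_sd_ka n_members reached
#>   <chr>    <dbl> <dbl> <chr>         <dbl>       <dbl>     <int> <lgl>
#> 1 site_001  1.25  30.8 P1             NA            NA         1 FALSE
#> 2 site_002  4.25  30.8 P1             NA            NA         1 FALSE
#> 3 site_003  5.75  30.8 P1             44.6           0         1 TRUE
```

The population grew from the 5000-person seed to ~7500 over the first
millennium, and the arrival front reached `site_003` at 44.6 ka; the two
unreached sites lie beyond the 1000-year front. `autoplot(run)` plots the
`Lambda`/`M` series, `autoplot(arrival_time_map(run))` maps the chronology,
and `plot_occupation(...)` draws density with occupation contours.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/cli/paleodisp`) with subcommands `synth`, `hep-train`, `simulate`,
`ensemble` and `diagnose`, driven by a schema-validated YAML configuration;
every output file embeds the configuration hash and seed.

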
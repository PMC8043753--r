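# paleopva

Stochastic, age-structured demographic-susceptibility models for
communities of extinct and extant megafauna.

## What problem this solves, and for whom

Palaeoecologists and conservation modellers often want to know whether a
species' *intrinsic demography* — late maturity, low fertility, low
density, long generations — predicts its extinction risk, and whether a
community's extinction *chronology* can be explained by relative
demographic susceptibility alone. `paleopva` provides the full modelling
chain for that question:

1. **Leslie models** per species (female-only, pre-breeding census,
   ages 0..ω): fertilities in the first row, survival on the
   sub-diagonal, optional terminal self-loop; eigenanalysis gives the
   growth rate λ, stable age distribution **w**, net reproductive rate
   R₀ and generation length G (mean age of mothers,
   G = Σ x λ⁻ˣ lₓ mₓ / Σ λ⁻ˣ lₓ mₓ).
2. **Stochastic projection** (compiled engine): binomial survival,
   Poisson recruitment, compensatory density feedback
   s(N) = 1/(1 + c(N/K)^θ) calibrated so λ = 1 at K = D·A, and
   catastrophic ~50% die-offs at a baseline 0.14 per generation.
   Runs start at n₀ = A·D·**Mw** (A = 250,000 km²) and last
   40·round(G) years.
3. **Perturbation scenarios** swept over progressive intensity grids:
   juvenile-survival, fertility, and all-ages survival reductions
   (0→1 by 0.05), individual offtake apportioned by **w**,
   catastrophe frequency and magnitude, plus juvenile-only offtake and
   bird egg-harvest sub-scenarios. A run is quasi-extinct when its final
   female total falls below E_q = 50.
4. **Risk synthesis**: the area under each quasi-extinction curve
   (normalized-axis trapezoid) is the scenario-specific risk; ranks,
   core-scenario totals Σ∫Pr(E_q)d(x) and median susceptibility ranks
   summarise each species.
5. **Allometric inference**: OLS of risk on log₁₀ mass or log₁₀ G with
   AICc evidence ratios (ER), Spearman concordance between risk and
   extinction-window midpoints, and outlier-removal sensitivity fits.

A synthetic-community generator (21 species, 13 extinct, five functional
groups, textbook allometries, near-stationary growth) makes the entire
pipeline testable without any external data; real demographic tables and
extinction windows enter as CSVs.

## Worked example

```r
library(paleopva)

species <- generate_species_table(generator_spec(seed = 1))
sp <- species[["syn_carnivore_02"]]
sp
#> <species_params> syn_carnivore_02 (extant carnivore)
#>   mass 7.66 kg | alpha 2 | omega 9 | D 8.835 km^-2 | terminal loop: 0
#>   S_x: 0.544 0.544 0.726 0.726 0.726 0.726 0.726 0.726 0.726 0.726
#>   m_x: 0 0 1.39 1.39 1.39 1.39 1.39 1.39 1.39 1.39

model <- build_leslie(sp)
model
#> <leslie_model> syn_carnivore_02: 10 age classes, census = pre
#>   lambda = 1.089652 | R0 = 1.3883 | G = 3.672 yr

cfg <- sim_config(iterations = 500, seed = 1)
curve <- sweep_scenario(sp, cfg, make_scenario("all_survival", grid_step = 0.1))
curve
#> <qe_curve> syn_carnivore_02 | all_survival | 11 grid points | integral 0.8556
round(curve$pr_eq, 3)
#>  [1] 0.000 0.056 1.000 1.000 1.000 1.000 1.000 1.000 1.000 1.000 1.000
```

Read: this small, fast carnivore (λ ≈ 1.09) persists unperturbed
(Pr(E_q) = 0 at intensity 0), tolerates a ~10% survival reduction in most
runs, and is certainly quasi-extinct once survival drops by 20% or more;
the area under that curve, 0.856 on the normalized axis, is its
all-survival risk integral, comparable across species and scenarios.
Slower, longer-generation species saturate earlier and score higher.

The full pipeline (all species × scenarios → curves, risk summary,
regressions, manifest):

```r
run_pipeline(species, sim_config(iterations = 500, seed = 1),
             out_dir = "results",
             windows = generate_extinction_windows(species, "random",
                                                   seed = 2))
```

or from the shell:

```sh
Rscript inst/cli/paleopva.R make-fixtures --seed 1 --out species.csv
Rscript inst/cli/paleopva.R pipeline --species species.csv \
  --iterations 500 --seed 1 --out-dir results
```

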
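# nightsong

Tools for relating the structure of nocturnal song in common nightingales
(*Luscinia megarhynchos*) to paternal provisioning effort at the nest.

Male nightingales sing extraordinarily large repertoires (~180 song types)
whose delivery follows partly fixed sequential rules. This package implements
the full analysis chain used to ask whether a male's song predicts how hard
he will later feed his chicks:

1. **Song corpus measures** — from a labelled sequence of 533 consecutive
   songs per male: repertoire size, whistle/trill/buzz repertoire sizes, and
   category occurrences.
2. **Orderliness via transition networks** — the song sequence becomes a
   directed graph (types = nodes, adjacent transitions = edges). Orderliness
   is quantified by the *average shortest path length*
   `L = mean over reachable ordered pairs (u,v) of d(u,v)` (long linear
   singing chains give large `L`) and the *transitivity* (global clustering
   coefficient) `C = 3 N_triangle / N_triples` of the undirected projection.
3. **Provisioning from RFID logs** — antenna registrations are collapsed
   into nest visits (gap < 60 s), converted to session rates (morning: first
   visit to 10:00; evening: 18:00 to last visit), summarised per male as the
   median rate (visits/h), and compared across males by one-way ANOVA.
4. **Prediction chain** — LASSO (`min 1/(2n)‖y − Xβ‖² + λ‖β‖₁`, own
   coordinate-descent solver, 5-fold CV penalty choice) selects song
   measures; an ε-insensitive support-vector regression (RBF kernel, C = 1,
   γ = 1/p, ε = 0.1; own SMO-style dual solver) predicts each male's feeding
   rate leave-one-out; Spearman's ρ between predicted and observed rates
   measures predictive power.
5. **Synthetic studies** — a generator with known ground truth (latent male
   quality → orderliness, repertoire composition and visit intensity)
   reproduces the published population moments, so every stage is testable
   without field data.

## Worked example

```r
library(nightsong)
report <- run_pipeline(pipeline_config(sim = sim_config(), seed = 1))
print(report)
#> <study_report> 20 males
#> One-way ANOVA: F(19, 220) = 159.540, p = 3.274e-117
#> LASSO selected: average_shortest_path, n_hatchlings, trill_repertoire, transitivity, buzz_occurrence
#> LOO SVR: Spearman rho = 0.833, p = 5.124e-06
```

The ANOVA shows feeding rates are far more variable between than within
males (stable individual provisioning styles). The LASSO kept the
orderliness measure (average shortest path) and brood size among the
strongest predictors, and the leave-one-out SVR predicts the held-out
males' median feeding rates with ρ = 0.83. Per-male summary statistics in
the style of a population table:

```r
report$measure_stats[1:3, 1:4]
#>              measure   mean    sd   cv
#> 1    repertoire_size 174.80 27.23 0.16
#> 2 whistle_repertoire  26.70  5.59 0.21
#> 3 whistle_occurrence  79.65 26.16 0.33
```

Realised feeding effort for this simulated population is 11.9 ± 4.1
visits/h (configured target 11.4 ± 3.8).

A command-line front end lives at `inst/cli/nightsong`
(`simulate`, `features`, `feeding`, `model`, `run` subcommands), e.g.

```sh
Rscript inst/cli/nightsong run --seed 4 --out results_dir
```

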
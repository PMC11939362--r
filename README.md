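# spawnhab

Reach-scale spawning-habitat assessment for drifting-egg river fish, built
around *Coreius guichenoti* in a large, dam-regulated river. The package
scores every cell of a two-dimensional hydraulic field with a fuzzy-logic
habitat model over **four factors** — bed grain size (substrate), water
temperature, depth-averaged flow velocity and water depth — and aggregates
the scores into reach-level habitat indices. A substrate-free three-factor
baseline lets you quantify what including substrate changes.

## The model

Each factor carries five linguistic grades (`VL, L, M, H, VH`) with
piecewise-linear membership functions anchored on published suitability
thresholds (e.g. spawning is blocked below 18 °C and above 27 °C, optimal at
20–25 °C). A plain-text rule base maps grade combinations to an output
suitability grade; min–max Mamdani inference with centroid defuzzification

    HSI = ∫ z μ(z) dz / ∫ μ(z) dz,   z ∈ [0, 1]

produces a crisp habitat suitability index per cell. With cell areas `A_i`,
the reach-level indices over wetted cells are

    WUA = Σ A_i · HSI_i                    (weighted usable area, m²)
    OSI = WUA / Σ A_i                      (overall suitability index)
    ISP, MSP, LSP                          (% of area with HSI ≥ 0.7,
                                            0.3 ≤ HSI < 0.7, HSI < 0.3)

Bed grain size can be estimated from the flow by inverting the
incipient-motion threshold-velocity formula
`Ue = (h/d)^0.14 · [17.6·(ρs−ρ)/ρ·d + 6.05e-7·(10+h)/d^0.72]^0.5`
on its coarse (monotone) branch, and a calibrated synthetic reach generator
emulates the semi-monthly hydraulic regimes of the study reach so the whole
pipeline runs reproducibly from a seed. The methods vignette
(`vignettes/spawning-habitat-model.Rmd`) documents every modelling choice.

## Worked example

```r
library(spawnhab)

vars <- default_fuzzy_variables()
rb   <- default_rule_base()

# the temperature crossover: 17 °C fully VL, 18 °C half VL / half L
membership(vars$temperature, "VL", c(17, 18, 19))
#> [1] 1.0 0.5 0.0

# one gravel-bedded cell in 18.7 °C water, 0.7 m/s, 5 m deep
evaluate_hsi(rb, vars, substrate = 0.1, temperature = 18.7,
             velocity = 0.7, depth = 5)
#> [1] 0.6673307

# a synthetic reach at the first-half-of-May operating condition
spec  <- calibrate_reach_spec(reach_spec(seed = 42))
sched <- default_schedule()
may   <- sched[sched$period == "First half of May", ]
res   <- run_period(generate_field(spec, may), may, rb = rb, vars = vars)
res$summary
#>              period wua_m2    osi isp msp lsp
#> 1 First half of May 708477 0.4373   0  66  34
```

The single-cell HSI (0.667) reflects marginal temperature compensated by
favourable substrate, velocity and depth. The May reach summary says about
0.71 km² of the ~2 km² wetted reach is effectively usable (OSI 0.44), with
no ideal habitat yet (temperature still below the optimum) and two thirds of
the area in the moderate class.

Comparing the four-factor model against the substrate-free baseline over the
whole schedule isolates the substrate effect per semi-month:

```r
cmp <- compare_models(generate_fields(spec, sched), sched, rb4 = rb,
                      vars = vars)
data.frame(period = cmp$period, wua_change_pct = round(cmp$wua_change, 2))
#>                  period wua_change_pct
#> 1   First half of March           0.00
#> 2  Second half of March           0.00
#> 3   First half of April           0.00
#> 4  Second half of April           0.00
#> 5     First half of May          19.97
#> 6    Second half of May          15.47
#> 7    First half of June         -24.73
#> 8   Second half of June         -10.45
#> 9    First half of July         -33.32
#> 10  Second half of July         -29.13
```

March–April are blocked by temperature in both models (0 % change); in May a
gravel/cobble bed lifts usable area substantially above the substrate-blind
baseline; from June the flood coarsens the synthetic bed into boulders and
substrate turns mildly detrimental.

A command-line front end wrapping the same functions ships in
`inst/scripts/spawnhab.R` (subcommands `simulate`, `substrate`, `evaluate`,
`compare`, `summarize`).

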
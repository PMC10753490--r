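# seabirdTEB

Time–energy budget modelling of marine bird energetics.

Measuring the energy expenditure of a free-living marine bird (a seabird, sea
duck, diver or grebe) normally requires doubly labelled water, heart-rate
loggers or accelerometry — data that exist for only a handful of species and
almost never outside the breeding season. Yet for most populations a
*time–activity budget* (hours per day spent flying, foraging, sitting on the
water, sitting on land) can be measured or at least estimated. `seabirdTEB`
turns such budgets into daily energy expenditure (DEE) estimates for **any**
marine bird family, including data-deficient and even extinct species.

## The model

For a bird of body mass *m* (g), basal metabolic rate (BMR, kJ h⁻¹) is
estimated allometrically as the mean of a seabird and a waterfowl power law.
Daily energy expenditure is then

> DEE = Σₐ tₐ · BMR · mₐ  +  Σₐ TC(medium(a)) · m(kg) · max(0, LCT − Tₐ) · tₐ

where *tₐ* are hours per activity *a* ∈ {flight, forage, on water, on land},
*mₐ* the activity-specific BMR multiplier for the bird's family, and the
second term is the thermoregulatory cost paid whenever the temperature of the
occupied medium (sea surface or air) falls below the lower critical
temperature (LCT). Thermal conductance TC is medium-specific: submerged in
water ≫ sitting on water > in air; flapping flight is assumed to generate
enough excess heat to cover thermoregulation.

The package ships a collated table of activity-specific BMR multipliers for
nine measured families (e.g. Alcidae flight = 31×BMR, Phalacrocoracidae
flight = 20.5×BMR, Diomedeidae flight = 2.2×BMR), a nine-guild ecological
taxonomy of all 18 marine bird family-groups, and explicit *borrow rules* so
the nine unmeasured families resolve to a measured donor with a recorded
provenance trail.

## Worked example: the great auk

The great auk (*Pinguinus impennis*), extinct since 1844, was a flightless
wing-propelled diver. With an assumed mass of 5 kg:

```r
library(seabirdTEB)
physiology_profile(5000)
#> Physiology profile (5000 g)
#>   BMR: 64.08 kJ/h [allometric (mean)]
#>   LCT: 10.10 degC
#>   TC (kJ/h/degC/kg): in water 1.423, on water 0.711, air 0.323
```

A 5-kg auk metabolises ~64 kJ h⁻¹ at rest and starts paying for heat below
~10 °C — which North Atlantic waters are below almost year-round.

Data-deficient families borrow multipliers via their ecological guild, with
the donor recorded per activity (shearwaters here take foraging costs from
the auks, the other activities from the albatrosses):

```r
resolve_multipliers("Procellariidae C")
#>   flight   forage on_water  on_land
#>      2.2      8.0      2.0      0.8
#> attr(,"donor")
#>        flight        forage      on_water       on_land
#> "Diomedeidae"     "Alcidae" "Diomedeidae" "Diomedeidae"
```

The scenario simulator reconstructs a full great auk year under three
migration strategies: (A) resident, nights ashore; (B) resident, nights at
sea; (C) swimming migration to a Moroccan-Atlantic wintering ground:

```r
a <- simulate_year("A", seed = 1)
b <- simulate_year("B", seed = 1)
a
#> Great auk simulation, scenario A (seed 1)
#>   breeding DEE: 4088 +/- 110 kJ/day; intake 5494 +/- 148 kJ/day (34.8 sand lance)
#>   non-breeding DEE: 3943 +/- 222 kJ/day (total 1199 MJ)
compare_scenarios(a, b)   # % of non-breeding energy saved by wintering ashore at night
#> [1] 11.89316
```

During the May–June breeding season the simulated auk must ingest ~5500 kJ of
prey per day (DEE divided by a 74.4% assimilation efficiency) — about 35
sand lance of 158 kJ each — and hauling out at night instead of floating on
cold water saves ~12% of the non-breeding energy bill.

## Command-line interface

A thin Rscript wrapper is installed under `inst/cli/seabirdteb`:

```sh
seabirdteb bmr --mass-g 5000
seabirdteb multipliers --family "Procellariidae C"
seabirdteb dee --budget budgets.csv --family Alcidae --mass-g 800
seabirdteb simulate-auk --scenario A --seed 1 --out runA.csv
seabirdteb compare --a runA.csv --b runB.csv --window nonbreeding
```

All subcommands emit JSON (errors as JSON on stderr with non-zero exit).

## What is packaged vs reconstructed

Multiplier records, allometric coefficient sets and scenario parameters all
live in human-readable CSV/YAML files under `inst/extdata/` with per-record
provenance notes (`printed` for values reproduced verbatim from the source
collation, `reconstructed`/`assumed` for values re-derived from the primary
literature). See the methods vignette (`vignettes/marine-bird-energetics.Rmd`)
for the full account of the model, its assumptions and its limitations.
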
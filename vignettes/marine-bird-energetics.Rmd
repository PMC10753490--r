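---
title: "Marine bird time-energy budgets: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marine bird time-energy budgets: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seabirdTEB)
```

## The model

`seabirdTEB` estimates the daily energy expenditure (DEE) of a marine bird
from a time-activity budget. The day is partitioned into four behavioural
categories — flight, foraging, resting on water, and being on land — and each
hour in an activity costs a fixed multiple of basal metabolic rate (BMR):

$$\mathrm{DEE} = \sum_a t_a \cdot \mathrm{BMR} \cdot m_a \;+\;
  \sum_a \mathrm{TC}_{\mathrm{medium}(a)} \cdot M \cdot
  \max(0, \mathrm{LCT} - T_a)\cdot t_a$$

with $t_a$ the hours in activity $a$, $m_a$ the activity- and
family-specific BMR multiplier (dimensionless), $M$ body mass in kg,
$\mathrm{TC}$ thermal conductance in kJ h^-1^ °C^-1^ kg^-1^, LCT the lower
critical temperature and $T_a$ the temperature of the medium occupied during
$a$. The two terms are strictly additive: activity heat never substitutes
for thermoregulatory heat except in flight, where flapping is assumed to
produce enough excess heat that no thermoregulatory cost is charged at all.

Key structural assumptions, all deliberate simplifications:

* **Multipliers are totals, not increments.** An activity at $m_a = 31$
  costs $31 \times$ BMR, not BMR $+ 31\times$BMR. This matches how
  activity costs are reported in the field ("31×BMR").
* **Excluded costs.** Digestion, growth, reproduction (egg formation, chick
  provisioning), moult and within-category behavioural variation (preening
  vs sleeping "on land") are not modelled. Breeding-season estimates are
  therefore colony-attendance costs only and will undercut a true breeding
  FMR.
* **Dive costs are depth-independent.** Foraging is one flat multiplier;
  depth- and duration-dependent dive costing is out of scope.

## Physiology from mass alone

When no empirical BMR exists, the package derives all physiology from body
mass via packaged power laws ($a\,m^b$), stored in
`inst/extdata/allometry_coefficients.csv` with the mass unit each equation
expects; the public interface always takes grams and converts internally,
which prevents the classic g/kg allometry bug.

* **BMR** (kJ h^-1^): the default `mean` method averages a seabird
  relationship ($2.30\,m_g^{0.774}$ kJ d^-1^) and a waterfowl relationship
  ($422.19\,m_{kg}^{0.744}$ kJ d^-1^); `seabird` and `duck` are exposed for
  sensitivity analysis, and an empirical value can override the allometry
  per call (`bmr_override`).
* **LCT** (°C): $47.17\,m_g^{-0.181}$ — larger birds tolerate colder
  environments. For a 5-kg bird the LCT is ~10.1 °C, so North Atlantic SSTs
  sit below it nearly year-round.
* **Thermal conductance** (kJ h^-1^ °C^-1^ kg^-1^): three media with a
  common $m_{kg}^{-1/3}$ surface-to-volume scaling and coefficients ordered
  *submerged (2.42) > sitting on water (1.21) > air (0.55)*, calibrated so
  that water-borne heat loss is roughly four-fold the in-air rate, as
  measured for aquatic birds. Which medium applies is an ecological mapping:
  foraging is fully submerged for wing- and foot-propelled diving guilds but
  surface-level for surface feeders and plunge divers (brief submersion
  only — a judgement call; the guild table makes it configurable); resting
  on water always uses sea-surface temperature, including for the emergent
  body fraction; land uses air temperature.

The coefficient sets carry provenance notes because the upstream collation
prints them only in equation images; every value here is flagged
`reconstructed` from the cited primary sources and frozen by a checksum
test so any change to the transcription is deliberate and visible.

## The multiplier table and guild fallback

`inst/extdata/` packages: 18 family-groups (16 families, with the speciose
Procellariidae split into A: fulmarine/gadfly petrels and prions, B: diving
petrels, C: shearwaters), nine ecological guilds defined by flight style ×
foraging style × resting substrates, direct multipliers for nine families,
and borrow rules for the other nine. Five multiplier values are reproduced
verbatim from the printed collation (`provenance: printed`); the remainder
are reconstructed from the per-family activity-cost literature and flagged
as such. Exactly eight guilds have a measured representative; the gap is the
flap-gliding wing-propelled divers (the shearwaters), which therefore borrow
flight/on-water/on-land costs from the closely related Diomedeidae and
foraging costs from the other wing-propelled foragers, the Alcidae. All
other unmeasured families default to the measured family of their own guild.
`resolve_multipliers()` records the donor per activity and refuses to
default silently when no rule exists.

## The great auk scenario simulator

The simulator reconstructs a year (365 days) of a representative great auk —
flightless, wing-propelled, resting on both water and land, so it takes the
multipliers of the flightless wing-propelled diver guild (Spheniscidae) —
under three migration strategies:

* **A** resident near the colony; diurnal foraging, nights *ashore*;
* **B** resident; nights *at sea* outside the breeding season;
* **C** swimming migration to a Moroccan-Atlantic wintering ground (the
  southernmost place the species is known from), nights at sea.

Because no behavioural data can exist for an extinct bird, every scenario
parameter is a documented reconstruction from analog extant species
(`provenance: assumed` tags in the shipped YAML): mass 5000 g; breeding
window May 1–June 30 with a guillemot-like colony-attendance template
(7 h foraging, 5 h on water, 12 h ashore); a 6-h daily foraging target
outside breeding, capped by daylight for this diurnal forager; an Icelandic
colony at 63.3°N and a wintering site at 31°N; autumn departure (Sep 1) and
spring return (Apr 15) with 30-day swimming passages each way, costed with a
10-h foraging-type swimming day. Night length comes from a standard
solar-declination day-length model (CBM form, 0.833° refraction), checked
once against an independent astronomical formulation.

### Synthetic climate

Daily sea-surface and air temperatures are annual sinusoids
(mean + amplitude · cos(2π(d − phase)/365)) plus Gaussian noise
(SD 0.4 °C), with parameters chosen to match climatological seasonal cycles
at the two sites (colony SST 3–10 °C, Morocco SST 16.5–21.5 °C). On travel
days temperatures interpolate linearly between sites with migration
progress. This emulates the *seasonal contrast* that drives the
thermoregulatory story; it does not emulate weather autocorrelation, storms,
interannual variability, currents or microhabitat choice — so passing tests
demonstrate the accounting and the climatological signal, not fidelity to
any particular historical year.

### Randomness and reproducibility

All stochasticity (climate noise, optional per-activity budget jitter,
default SD 0 h) flows from a single integer seed. Draws are laid out in a
fixed order (jitter, colony climate, then wintering climate) so that
same-seed runs of different scenarios share identical breeding-window days
by construction — scenarios are supposed to differ only outside the
constraints of the breeding season. Results embed the seed and an MD5 hash
of the configuration.

## Numerical choices

* Budgets must sum to 24 h within 1e-6 h; `renormalise = TRUE` rescales
  proportionally (with a logged message per adjusted row) for tolerant
  ingestion of classified biologging budgets.
* Thermoregulatory cost is continuous at the LCT (the deficit term is
  `max(0, LCT - T)`), linear in exposure hours, and additive over arbitrary
  partitions of the day — properties the test suite asserts directly, along
  with equivalence to a brute-force time-slice oracle at < 1e-9 relative
  error over 1000 random simplex-drawn budgets.
* Prey counts are reported as a continuous value *and* a round-half-up
  integer, because published counts rarely state their rounding.
* Percent scenario differences are `100 * (sum(y) - sum(x)) / sum(y)` — the
  share of the *reference* scenario's expenditure saved by the alternative;
  the sign convention makes "x cheaper than y" positive.
* Temperature plausibility is enforced as warnings at [−5, 45] °C, not
  errors, since brackish and lagoon extremes exist.
* The day-to-day SD reported for the breeding-season intake is the spread
  across the 61 May–June days of one simulated year (temperature noise plus
  seasonal trend), the most defensible reading of a "±" on a daily
  requirement; with budget jitter enabled it widens accordingly.

## Problem sizes

The shipped analyses are intentionally small: three 365-day simulations per
comparison, 1000-budget oracle sweeps, 1000-replicate climate calibration
checks. Each completes in seconds, so the whole pipeline can be re-run from
scratch for every seed.

## Known limitations

Estimates inherit the full uncertainty of the BMR allometry (family-level
multipliers dominate species-level variation); reconstructed multiplier and
conductance values carry transcription uncertainty flagged in the data
files; the great auk configuration is a plausibility argument, not an
inference about actual great auk behaviour; and the breeding-season costs
exclude reproduction itself. Where species-specific BMR, conductance or
multiplier measurements exist, they should be supplied via the override
hooks rather than the allometric defaults.
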
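---
title: "Simulating nutrient exports from managed boreal catchments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nutrient exports from managed boreal catchments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealnp)
```

## The problem

Forestry on drained peatlands is a major and long-lasting source of nitrogen
and phosphorus to boreal surface waters. Managers face two families of
levers: changing the silvicultural system itself (continuous cover forestry,
longer rotations, or no management at all, instead of conventional rotation
forestry with clear-cuts), or intercepting the nutrients on their way to the
water body (sedimentation ponds, peak-runoff-control dams, wetland buffers,
riparian buffer zones). These cannot be compared empirically in one place
and time, so `borealnp` compares them by simulation: a stand register is
stepped through 50 years under a management system, every operation and the
drainage legacy of each peatland generate annual N and P export increments,
and a protection practice removes part of the load.

## Export model

### Drainage legacy

For each drained-peat compartment the August water-table depth (WTL, cm,
positive downward) is predicted every year from the growing-stock volume
$V$ (m^3^/ha), mean July--August monthly precipitation $S$ (mm), ditch depth
$D$ (cm, default 60) and latitude:

$$\mathrm{WTL} = 47.92 + 159.83\,(1-0.3^{V/90})
  - 30.684\,(1-0.3^{V/90})\ln S + 8.095 \ln D - 0.73\,\mathrm{LAT} - 0.185\,S$$

A mature stand transpires more, draws the table down, and accelerates
aerobic peat mineralization; the mineralized nutrients below the rooting
zone leave with the drainage water. The WTL-to-export mapping itself comes
from a process simulator whose curves are not published as equations, so the
package ships a monotone hinge surrogate per fertility class,
`export = slope * max(0, WTL - 30 cm)`, with slopes ordered by fertility
(herb-rich 0.055 to xeric 0.016 kg N/ha/yr per cm; P slopes about 7% of the
N slopes). The slopes were chosen once so that a mature synthetic register
averages 0.3--0.6 kg N/ha/yr of legacy export, the plausible band for such
landscapes, and they are replaceable via `legacy_response()` or
`legacy_response_from_yaml()`. Because the hinge is zero above 30 cm, a
freshly clear-cut peatland (volume near zero, shallow table) exports no
legacy nutrients until the new stand lowers the table again -- the
simulation therefore reproduces the characteristic collapse-and-recovery
pattern of legacy exports over a rotation.

### Operations

Short-term operation effects use export coefficients (kg/ha/yr by years
since treatment, year 1 = the treatment year): 10-year schedules for
mineral-soil clear-cuts and for ditch-network maintenance (DNM), a 2-year
N schedule for mineral fertilization, and a 5-year P schedule for wood-ash
fertilization of peatlands. DNM coefficients describe nutrients adhered to
suspended solids and are flagged particulate, which is what ponds and dams
can capture. Partial harvests on mineral soils are assumed export-free.

Harvests on drained peatlands are different: their annual export depends on
the removed stem volume $V_{cut}$ through logistic curves,

$$N_{harvest} = \frac{10}{1+e^{-(-3.3375+0.0164\,V_{cut})}}, \qquad
  P_{harvest} = \frac{1.3}{1+e^{-(-5.1772+0.0209\,V_{cut})}},$$

held constant for 6 years on fertile (mesic or better) and 4 years on
low-productive sites, regardless of the harvest method.

### Protection structures

* **Ponds and dams** retain only particulate DNM loads. The retained
  fraction saturates with the load above the structure:
  `0.40 * (1 - exp(-(L - 0.5)/2))`. The exponential form was chosen over a
  hyperbolic one so that the curve actually attains its 40% peak within the
  empirical load range; the dam's peak is not separately documented and
  mirrors the pond's (configuration, not data).
* **Wetland buffers** act on all forestry-induced exports of drained
  peatlands. The retained fraction is logistic in the forestry-induced load
  (background exports of 1.3 kg N and 0.025 kg P /ha/yr are subtracted
  first), exceeding 50% beyond 0.6 kg N/ha/yr and approaching 90%.
  Behaviour below 0.6 kg N/ha/yr extrapolates beyond the source data and is
  the model's most uncertain region.
* **Riparian buffer zones** retain a flat, load-independent 12% of mineral
  forestry exports at their 3% base coverage, plus 5 percentage points per
  doubling of coverage.

One practice per scenario; the ledger refuses double application.

## Stand dynamics surrogate

The quantitative content of the package is the export accounting; stand
dynamics only need to produce realistic harvest timing and volume
trajectories. The published individual-tree increment, survival and taper
models behind the original analyses are not reproducible from print, so the
package uses a deliberately simple diameter-cohort surrogate behind a
pluggable interface (`growth_params()`):

* annual diameter increment `g0 * f(fertility) * f(species) * (ts/1200) *
  exp(-0.035 BA)`, multiplied by 1.10 for planted and 1.05 for seeded
  stands (the tree-breeding benefit, applied exactly as a multiplier so the
  relative effect is testable);
* stem volume `v(d) = 2.5e-4 * d^2.3` m^3^;
* constant ingrowth of 15 stems/ha/yr into the smallest cohort;
* no explicit mortality (competition enters through the basal-area term).

Treatments are evaluated in the middle of each 10-year period, in the order
felling, thinning (or continuous-cover harvest), fertilization, DNM;
regeneration follows the felling immediately and tending is booked to the
following period. Thinnings remove half of the basal-area reduction as a
uniform percentage across cohorts and half from the smallest (rotation
forestry) or largest (extended rotation) cohorts, splitting the boundary
cohort fractionally (stems/ha are continuous, so the plan is
order-independent). The continuous-cover threshold basal area is the linear
surrogate `a + b * mean_d` (fertility-shifted, scaled by temperature sum
and discount rate) with defaults tuned once so stands cycle on roughly
15--25-year cutting intervals; the rule never clear-cuts.

Two rule details deserve a note because the sources leave them open:

* **DNM trigger.** Maintenance is tied to the rotation: a final felling
  arms a pending trigger, and the operation fires in a later period once
  the regenerated stand is inside the 5--30 cm / 10--40 m^2^/ha windows, at
  least 30 years have passed since the previous maintenance, and the
  growing stock is at most 150 m^3^/ha. Under continuous cover the trigger
  never arms, so those stands receive no DNM -- one of the system's selling
  points.
* **Mineral N fertilization** is restricted to one treatment per rotation
  (the stated outcome of the original parameterization); without this the
  interval and window rules alone would occasionally permit two.

## Synthetic catchments

`generate_catchment()` emulates the composition of a large
(3824 km^2^) boreal catchment: 40% mineral-soil forest, 31.5%
forestry-drained peatland, 21.1% undrained peatland, remainder non-forest.
Class areas are matched exactly by rescaling log-normally drawn compartment
areas; with the default 2000 compartments a "compartment" is therefore an
aggregated stratum rather than a 3-ha stand. Fertility shares per land
class are plausible placeholders (no fertility breakdown is documented for
the emulated landscape) and should be overridden when better data exist.
Initial mean diameters are drawn uniformly per fertility class (5--28 cm)
and structures are truncated-Weibull diameter distributions in 2-cm
classes; 10% of mineral compartments carry a pre-simulation clear-cut in
years -1 to -9, so the first period shows the residual exports of past
fellings even under no-management scenarios. Undrained peatlands and
non-forest are carried in the register but receive no management and
contribute no forestry-induced exports.

What the generator does **not** emulate: spatial structure and hydrological
routing, real stand registers, correlated site mosaics, demand-driven
harvesting, or inter-annual weather. Passing scenario orderings on these
synthetic registers therefore demonstrates the internal consistency of the
rule and export models, not a calibrated reproduction of any real
catchment's export magnitudes.

## Numerical choices

* Stand state advances in annual steps (Euler); the cohort increment
  changes by a few percent per year at most, and the class-table
  trajectory agrees with a continuous integration of the same increment
  model to well under 1% over a decade (tested).
* Mid-period events are dated to years congruent to 5 mod 10; coefficient
  year 1 falls in the event's calendar year, so five schedule years land in
  the treatment's own period.
* Retention fractions are evaluated on per-hectare loads of the
  contributing compartment (kg/ha/yr), summed per compartment, year and
  nutrient before entering the curve.
* Thinning plans clamp at zero stems and skip exhausted cohorts;
  continuous-cover removals cap at 90% per cohort with a fixed-point
  rescale to conserve the planned basal-area removal.
* Degenerate inputs fail loudly: zero precipitation or ditch depth are
  domain errors (logarithms), unknown category tokens are schema errors
  with row numbers, ERP on drained peat is rejected at validation.

## Problem sizes used by the test suite

The package's own acceptance checks run 20 seeded replicates of
2000-compartment catchments over 50 years (around 120 scenario runs) and
assert the qualitative orderings -- mineral accumulated exports
RF >= ERP >= CCF >= none; peatland RF with wetlands strictly below the
other RF protection variants; a positive period-wise harvest-export
association on peat under both RF and CCF -- together with exact
reproduction of every printed constant and 1e-9 agreement of the equations
with independent evaluations. These sizes were chosen as the smallest at
which the landscape-scale orderings are stable across seeds.

## Known limitations

* Legacy-response slopes and all retention-curve shapes are calibration
  placeholders behind documented interfaces, not fitted to data shipped
  with the package.
* Export magnitudes depend on the surrogate growth model's harvest volumes;
  only orderings and model-constant reproduction are tested.
* No suspended-solids mass accounting beyond the embedded DNM coefficients,
  no ditch-mounding exports, no restored-wetland transient source phase, no
  in-stream processes or water-quality classification, no combined
  protection practices, and no economic or wood-demand constraints.
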
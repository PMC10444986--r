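---
title: "Quantifying floral resources and pollinator visitation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying floral resources and pollinator visitation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florivis)
```

# The problem

Flower-visiting insects depend on two floral resources: nectar sugar
(carbohydrate) and pollen (protein). In plant communities invaded by alien
species, a handful of long-flowering, resource-rich aliens can dominate the
gross supply of both. Whether wild pollinators actually concentrate their
visits on those dominant suppliers — or instead spread visits over many
co-flowering species — determines whether gross resource quantity or
resource *diversity* is the quantity that conservation management should
protect.

`florivis` implements the full measurement-to-inference chain for that
question: converting raw field measurements into per-flower resource
values, scaling them to per-area availability, pooling availability and
insect visits into species contribution shares, modelling seasonal trends,
and comparing the Shannon diversity of resource-supplying versus
insect-visited flowering species. A seed-deterministic survey simulator
generates complete input bundles with known ground truth, so every stage of
the chain is testable end to end.

# From raw measurements to per-flower resources

**Nectar sugar mass.** A flower's standing nectar is extracted with a
microcapillary (volume $v$, µL) and its sugar concentration $C$ (g sucrose
per 100 g solution) read on a refractometer. Sugar mass in µg is

$$s = 10\,d\,v\,C, \qquad
  d = 0.0037921\,C + 0.0000178\,C^2 + 0.9988603,$$

where $d$ (g/mL) is the density of a sucrose solution at concentration
$C$ — the standard quadratic calibration used across floral resource
surveys. For flowers too small for direct extraction, the nectaries are
rinsed with 2 µL of distilled water and the same formula is applied to the
diluted solution ($v$ = rinse volume, $C$ = diluted reading). We apply no
correction for the nectar's own volume in the rinse dilution: the
measurement is treated as relative, and the same machinery is applied to
both methods. The refractometer domain is bounded at 85 g/100 g (the
physical limit of sucrose refractometry); the bound is configurable.

**Pollen volume.** All stamens of a flower are suspended in $U$ µL of
sucrose solution (30–1000 µL depending on flower size); two 10-µL aliquots
are counted under a microscope. Grains per flower are
$N = \bar{c} \cdot U / 10$ with $\bar{c}$ the aliquot mean. Grains are
modelled as prolate spheroids, $V = \tfrac{4}{3}\pi A B^2$ (µm³), with $A$
and $B$ half the species-mean major and minor axis lengths. Per-flower
pollen volume in µL is $N \cdot V / 10^9$.

**Species profiles.** Species means are unweighted arithmetic means over
samples, and pollen volume multiplies the species-mean grain count by the
species-mean grain volume (means before multiplication, matching the
standard protocol in which counts and grain sizes are measured on different
samples). Two conventions deserve emphasis:

* *Absence of a measurement is never zero.* A species with no nectar
  samples is flagged unmeasured (`NA`) and excluded from sugar totals; it
  can still contribute to pollen totals. The one exception is species
  without nectaries, whose sugar is zero by definition.
* No flower-age or depletion correction is applied — a deliberate,
  documented simplification; the values are relative comparisons between
  species, not absolute productivities.

# Availability, contributions, diversity

Per-plot availability multiplies each species' open floral-unit count
(heads for composites and clover, individual flowers otherwise, always per
1 m²) by its per-flower mean; plot totals sum over measured species.
Contribution shares pool raw totals over all plots of a site within a
period (calendar month or study year) and divide by the pooled grand
total. Annual shares always pool raw year totals — never averages of
monthly proportions — so months with two survey occasions simply
contribute both occasions, with no reweighting.

Diversity of a share vector is Shannon's
$H' = -\sum_i p_i \ln p_i$ (nats), with evenness $J' = H'/\ln S$. The
annual panel carries six categories per site and year: Sug and Pol
(species shares of nectar sugar and pollen supply) and AP, WB, HF, BF
(shares of all-insect, bee/wasp, hoverfly and butterfly visits).
Differences in $H'$ between categories are tested within a year by a
one-way Tukey HSD with sites as replicates — the only replicate unit the
design supports; the error structure beyond that is not specified by the
protocol, so the choice is deliberately plain and is stated here rather
than hidden. For evenness the denominator uses the category's own
nonzero-share richness by default; a `site_total` mode (union richness of
all categories at the site and year) is available because published
summaries are ambiguous between the two; the pipeline logs the mode used.

Visit records of European honeybees (a managed species) and of Coleoptera
and Hemiptera (too scarce for inference) are removed before any analysis,
with removed counts logged per group.

# Seasonal trend models

Per site, seasonal trends are generalized additive models with one
penalized thin-plate spline smooth of census day (days since the site's
first survey) spanning both study years, basis dimension $k = 10$
(reference df ≈ 9):

* **Resources** (sugar µg/m², pollen µL/m² per plot × occasion): the
  response is value + 0.0001 with a gamma error distribution and log link —
  the offset admits the exact zeros that winter occasions produce.
  Smoothing parameters are selected by GCV (the stack's classical default
  for this family).
* **Visits** (counts per plot × occasion, per group and pooled): negative
  binomial with log link; theta is estimated during fitting, which
  requires an ML-type criterion, so these fits use REML.

Both the basis dimension and the criterion are arguments, not constants.
The analysis unit is the plot × occasion observation, not site means.

Numerical/degenerate-input rules: a response with zero variance (all-zero
or constant series) carries no seasonal information and the gamma
likelihood degenerates under smoothing-parameter selection, so the fit
short-circuits to the intercept-only limit (flat prediction at the mean,
smooth p-value 1). All-zero count series are returned as flagged unfitted
objects rather than errors. Designs with fewer than 3 distinct census days
or fewer than 20 observations are refused. Fitted-curve peaks are interior
strict local maxima of the one-day prediction grid, with maxima below 5%
of the curve's range above its minimum discarded as noise.

# What the simulator emulates

`simulation_config()` defaults encode the survey structure the analysis
assumes: 4 sites × 5 plots of 1 m², two study years (21 Apr 2018 –
13 Apr 2019, then to 4 Apr 2020), 2-week survey intervals in year 1 and
monthly intervals in year 2. The default community
(`default_archetypes()`) has 29 species: 4 long-flowering
(210–280 days) resource-rich aliens — the dominant one supplying roughly
0.6 of annual sugar and pollen — and 25 shorter-flowering natives with
staggered peaks, one flowering in winter. Counts are negative-binomial
draws around Gaussian-in-time phenology curves (zero outside the flowering
window, $\sigma$ = duration/5), giving the bimodal community availability
profile (late-spring/early-summer and autumn peaks) typical of these
riverbanks. Measurement tables are drawn so the pipeline recovers the true
species means: log-normal per-flower sugar re-expressed as
volume + concentration (or rinse readings, obtained by numerically
inverting $s = 10\,d\,C\,v_\text{rinse}$), Poisson aliquot counts around
the true grain number, and Gaussian axis lengths. Default sample sizes
(18 nectar, 9 pollen per species) match the emulated study's means.

Visits are the scientifically interesting part. Group totals per plot ×
occasion are negative binomial around bimodal seasonal activity curves
(normalized within study year; expected total 10⁴ visits per site-year at
default), and allocated among the plot's flowering species by one of three
regimes operationalizing the competing hypotheses:

* `resource_proportional` — hypothesis 1: weights equal the mean of the
  species' sugar share and pollen share of plot availability (the mean of
  shares is used because µg of sugar and µL of pollen are not summable
  units), and plots attract visitors in proportion to their resource
  share, so insects aggregate where and on what resources are.
* `even_preference` — hypothesis 2: weights are flat preference weights
  over co-flowering species, blind to resource content.
* `native_biased` — even preference with native weights inflated by a
  configurable factor.

Under `resource_proportional`, annual visit shares converge to annual
resource shares when insect activity tracks community resource phenology;
the default activity curves are therefore aligned with the default
community's bimodal resource curve, and the diversity gap
$\Delta H = H'(\text{AP}) - \tfrac{1}{2}(H'(\text{Sug}) + H'(\text{Pol}))$
is near zero. Under `even_preference` the visited-flower diversity rises
to near $\ln$(number of co-flowering species) while the supply stays
dominated, producing the large positive gap that is the headline pattern
the pipeline is designed to recover. Honeybee/Coleoptera/Hemiptera rows
are emitted at a low rate purely to exercise the exclusion filter.

What the simulator does *not* emulate: pollinator species identity and
trait-based preferences (colour, morphology), nectar depletion and
flower-age effects, spatial autocorrelation between plots, weather-driven
missingness, and observer effects. Passing the recovery tests therefore
shows the inference chain is correct under the stated generative
assumptions, not that real communities satisfy them.

# Problem sizes and calibration checks

The test-suite checks use sizes chosen to make the stochastic assertions
sharp at reasonable cost: 50 simulated two-year surveys per visitation
regime for the diversity-gap recovery (expecting
$H'(\text{AP})$ highest in ≥ 90% of runs under `even_preference`, and
$|\overline{\Delta H}| < 0.15$ under `resource_proportional`); 200
iid negative-binomial null series of 150 observations for the smooth-term
type-I error (accepted within [0.01, 0.12] at $\alpha = .05$); 100
planted-bimodal series for peak recovery within ±20 days; 1000 random
inputs per formula against brute-force oracles (tolerance 10⁻⁹); and 100
random 6-group × 4-replicate layouts for agreement of the Tukey HSD
p-values with a direct studentized-range computation (tolerance 10⁻⁴).

# Known limitations

* Resource values are relative: the 2-h accumulation protocol the nectar
  numbers assume underestimates absolute productivity by design.
* The Tukey comparison treats sites as exchangeable replicates and years
  separately; repeated measurement of the same sites across years is not
  modelled.
* Evenness for a category observed with a single species is undefined
  (ln 1 = 0) and returned as `NA`, not 0.
* The simulator's survey calendar is shared across sites; site-specific
  gaps (e.g. mowing closures) can be emulated by deleting rows, which the
  I/O layer treats as absent occasions, never as zeros.
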
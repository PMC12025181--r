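---
title: "Functional-group succession and stability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-group succession and stability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytofg)
```

`phytofg` analyses monthly multi-site phytoplankton surveys at the level of
Reynolds/Padisák functional groups. This vignette documents the statistical
procedures, their assumptions, the numerical conventions adopted where the
field literature is ambiguous, and the design of the synthetic survey
generator used to validate the pipeline.

## Data model

The raw input is a long table of cell densities (cells/L) per
`(site, date, taxon)` with per-taxon metadata (phylum, mean cell volume in
µm³, optionally a functional-group code), plus an environmental table of
eight routine water-quality variables (WT °C, pH, DO mg/L, Secchi depth m,
TN, TP, NH₃-N and COD~Mn~ mg/L). Dates are stored to day precision; the long
format is canonical on disk, dense matrices live only in memory. Missing
environmental cells are retained as `NA`, never imputed: downstream
statistics drop incomplete samples and report how many, the conservative
default for monitoring data of uneven completeness.

## Classification and biomass

Taxa are classified against the packaged 27-group trait catalog. An explicit
code in the metadata always wins; otherwise the taxon name is matched
case-insensitively against the catalog's representative taxa, first as a full
name and then at genus level (leading token). Genus-level matching is the
right default because trait catalogs list mostly genera ("*Cyclotella* sp."),
but it cannot resolve genera that legitimately span groups; survey-specific
overrides in the metadata are the supported escape hatch. Unmatched taxa get
the sentinel `UNASSIGNED` and are reported rather than dropped, so
classification coverage is always visible.

Biomass uses the standard biovolume conversion at unit cell density:
1 µm³ of unit-density matter weighs 10⁻⁹ mg, so
`mg/L = cell volume (µm³) × abundance (cells/L) × 10⁻⁹`. The `density`
argument is a dimensionless factor defaulting to 1; unit algebra is the only
reading under which the conventional formula yields mg/L. Group biomass is
the sum over member taxa — a partition, so total biomass is conserved
regardless of grouping.

## Dominance

The McNaughton index for a species over an evaluation scope of samples is
`Y = (Nᵢ/N)·fᵢ` with `Nᵢ` the species' summed abundance, `N` the all-species
total, and `fᵢ` its occurrence frequency. Two conventions needed fixing:

* `fᵢ` is the fraction of *scope samples* (site × occasion) with strictly
  positive abundance. This is the standard per-sample reading and reduces to
  per-site frequency when the scope is a single date.
* Thresholds follow the field wording exactly: dominant at `Y ≥ 0.02`,
  absolutely dominant at `Y > 0.1` (the latter implies the former).

The scope is a required argument in spirit: dominance over one year and over
a whole study differ, so `dominance()` takes an explicit sample subset.

Dominant *functional groups* use a different rule: share of
stratum-aggregated biomass strictly exceeding 5.00 %. Shares are computed on
pooled biomass, not as means of per-sample shares, matching how "% of total
biomass" is conventionally reported per year or site.

## Succession rate

For consecutive occasions `a < b` at one site,
`SR = Σᵢ |f_ib − f_ia| / (b − a)` per day, where `f` is group relative
biomass and the sum runs over the union of groups present at either
occasion. The definition is a total-variation distance scaled by time, so
`0 ≤ SR ≤ 2/Δt`; `Δt` is taken from the actual sampling dates in calendar
days, never a nominal 30. Printed forms of this statistic sometimes carry an
integral sign and mention the species count `n`; the quantity itself is a
finite sum over discrete groups and contains no `n`-normalisation, and that
is what `succession_rate()` computes. Aggregation (`aggregate_sr()`)
attributes each interval to the calendar month or year of its endpoint `b`
and averages arithmetically; "spatial SR" is the per-site mean of temporal
interval SRs, not an along-river site-to-site difference. Group scope
defaults to all groups (`series_sr(..., groups =)` restricts it), since
restricting to dominant groups is a reporting choice, not part of the
statistic.

## Average variation degree

For a stratum of `k ≥ 2` samples, each group `i` with positive sample
standard deviation `δᵢ` contributes `a_ij = |x_ij − x̄ᵢ| / δᵢ` per sample
`j`, and `AVD = Σᵢ Σⱼ a_ij / (k·n)` with `n` the number of contributing
groups. Numerical conventions:

* The absolute value is essential: without it the inner sum is identically
  zero and the index is vacuous.
* `δᵢ` defaults to the `n−1` sample standard deviation
  (`sd_denominator = "n"` gives the population form; the latter is exactly
  invariant under duplicating every sample).
* Zero-variance groups are excluded from numerator *and* `n` and are
  reported. They carry no information about variability; counting them in
  `n` would let absent groups dilute the index arbitrarily.
* AVD is computed on functional-group biomass by default (`measure =
  "relative"` or a user-aggregated abundance matrix are alternatives),
  because the stability question is posed at group level while the index's
  definition speaks of species abundance — both are supported.

`1 − AVD` is reported alongside as a stability score (higher = more
stable). AVD is scale- and location-invariant per group, so unit changes and
baseline shifts cannot move it.

## Community–environment statistics

* **Distances.** Bray–Curtis for community matrices (undefined for all-zero
  rows, which are an error), Euclidean for (standardised) environmental
  matrices. Computed by `vegan::vegdist()`.
* **PCA.** Centered, optionally z-scored; the variance share of a component
  is its eigenvalue over the eigenvalue total, so shares sum to 1.
* **Mantel.** Pearson correlation (Spearman by flag) of the vectorised
  distance triangles; one-sided permutation p with the +1 correction,
  `p = (#{r* ≥ r} + 1)/(n_perm + 1)`, default 999 permutations, seed
  required. Delegated to `vegan::mantel()` after seeding.
* **Dispersion.** Principal-coordinate embedding with the standard
  correction for negative eigenvalues, distances to *group centroids* (not
  spatial medians — deterministic and matching the classical ANOVA oracle),
  one-way F on those distances, permutation p over group labels
  (`vegan::betadisper()` + `permutest()`).
* **Hierarchical partitioning.** For every subset `S` of predictors,
  `R²(S)` is the explained-variance fraction of the multivariate linear
  model of the transformed community matrix on `S` (the RDA trace ratio);
  the individual contribution of predictor `j` averages its `R²` increment
  over all orderings (Chevan–Sutherland), computed with exact subset-size
  weights from the `2^p` table (hence the `p ≤ 12` guard). Individual
  contributions sum to the full-model `R²` by algebraic identity; joint
  contribution is `R²({j}) − individual(j)`. Negative individual values are
  reported with a flag, never truncated: truncation silently breaks the
  decomposition identity. The community transformation defaults to Hellinger
  (square-root of relative abundance), the standard pre-transformation for
  abundance RDA; `log1p` and `none` are available since the convention is
  not universal. Unadjusted `R²` is reported; adjusted variants answer a
  different question and are out of scope.

Random-forest variable importance and partial-least-squares path modelling,
which often accompany these analyses, are deliberately not implemented: they
are off-the-shelf procedures, and the package instead exposes the prepared
response/predictor tables (`align_samples()`, `compute_biomass()`) that such
tools consume.

## The synthetic survey generator

`simulate_reservoir()` emulates the study design the pipeline targets: 5
sites sampled monthly for 48 months, 95 taxa across 7 phyla with a
realistic mix (45 % Chlorophyta, 26 % Bacillariophyta, 18 % Cyanophyta, the
rest split evenly), an annual water-temperature cycle spanning 7.1–28.3 °C,
and one high-nutrient, high-variability headwater site. Mechanisms, chosen
as the minimal set that creates succession and site contrast:

* **Temperature.** A skewed annual cycle — minimum in February, maximum in
  July, i.e. a 5-month warming limb and a 7-month cooling limb, as in
  monomictic reservoirs where spring warming outpaces autumn cooling — plus
  month-to-month noise. The skew is what makes spring succession faster
  than autumn succession, a pattern the generator is expected to reproduce.
* **Taxon responses.** Gaussian thermal niches (optimum and width per
  taxon) and Monod (saturating) responses to TN, with lognormal baseline
  abundances and per-phylum lognormal cell volumes. Expected abundance is
  the product of baseline, thermal and nutrient responses.
* **Noise structure.** This is the load-bearing design choice. The mean
  absolute standardised deviation that AVD measures *decreases* with iid
  multiplicative noise: heavier-tailed series concentrate their standard
  deviation in spikes, so simply giving a disturbed site "more noise" makes
  it look *more* stable, while the succession rate moves the other way.
  The generator therefore separates two channels:
  * quiet sites receive mostly **synchronous** community-wide lognormal
    pulses (hydrology and mixing acting on all taxa at once, sdlog 1.0)
    plus small idiosyncratic noise (sdlog 0.25). Synchronous variation
    produces spiky per-group series (low AVD) yet cancels in relative
    biomass (low SR) — the signature of a stable, externally forced
    community;
  * the headwater receives larger **idiosyncratic** noise (sdlog 0.5), a
    weak synchronous channel (0.3), a flattened thermal gate
    (nutrient-replete growth continues outside the optimum: niche floor
    0.5, widths 6–10 °C vs 2–4 °C elsewhere) and, crucially,
    **asynchronous per-taxon bloom episodes**: two-state Markov chains
    (on-probability 0.45, stay-probability 0.5, i.e. ~2-month persistence)
    multiplying abundance by 5.5 while on. Sustained, balanced excursions
    raise each group's mean standardised deviation (high AVD) and every
    episode boundary reallocates composition (high SR).

  With these defaults the headwater ranks first among the five sites in
  both mean AVD and mean SR in ≈98 % of seeded replicates — the directional
  property the acceptance suite checks — while its *total* noise magnitude
  remains the largest, as a disturbed site's should be.
* **Environment.** TN/TP/NH₃-N/COD~Mn~ scale with a per-site nutrient
  multiplier (2.5 at the headwater), TN additionally carries a May-centred
  spring loading pulse; Secchi depth scales inversely with nutrients.
* **Bookkeeping.** Abundances below a 100 cells/L detection limit are
  recorded as zero, giving realistic absences for occurrence frequencies.
  A single seed drives everything; the same seed reproduces the tables
  exactly, and the drawn parameters are returned as a `truth` object for
  recovery tests.

What the generator does **not** emulate: hydrodynamic transport between
sites, biotic interactions (grazing, competition beyond share reallocation),
multi-year trends, observation (counting) error as distinct from process
noise, and any calibration to a specific real reservoir beyond the printed
environmental ranges. Passing tests on synthetic data therefore demonstrate
that the statistics recover structure *of the kinds modelled here*, not that
any particular field estimate is correct.

## Testing strategy and problem sizes

Every formula-level statistic (SR, AVD, dominance Y, Bray–Curtis, the
dispersion F, hierarchical-partitioning contributions) is checked against an
independent brute-force oracle — plain loops over the definitions — on at
least 100 random small instances at 10⁻⁹ tolerance, alongside exact
hand-computed cases and property suites (bounds, symmetries, invariances,
the coarsening inequality for SR, the decomposition identity for
hierarchical partitioning). The Mantel test's type-I error is verified
empirically (200 independent replicates at n = 20 with 999 permutations,
rejection rate required inside 0.05 ± 0.03), and the generator's directional
property over 100 seeded replicates of the full default configuration. These
sizes keep the complete suite around a minute on a single core while leaving
each check statistically meaningful.

## Known limitations

* Genus-level classification cannot express within-genus group splits
  without explicit per-taxon overrides.
* `fᵢ` and dominance depend on the chosen scope; no scope is privileged by
  the package, and results are only comparable across identical scopes.
* Hierarchical partitioning enumerates `2^p` subsets; beyond ~12 predictors
  a sampling approximation would be needed and is not provided.
* Permutation p-values inherit the `1/(n_perm+1)` resolution floor.
* AVD compares strata fairly only when their sample counts are similar;
  the index has no small-sample correction.
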
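---
title: "Estimating phytoplankton assemblages from multi-excitation fluorescence"
author: "fluorotax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phytoplankton assemblages from multi-excitation fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorotax)
```

## The problem

Phytoplankton community composition — which algal groups carry the
chlorophyll-a biomass — shapes marine food webs and element cycles, but the
standard way of measuring it (HPLC analysis of marker pigments on discrete
water samples) is slow and depth-sparse. A submersible multi-wavelength
excitation fluorometer (MEX) records chlorophyll fluorescence excited by nine
LEDs (375, 400, 420, 435, 470, 505, 525, 570 and 590 nm) at 10 Hz while
profiling, because different accessory-pigment systems absorb these
wavelengths differently: fucoxanthin-containing brown groups respond strongly
in the blue, the peridinin–chlorophyll protein of dinoflagellates around
480–510 nm, and the phycobilins of cyanobacteria at 570/590 nm. `fluorotax`
implements an empirical two-step conversion from such nine-channel spectra to
nine chemotaxonomic groups (diatoms, haptophytes types 3 and 4,
dinoflagellates, cryptophytes, prasinophytes, chlorophytes, cyanophytes,
prochlorophytes), together with the machinery to build and validate the
reference database the conversion relies on, and a pipeline from raw casts to
water-column-integrated group biomass.

## Pigment chemotaxonomy

The reference compositions come from marker pigments. Each group g has a
characteristic pigment:chlorophyll signature (row of the ratio matrix `R`,
pigment units per 100 units chlorophyll-a; `defaultRatioMatrix()`). Given the
eleven marker-pigment concentrations `b` of a sample,
`estimateComposition()` solves

    min_{x >= 0} || b - x' R/100 ||_2

for the group chlorophyll vector `x` by non-negative least squares
(Lawson–Hanson, via `pracma::lsqnonneg`) and reports fractions `x / sum(x)`.
The ratio matrix is held fixed — no CHEMTAX-style iterative ratio
re-optimisation — and the misfit is computed on raw concentrations (µg/L),
unweighted. Whether a concentration or a chlorophyll-normalised misfit is
preferable is genuinely open; the concentration choice is the simpler one and
is what the recovery guarantees in the test suite are stated for. Neoxanthin
and lutein are carried in pigment tables but have no ratio-matrix column and
do not enter the fit. An all-zero pigment vector yields an explicit
"undefined composition" error rather than NaN fractions.

## TChla calibration

Total chlorophyll-a (TChla = monovinyl + divinyl) is recovered from the raw
435 nm channel through a zero-intercept robust regression
(`fitRobustZeroIntercept()`): Tukey bisquare M-estimation (tuning constant
4.685) with scale from the MAD of residuals, iterated to a relative slope
tolerance of 1e-8. The zero intercept guarantees non-negative predictions.
Bisquare weights vanish exactly for gross outliers, so the outlier rule —
final weight below 1e-3 — is sharp; flagged samples are excluded from the
reference database. The iteration cap is 200: bisquare IRLS converges
linearly and contaminated data routinely need beyond 100 iterations to reach
the 1e-8 tolerance. The slope standard error is the asymptotic sandwich
estimate on the final weights, and r² is computed through the origin on
non-outlier points (1 − SSres/SSy, uncentred), a convention that is stated
here because zero-intercept r² definitions differ between packages.
`selectCalibrationChannel()` fits every channel and returns the highest-r²
one, breaking exact ties toward the shorter wavelength.
`publishedCalibration()` carries the deployed conversion
TChla = 0.54095 × F435nm (SE 0.02205, r² 0.8844, n = 271) for use when no
site-specific calibration exists.

When pairing bottles with cast data, the bottle depth is matched to the
nearest 1-m bin within ±1 m (`matchBottleDepths()`); the tolerance is
configurable because the pairing convention is not standardised.

## Spectral decomposition and reconstruction

Every spectrum is first standardized to sum 1 (`standardizeSpectrum()`), so
shape, not intensity, carries the taxonomic signal. The reference database
`U` pairs each standardized spectrum `F_i` with its pigment-based composition
`P_i`. A target spectrum `f` is decomposed (`decomposeSpectrum()`) as

    f ≈ sum_i alpha_i F_i,   0 <= alpha_i <= 1,

with the coefficients chosen to minimise the Euclidean residual. Only the
box bounds are imposed — no simplex constraint — but because both `f` and all
`F_i` sum to one, any near-zero-residual solution has coefficients summing
to ≈ 1 automatically. The composition is reconstructed
(`reconstructComposition()`) as `p = sum_i alpha_i P_i`, renormalized to sum
to 1; the raw coefficient sum is kept as a diagnostic, since values far from
1 flag targets poorly covered by the reference span. TChla_MEX is taken from
the *raw* 435 nm channel (the calibration was fitted on recorded
fluorescence), so scaling a spectrum scales TChla_MEX proportionally and
leaves the composition untouched.

The box-constrained solver is a projected quasi-Newton iteration (L-BFGS-B
with analytic gradient, zero start, tight tolerances) followed by an
active-set polish that re-solves the free coordinates exactly by
minimal-norm least squares, pinning any coordinate the exact solve pushes
past a bound. The objective is convex, so the polish cannot leave the global
minimum; the zero start makes the returned solution deterministic. With more
references than channels the minimiser is not unique: near-duplicate
reference spectra are deliberately *not* deduplicated, the solver's
deterministic choice is accepted, and the reconstruction is stable exactly
insofar as collinear references carry similar compositions. The largest
pairwise correlation among references that receive weight is reported as a
diagnostic, and the test suite pins the unique-solution case (databases with
at most nine records) to machine precision against a grid-search oracle.

## Validation machinery

Two cross-validation designs probe the conversion. Leave-one-out
(`loocvConversion()`) removes, for each target, *all* records sharing its
(cruise, station, depth) key, so replicate bottles from the same water never
inform their own estimate. Leave-area-out (`leaveAreaOutConversion()`)
converts each record using only references from other areas, testing
transfer across water masses. `comparisonStats()` summarises agreement per
group on the percent scale: OLS slope, t, p, r², mean absolute difference,
and a 95% interval half-width of the differences. Both a percentile
(2.5/97.5) and a normal (1.96 sd) half-width are reported; the percentile
version is primary because difference distributions are routinely skewed.

`bootstrapSensitivity()` resamples each target's leave-one-out reference set
with replacement (unit of resampling: the record), converts the target
against each replicate, and reports the per-group coefficient of variation
(CV, %) of the estimates, aggregated as mean, sd and mean + 2 sd per group.
Small values mean the conversion does not hinge on a handful of reference
records. `permanovaFluorescence()` quantifies how much compositional
variance the nine channels explain: sequential (type-I) PERMANOVA on
Bray–Curtis distances, terms in wavelength order, via `vegan::adonis2`.

Because individual green-lineage groups are hard to separate optically,
`aggregateGroups()` provides the standard merges: chlorophytes +
prasinophytes + both haptophyte types as *eukaryotes*, and cyanophytes +
prochlorophytes as *cyanobacteria*.

## Profile pipeline

Raw casts are segmented into *observations* — maximal runs at sensor depth
≥ 2 m lasting ≥ 300 s (`segmentObservations()`); "lasting" is read as run
duration, and any shallower record breaks a run (a gap tolerance is exposed
but defaults to 0 s). Spikes are removed by per-second medians
(`medianResample1s()`; even windows use the midpoint-average convention).
`binProfile1m()` averages the 1-s records into half-open 1-m bins [k, k+1)
from 2 m down — a record at exactly 3.0 m belongs to [3, 4) — and converts
each bin-mean spectrum. Down- and up-cast records within an observation are
binned together.

Vertical heterogeneity of a group's proportion is the quartile coefficient
of dispersion, QCoD = (Q3 − Q1)/(Q3 + Q1), with quartiles by linear
interpolation (quantile type 7 — stated because QCoD is sensitive to the
quartile convention). Across a set of profiles the high-heterogeneity
threshold is mean + 2 sd of all defined QCoD values
(`heterogeneityReport()`); undefined QCoDs (Q1 + Q3 = 0, i.e. absent groups)
are excluded from the summary with their count reported.

`integrateWaterColumn()` integrates fraction × TChla_MEX per group by the
trapezoidal rule on the bin grid (µg/L over m, hence mg/m²), linearly
interpolating missing bins and holding edge values constant beyond the
outermost bins; using one common grid for all groups makes group integrals
sum *exactly* to the TChla integral. `stationSimilarity()` embeds the
integrated group shares by two-dimensional NMDS (Kruskal stress-1, monotone
regression, 20 seeded random restarts, best fit returned) on Bray–Curtis
dissimilarities.

## The synthetic-data generator

Everything above is testable without field data through `simulateReferenceDb()`
and `simulateCast()`. The generator's structural choices matter, so they are
stated here.

**Compositions.** Samples are convex mixtures of four community archetypes
(`communityArchetypes()`): a diatom-bloom community, an oligotrophic
picocyanobacterial community, a green/nano-flagellate community and a
dinoflagellate–cryptophyte coastal community. Per sample, archetype weights
are drawn from an area-specific Dirichlet (diatom-heavy subarctic areas, a
prochlorophyte-heavy subtropical area, a small-eukaryote-heavy marginal-sea
area) and multiplied into the archetype matrix. This places compositions on
a low-dimensional manifold with strong between-group covariance — the way
field assemblages behave under succession — rather than filling the
nine-group simplex uniformly. The manifold structure is not incidental: the
reference-decomposition method estimates a target as a bounded combination
of reference records, so it can only recover compositional variation that
the reference cloud covers. A full-dimensional Dirichlet cloud at realistic
sample sizes has essentially every point on its own convex hull, which
guarantees systematic shrinkage for every sample no matter how many
references exist; on the archetype manifold, interior targets are covered
and the noiseless pipeline closes (leave-one-out slopes 0.97–1.00 at
n = 200).

**Spectra.** Group endmembers (`makeEndmemberSpectra()`) are synthetic
Gaussian-mixture shapes over the nine channels — *not* measured excitation
spectra — constrained by the qualitative bio-optics above: all groups excite
in the blue; dinoflagellates carry an elevated 505 nm response relative to
diatoms; cyanophytes and prochlorophytes are elevated at 570/590 nm;
haptophytes, prasinophytes and prochlorophytes differ in the UV channels;
chlorophytes are green-shifted (stronger 470–480 nm response relative to
435 nm) as chlorophyll-b systems are. A small seeded lognormal jitter (2%)
keeps the matrix well conditioned; pairwise correlations are checked below
0.999 at generation time (the realised maximum is ≈ 0.92). A sample's raw
spectrum is the composition-weighted endmember mixture × TChla × instrument
gain with multiplicative lognormal channel noise.

**Noise defaults.** Spectral channel noise is 5% (the stress level at which
the end-to-end recovery properties are stated); pigment noise is 2%,
matching routine HPLC replicate precision. TChla is log-uniform on
0.05–5 µg/L, spanning oligotrophic surface water to bloom conditions. The
default reference size is 271 samples over 4 areas.

**What the generator does not emulate** — and hence what green tests do not
establish about real data: optical pathologies (quenching at depth, red
CDOM/detritus fluorescence, scattering), pigment packaging and physiological
ratio plasticity (the fixed Table-2-style ratios are themselves an
approximation on real samples), within-group spectral diversity,
peridinin-lacking dinoflagellates (invisible to pigment chemotaxonomy), and
instrument drift between sensors. On field data the published workflow
reports R² ≈ 0.33 of compositional variance explained by fluorescence; the
synthetic endmembers are more distinct than reality at the hard pairs
(diatoms vs haptophytes), so recovery slopes here are an upper bound on
field performance, not a promise.

**Casts.** `simulateCast()` descends at constant rate (default 0.25 m/s)
through user-defined layers, with an optional Gaussian subsurface
chlorophyll maximum and optional multiplicative spike contamination for
median-filter tests. Layers may not overlap; all generators are fully
deterministic given their seed.

## Numerical and design notes

- Problem sizes in the shipped tests (reference databases of 25–271
  records, 200 type-I-error simulations at n = 50 with 199 permutations,
  bootstrap at R = 20–30) were chosen so the full suite runs in about a
  minute while still exercising every property at paper-like structure;
  the statistics scale unchanged to larger inputs.
- The acceptance script (`scripts/acceptance.R`) takes a `--seed` so every
  stochastic step is reproducible; identical seeds give bitwise-identical
  bootstrap and simulation output.
- Degenerate inputs are errors, not silent NaNs: all-zero spectra and
  pigment vectors, empty reference views, single-area leave-area-out,
  Q1 + Q3 = 0 QCoDs (flagged NA with a warning).
- The 95% CI convention for validation differences (percentile vs normal)
  and the zero-intercept r² convention are both documented rather than
  asserted, since the field literature is not explicit about either.

## Limitations

The conversion interpolates within its reference database; it cannot
extrapolate to assemblages or optical conditions unlike anything in the
references, and leave-area-out validation should be run before trusting
transfer to a new region. Prochlorophytes and cyanophytes are spectrally
similar in real phycobilin signals; merged *cyanobacteria* estimates are
more trustworthy than the split. The TChla conversion ignores
non-photochemical quenching, so near-surface daytime biomass can be
underestimated on real casts.
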
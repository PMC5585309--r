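---
title: "Methods: models, estimators and design choices in daisynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in daisynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daisynet)
```

`daisynet` analyses the synaptic connections of the patchy ("daisy")
lateral projections of superficial-layer pyramidal cells in columnar
visual cortex. This vignette documents the models the package implements,
the estimators and their assumptions, the tunable parameters, and the
places where the design was genuinely open and a choice had to be made.

## Orientation maps and the Similarity Index

### Preference maps

A `condition_stack` holds one response image per stimulus orientation
(typically the eight grating orientations 0°, 22.5°, …, 157.5°).
`cocktail_blank_map()` normalises one condition by the sum of all
conditions (the cocktail blank), or by the orthogonal condition
(differential map). `preference_map()` applies the standard vector-average
construction on doubled angles: orientations are circular with period
180°, so each response $r_k$ at stimulus angle $\theta_k$ contributes a
vector at $2\theta_k$,

$$R = \sum_k r_k e^{i 2\theta_k},\qquad
\hat\theta = \tfrac{1}{2}\arg R \in [0^\circ, 180^\circ),\qquad
m = |R| \Big/ \sum_k r_k .$$

The ratio normalisation makes the map invariant to a positive gain
applied to all conditions; a common additive offset leaves the angles
untouched and only deflates the magnitude. For responses of the form
$r(\theta) = 1 + \cos 2(\theta - \theta_0)$ sampled at the eight standard
angles the vector sum is exactly $4 e^{i2\theta_0}$, so the construction
recovers $\theta_0$ to machine precision; the suite asserts recovery
within 0.5° across all integer $\theta_0$. Pixels with vanishing
resultant (e.g. equal responses to all orientations) carry magnitude 0
and an undefined (`NA`) angle rather than an arbitrary one.

`sample_map()` uses nearest-pixel lookup, not interpolation: the
similarity index aggregates over many points, interpolation is immaterial
at that scale, and nearest-pixel is bit-reproducible.

### The Similarity Index

`domain_angle()` defines the orientation domain of a point set (dendritic
nodes or bouton positions) as the magnitude-weighted circular mean of the
sampled pixel orientations, again on doubled angles. `similarity_index()`
is then

$$\mathrm{SI} = 1 - \Delta / 90,$$

with $\Delta \le 90^\circ$ the acute angular difference between the two
domain angles. This fixes SI = 1 for identical orientation tuning and
SI = 0 for orthogonal domains, is symmetric in its arguments, and is
invariant under joint rotation of both domains. The exact weighting used
in the original index cannot be recovered from the source material —
only its endpoint behaviour is characterised — so the linear-in-$\Delta$
form on magnitude-weighted domain means is this package's documented
choice; any monotone alternative agreeing at the endpoints would order
clusters identically. Degenerate inputs (all sampled magnitudes zero, or
an exactly vanishing resultant from antipodal cancellation) raise errors
rather than returning arbitrary angles. `classify_si()` applies the
extreme bands used for target analysis: similar above 0.65, dissimilar
below 0.35.

## The random-walk null model

`run_walk()` asks how much between-cluster variance in the smooth-target
fraction is expected if synapse formation is purely opportunistic. A
virtual axon starts at a uniform random interior point of a neuropil cube
with uniform random direction and performs a persistent random walk: at
each step the new direction is drawn from a von Mises–Fisher distribution
concentrated around the previous one. Every not-yet-consumed candidate
site within the capture radius of the new position is scored as a synapse
(nearest first), and a replicate ends when the experimentally observed
synapse count is reached.

Parameters, defaults, and rationale:

| parameter | default | units | rationale |
|---|---|---|---|
| `cube_um` | 500 | µm | neuropil volume of the study's simulation |
| `capture_radius_um` | 1 | µm | scoring distance to a target site |
| `n_reps` | 10000 | – | replicates per simulation |
| `step_um` | 1 | µm | growth-cone scale step |
| `persistence_kappa` | 20 | – | vMF concentration; mean turning ~18°/step, honouring the near-straight trajectories of real collaterals |
| `max_steps` | 10⁶ | – | termination guarantee; truncated replicates are counted, never dropped |

The bias mechanism, step size and boundary rule of the original
simulation are unstated; the persistent walk with reflecting boundaries
is this package's parameterisation (reflection keeps site density
constant near the walls without wrap-around artifacts), and all of it is
configurable. Targets are consumed on capture — one synapse per
anatomical site. Capture is class-blind; soma and spiny-shaft sites score
as spiny and only smooth-shaft sites as smooth, mirroring the
experimental spiny/smooth dichotomy.

Because capture never consults the class label and labels are i.i.d.,
the number of smooth synapses per replicate is exactly
$\mathrm{Binomial}(n_\mathrm{stop}, \hat f)$ with $\hat f$ the realised
smooth fraction of the field — an exact oracle the suite tests by
chi-square at 10,000 replicates. One caveat governs that test's design:
replicates share one field realisation, so if total captures approach the
pool size the same sites recur across replicates and the aggregated
histogram is over-dispersed relative to independent binomials (a test
artefact, not a simulator defect — the per-replicate law is still
binomial). The oracle tests therefore use a 100 µm cube at
0.3 sites/µm³ (~3×10⁵ sites against 2×10⁵ total captures). The
package default density of 0.3 sites/µm³ is a typical cortical synapse
density; the study's own disector-derived density and class fractions are
not published, so both are free parameters of `synth_config()`.

`variance_comparison()` compares the variance of observed per-cluster
smooth fractions against the null distribution obtained by repeatedly
drawing the same number of replicate fractions from the simulation,
with a two-sided Monte Carlo p-value (add-one corrected). When the
observed fractions are themselves drawn from the simulation the p-values
are uniform (tested by Kolmogorov–Smirnov). Note that against a single
homogeneous field the reconstructed fixture clusters show *more*
between-cluster variance than the binomial null — unsurprising, since
the smooth-target fraction in the fixtures co-varies with soma depth,
i.e. the effective neuropil composition differs between animals, which a
homogeneous null deliberately ignores.

## Physical-disector stereology

`disector_count()` counts synapses with a profile inside the counting
frame in the reference section and no profile in the lookup section,
with the standard unbiased-frame edge rule (profiles on the top/right
inclusion edges count, bottom/left exclusion edges do not); used
bidirectionally, both sections of a pair serve as reference and lookup,
doubling the probe count.

The pair is separated by one intervening section. Disappearance is
therefore assessed over the slab *between the two section planes*, and
the disector height used by `disector_height_nm()` is

$$h = (\mathrm{lookup} - \mathrm{reference}) \times t = 2t,$$

with $t$ the section thickness. Taking $h = t$ instead would double the
density estimate for any object taller than one section;
`numerical_density()` exposes $h$ explicitly so either convention can be
computed, but the package estimator uses the plane separation because it
is what makes $N_V = \sum Q^- / (n\,a\,h)$ size-unbiased. The residual
limitation of a spaced disector remains: an object whose z-extent is
smaller than one section thickness can fall entirely within the
intervening section and escape both probes. The unbiasedness property is
therefore tested with synapse extents drawn continuously from 1–5
section thicknesses, for which every object is probed from exactly two
reference positions; the suite verifies recovery within 5% at 500
disectors, and the acceptance script recomputes it at the runtime seed.

`composition_estimate()` wraps Goodman (1965) simultaneous multinomial
confidence intervals; simulated coverage at the 95% simultaneous level
is asserted at ≥ 94/100 runs. `systematic_random_sites()` produces the
standard lattice-with-random-phase sampling design.

## Serial-section morphometry

`psd_area()` treats the postsynaptic density as a thin surface sampled by
one linear trace per section: area = Σ(trace length × thickness). This
is the standard estimator for structures recorded as linear profiles; it
is consistent for surfaces roughly perpendicular to the cutting plane
and *underestimates* oblique patches by the cosine of their tilt, which
is why the closed-form oracle in the suite slices an equatorial band of
a sphere (estimator error < 3%) rather than a polar cap. Mesh
reconstruction is out of scope. `spine_volume()` is the Cavalieri sum of
cross-section areas × thickness (exact for prisms, < 3% for spheres at
60 nm sections); `dendrite_radius()` averages equivalent-circle radii
$\sqrt{A/\pi}$ over ≥ 3 sections. Both measures are additive over
disjoint sub-stacks, invariant to in-plane rotation, and scale as $s^2$
and $s^3$ under rescaling — properties the suite checks, along with the
commutation of shrinkage correction (`shrinkage_correct()`, default 11%
linear) with measurement.

`classify_dendrite()` encodes the anatomical criterion for smooth
(GABAergic) dendrites — no spines, shaft densely covered with asymmetric
synapses — with thresholds that are this package's choice, since none
are published: spine density ≥ 0.1/µm ⇒ spiny; zero spines and
asymmetric shaft-synapse density ≥ 0.5/µm ⇒ smooth; minimum assessable
length 2 µm; everything else (including too-short segments) is
`unclassified`, a first-class outcome mirroring the limited traceability
of real material. All thresholds are arguments.

## Axonal biophysics

`g_ratio()` is axon diameter over total fiber diameter,
$(d - 2s)/d$ — scale-invariant, hence unaffected by fixation shrinkage.
`conduction_velocity_myelinated()` applies the empirical linear relation
of 5.5 m/s per µm total diameter for thin myelinated CNS fibers;
`conduction_velocity_unmyelinated()` applies a fixed 15% penalty, taken
as an empirical factor rather than re-derived. At the 0.35 µm calibre of
myelinated linear segments these give 1.925 and 1.636 m/s, and
`transit_time_ms()` shows the myelination advantage over the 1 mm
soma-to-cluster distance is below 0.1 ms. No cable-equation modelling is
attempted. Note that a mean per-fiber g-ratio is *not* computable from
summary means of diameter and sheath thickness (the mean of ratios is
not the ratio of means), so the package reports g only per fiber.

## The synthetic-data generators

All generators are pure functions of (`synth_config`, seed). A single
root seed is expanded into labelled child streams by `child_seed()`, so
adding a generator never perturbs the output of existing ones.

- **Orientation maps** (`make_orientation_map()`): annular-bandpass
  filtering (in cycles/mm) of complex Gaussian white noise; angle =
  arg/2, magnitude = modulus. This is the standard construction for
  pinwheel-rich model maps and reproduces the qualitative statistics the
  SI needs — smooth iso-orientation domains, pinwheel singularities, an
  isotropic angle distribution (Rayleigh-tested across seeds). It does
  not emulate hemodynamic signals, camera noise or vascular artifacts.
- **Morphologies** (`make_morphology()`): SWC-valid trees (single soma
  root, parents precede children) whose dendrites and local boutons sit
  on pixels preferring the requested local domain, and whose distal
  cluster sits on pixels preferring the requested distal domain at the
  requested lateral offset. Candidate pixels must match the requested
  orientation within `domain_tol_deg` = 4°; the tolerance is deliberately
  tighter than the 10° existence check because ±10° placement could
  produce domain means 20° apart and an SI of only 0.78 for a
  "same-domain" construction, while ±4° guarantees SI ≥ 0.91 (same
  domain) and ≤ 0.09 (orthogonal), which is what the extreme-SI test
  constructions require. Bouton markers use SWC type codes 7 (local) and
  8 (distal).
- **Neuropil fields** (`make_neuropil_field()`): homogeneous Poisson
  site counts, uniform positions, i.i.d. class labels over
  {spine_spiny, shaft_spiny, shaft_smooth, soma}.
- **Contour stacks** (`make_contour_stack()`): fixtures of known
  analytic measure — a PSD disc whose per-section trace lengths carry
  the exact band areas (so the target area is recovered exactly), a
  square prism (Cavalieri exact), and a sphere with 64-gon
  cross-sections inflated to the exact circle area (volume within ~0.5%
  at 60 nm sections).
- **Fixture tables** (`fixture_tables()`): a synapse-level dataset
  reproducing every published count marginal. Quantities printed only as
  summaries — the spiny/smooth split of the five somatic targets, the
  intermediate local-cluster percentages, all per-synapse measurements,
  and the soma depths — are a clearly flagged *reconstructed* tier,
  engineered to be consistent with the printed statistics (exact
  linear-segment PSD means/SDs, exact PSD-volume correlations of
  0.63/0.68, depth correlation ≈ 0.67) but never to be read as measured
  data. Linear-segment spine volumes are left `NA` (those spines were
  not traced). One printed inconsistency is resolved in favour of the
  totals: the per-figure cluster counts of 103 + 101 do not sum with the
  28 linear synapses to the stated 233, so the fixtures carry 205
  cluster synapses.

What passing tests on these generators shows — and what it does not:
the suite demonstrates that the estimators are correct on data with the
statistical structure the analysis assumes (uniform target placement,
i.i.d. classes, isotropic maps, exact analytic fixtures). It cannot show
robustness to the failure modes of real material: registration error,
tissue compression, incomplete traceability, or neuropil heterogeneity.

## Numerical choices and problem sizes

Degenerate inputs raise informative errors rather than silently
producing numbers: zero cocktail-blank denominators name the offending
pixel, undefined orientation domains and unmyelinated g-ratios refuse to
evaluate, empty contour stacks and too-short dendrite segments are
rejected. Ties in candidate-pixel selection are broken by magnitude and
then index, keeping every construction deterministic.

The test suite and acceptance script choose problem sizes that exercise
the asymptotic claims while staying light: walks use 30–100 µm cubes at
0.3 sites/µm³ (the binomial-oracle run is the full 10,000 replicates),
disector checks use 40 × 40 µm stacks of 60 sections with 6,000 synapses
and 500 probes, coverage simulations use 100 runs of 200-count
multinomials, and map constructions use 64–256 px rasters. The full
suite runs in about three minutes; `scripts/acceptance.R` in about one.

## Known limitations

- The SI weighting is a documented reconstruction, not the original
  formula; cluster orderings are insensitive to this, absolute SI values
  near the band edges may not be.
- The walk null models a single homogeneous neuropil; between-animal
  composition differences (which the depth correlation in the fixtures
  implies) are deliberately outside it.
- The PSD-area estimator underestimates strongly oblique surface
  patches; no obliquity correction is applied.
- Spaced disectors miss objects thinner than one section.
- No apical/basal dendrite classifier is provided — dendrite radius is
  reported raw as the proximity proxy.
- No multiple-comparison correction is applied anywhere, matching the
  analysis style the package reproduces; reports flag this.
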
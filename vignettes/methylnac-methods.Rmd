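---
title: "MethylNAC: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MethylNAC: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylNAC)
```

## The geometric model of OMT regioselectivity

An S<sub>N</sub>2 methyl transfer from SAM to a substrate hydroxyl
requires two things simultaneously: the catalytic histidine must be close
enough to deprotonate the hydroxyl, and the resulting oxyanion must sit
roughly in line with the S–CH<sub>3</sub> bond being broken. MethylNAC
reduces each conformation to the two corresponding reaction coordinates:

* `d` — the distance from the nucleophile oxygen to the histidine
  acceptor nitrogen(s), in Å;
* `theta` — the angle at the SAM methyl carbon C1 between the attacking
  oxygen and the sulfonium sulfur, in degrees.

A frame is methylation-competent (a near-attack conformation) when
`d < dMax` and `thetaMin <= theta <= thetaMax`. The defaults —
3.5 Å and 125°–170° — are the conventional NAC criteria for this
chemistry; they are *parameters*, not constants, because the literature
tunes such windows per substrate class. The distance bound is strict and
the angle window inclusive, matching the way the criteria are usually
printed ("distance < 3.5 Å; angle between 125° and 170°").

Three measurement conventions deserve explanation:

* **Heavy-atom distance.** The physically meaningful contact is
  O···H–N, but crystal-derived models usually lack hydrogens, so `d` is
  measured O→N. The systematic N–H offset (~1.0 Å) is absorbed by the
  user-settable `dMax`. If a model does carry hydrogens the user can
  simply select them as additional "acceptor" atoms.
* **Minimum over acceptor nitrogens.** A histidine imidazole presents two
  N–H groups (Nδ1/Nε2) depending on tautomer; when both are listed the
  minimum distance is taken, since either can act as the base.
* **Degrees outside, radians inside.** All user-facing angles are in
  degrees; trigonometry is done in radians. The arccosine argument is
  clamped to [−1, 1] so collinear arms cannot produce NaN.

The per-site evidence is the *fraction* of frames classified competent,
computed as an exact integer count ratio, plus a kernel density estimate
over the (d, θ) plane for visual inspection of the conformational basin.
`rankSites()` orders sites by fraction; exact ties are broken
alphabetically and flagged rather than hidden, because a tie between
candidate sites is itself a scientific finding (no discrimination).

### KDE

The KDE uses a product Gaussian kernel with Scott's rule per axis
(`h_j = sd_j * n^(-1/6)`, the d = 2 case of `n^(-1/(d+4))`), evaluated on
a default 100×100 grid spanning [0, 8] Å × [0, 180]°. The literature
names KDE for these maps without stating a bandwidth; Scott's rule is the
standard reference choice and both bandwidths are user-overridable. For a
single-frame or zero-variance input the bandwidth falls back to a small
positive floor so the estimate stays defined. The implementation is the
direct sum of kernel evaluations (vectorised as two outer products and a
matrix product), so the density at any grid point equals the brute-force
kernel sum to machine precision — the test suite asserts 1e-12.

### Superposition and RMSF

`superpose()` is the closed-form Kabsch solution via SVD with the
determinant correction that enforces a proper rotation (no reflections).
`rmsf()` fits every frame to the ensemble mean with a two-pass refit
(mean → refit → recompute mean → refit) before measuring per-atom
root-mean-square displacements, which are then averaged per residue; the
default selection is the backbone-named atoms N, CA, C, O and there is no
mass weighting. A `refit = FALSE` switch supports pre-aligned ensembles
and the self-consistency check in the tests.

## The synthetic-ensemble generator

MD trajectories are expensive and rarely deposited; the generator stands
in for them by *construction*: it draws (d, θ) pairs per site from
truncated normal distributions — d truncated below at 0.5 Å, θ to
[0, 180]° — and embeds each pair as a minimal four-atom Cartesian
scaffold (S at the origin, C1 at 1.80 Å on the x-axis, O placed in the
xy-plane 3.0 Å from C1 at the requested angle, N displaced from O along
+z by the requested distance). The scaffold constants (1.80 Å S–C
bond-like, 3.0 Å van der Waals approach) are fixed and by construction
irrelevant to recovery of (d, θ): `measureSite()` returns the sampled
pair to 1e-6, which is the package's central round-trip invariant.

Sampling uses inverse-CDF truncated-normal draws; with a nonzero `rho`
the two coordinates share a Gaussian copula. Per-site random streams are
derived from the master seed and the site *label*, so adding a site to a
config never perturbs another site's draws.

Default study conditions follow the sampling scale the geometry arm is
meant for: ensembles of 20 000 conformations, with the reference
3′-OH-like site at d ~ N(3.3, 0.3) Å, θ ~ N(155, 10)° — centred on the
printed crystal-model geometry of the gallacetophenone substrate, with
spreads typical of a stable bound pose over a 100 ns trajectory.

What the generator deliberately does **not** emulate: protein context
(no clash checking, no force field), time correlation between frames
(draws are i.i.d., whereas real MD frames are autocorrelated), and the
d–θ correlation structure a real basin shows (independence is the
default; `rho` exists for stress tests, not realism). Passing tests on
synthetic ensembles therefore validate the *measurement and statistics
machinery*, not any claim about real conformational ensembles.

## Fusion-construct descriptors

For a two-enzyme fusion, `dIC()` and `oIC()` compute the inter-tunnel
centroid distance and the angle between two user-defined line segments.
Tunnel detection itself is out of scope — published tunnel placements
come from dedicated platforms whose algorithms are not reproducible from
the descriptor definitions alone — so anchors are explicit user input and
the package guarantees only the geometry: rigid-motion invariance,
symmetry, and an orientation-sensitive angle on [0, 180]° (antiparallel
segments give 180°, so near-straight tandem arrangements, e.g. ~157°,
are representable rather than folding to 23°).

## The kinetics model

### Competitive SAH inhibition

SAH inhibition is modelled as purely competitive with the acceptor
substrate: K<sub>m</sub> scales by (1 + [I]/K<sub>i</sub>), V<sub>max</sub>
unchanged. This is a modelling decision, not an established mechanism:
the available evidence reports the inhibition entirely as a
K<sub>m</sub> increase (51.7 → 2794 µM at 1.5 mM SAH) with no
V<sub>max</sub> effect reported. Under that model the printed pair
inverts exactly:

```{r}
inferKi(km = 51.7, kmApp = 2794, inhibitorConc = 1500)
```

`apparentKm()` and `inferKi()` are exact algebraic inverses, which the
tests assert to 1e-9.

### Initial-rate fitting

`fitMM()` fits untransformed rates (no Lineweaver–Burk linearisation,
which distorts the error structure) by Levenberg–Marquardt
(`minpack.lm::nlsLM`) with multi-starts: three heuristic
(vmax, km) starts, crossed with three K<sub>i</sub> starts spanning
I/2 down to I/1000 when inhibitor rows are present, lowest SSE winning.
The K<sub>i</sub> spread matters: a K<sub>i</sub> far below the applied
inhibitor concentration (28 µM vs 1.5 mM here) puts the optimum orders
of magnitude from a naive concentration-scale start, and a single start
can converge to a boundary local minimum. A design whose fitted
K<sub>m</sub> exceeds the largest tested concentration triggers an
identifiability warning.

### The cascade ODE

The coupled cycle is integrated with `deSolve::lsoda` (stiff-capable,
rtol 1e-8, atol 1e-10) using rapid-equilibrium-random products of
saturating terms for both enzymes — no bi-substrate mechanism
(ordered/ping-pong) is asserted by the available data, and the product
form reduces correctly in every limit the tests exercise. The rate laws
conserve S + P and SAM + SAH *pointwise* (the derivative sums are exactly
zero), so trajectory-level conservation to 1e-6 relative is a pure
integrator-accuracy check. Two qualitative mechanisms are built in and
tested rather than fitted:

* **Fast-regeneration limit.** When HMT capacity is ~100× the OMT flux,
  SAH is cleared as fast as it forms and the product curve collapses onto
  a single-enzyme SAM-replete model (within 2% in the tests) — the
  mechanism by which regeneration alleviates product inhibition.
* **Monotone regeneration penalty.** Shrinking HMT capacity never
  accelerates conversion; time-to-95% is non-decreasing as kcat·E of the
  HMT falls. This is the qualitative content of the observed contrast
  between completion in ~8 h with the coupled system and ~2 h with
  direct SAM supplementation.

### Default parameters

Concentrations are µM, kcat s⁻¹, time hours. `cascadeParams()` defaults
describe a desk-scale coupled assay: S₀ = 800 µM acceptor, 4000 µM SAH
as the cofactor source, 10 000 µM CH₃I, 2.5 µM of each enzyme
(≈10 µg of a ~40 kDa protein in 100 µL). Measured constants shipped via
`referenceKinetics()`: K<sub>m</sub> = 243.5 µM (caffeic acid),
51.7 µM (gallacetophenone), K<sub>m,app</sub> = 2794 µM at 1.5 mM SAH,
coupled-system K<sub>m,app</sub> = 499.6 µM, kcat/K<sub>m</sub> =
0.068 s⁻¹·mM⁻¹ (stored under the kcat/K<sub>m</sub> reading, which is
what the printed units support), and K<sub>i</sub>(SAH) ≈ 28.3 µM
inferred from the K<sub>m</sub> pair. The remaining constants —
kcat values (0.05 / 0.02 s⁻¹), K<sub>m,SAM</sub> = 50 µM,
K<sub>m,SAH</sub> = 20 µM, K<sub>m,donor</sub> = 500 µM — are
unmeasured; the defaults are plausible mid-range values for OMT/HMT
enzymes and are flagged as assumptions in `referenceKinetics()`. The
coupled-system K<sub>m,app</sub> of 499.6 µM is treated as qualitative
(between the clean and fully inhibited values) because it is an emergent,
protocol-dependent quantity, not a parameter of this model.

## Degenerate inputs and tie-breaks

* `embedGeometry()` rejects θ of exactly 0° or 180° (the scaffold plane
  is undefined) and non-positive distances.
* `angleDeg()` rejects zero-length arms.
* PDB parsing: first altloc wins, occupancy ignored (model ensembles are
  not experimental data); topology must be identical across MODEL blocks;
  coordinates |x| ≥ 10 000 Å cannot be written in fixed columns and are
  an error rather than silent truncation.
* `rankSites()` breaks exact fraction ties alphabetically and sets a
  `tie` flag.
* `timeToConversion()` interpolates the first crossing linearly and
  returns `Inf` when the target is never reached.

## Problem sizes in the tests and acceptance script

The suite exercises ensembles of 10–20 000 frames (20 000 matching the
conformational sample size the fraction statistics are designed for),
KDE brute-force checks on 20×20 grids with 400 points, 200-replicate
fitting studies at 8 concentrations × 3 replicates, and cascade
integrations to 400 h for the slow-regeneration sweep. These sizes give
sub-percent Monte-Carlo error on every stochastic check while keeping a
full run in seconds.

## Known limitations

* The NAC criterion is a rectangle in (d, θ); real reactive basins are
  not rectangular, and no free-energy weighting is applied — frames are
  equally weighted, with no time decorrelation.
* Heavy-atom d systematically overestimates the O···H distance by
  roughly the N–H bond length; comparisons across structures with and
  without hydrogens need a consistent convention.
* The cascade model ignores enzyme inactivation (e.g. alkylation by
  CH₃I), pH/temperature dependence, and any bi-substrate mechanism
  beyond the saturating-product approximation.
* mmCIF and binary trajectory formats are out of scope; conversion to
  multi-model PDB is the user's responsibility.
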
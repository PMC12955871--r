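# MethylNAC

Regioselectivity and cascade-kinetics analysis for SAM-dependent
O-methyltransferases (OMTs).

## The problem

Plant OMTs often face substrates carrying several chemically similar
hydroxyl groups (e.g. the 2′-, 3′- and 4′-OH of a catechol-type acceptor),
yet methylate only one of them. Two geometric factors govern which site
reacts in the S<sub>N</sub>2 methyl transfer from
S-adenosyl-L-methionine (SAM):

* **d(O···H–N)** — the distance between the substrate hydroxyl oxygen and
  the catalytic histidine imidazole nitrogen that deprotonates it
  (measured heavy-atom O→N when the model carries no hydrogens);
* **∠(O–C1–S)** — the angle at the SAM methyl carbon C1 between the
  attacking oxygen and the sulfonium sulfur; ~180° is ideal for in-line
  attack.

A conformation is a **near-attack conformation (NAC)** when
`d < d_max` (default 3.5 Å) and `θ_min ≤ ∠ ≤ θ_max` (default 125°–170°).
Scoring every frame of a structural ensemble against this region, per
candidate site, gives per-site competent-conformation fractions whose
ranking is the structural evidence for regioselectivity.

The package also models the *productivity* side of methylation: OMTs are
product-inhibited by S-adenosyl-L-homocysteine (SAH), and a halide
methyltransferase (HMT) can regenerate SAM from SAH plus an alkyl donor
(CH₃I). MethylNAC fits Michaelis–Menten and competitive-inhibition
kinetics, inverts printed apparent-K<sub>m</sub> shifts to the inhibition
constant K<sub>i</sub> = [I] / (K<sub>m,app</sub>/K<sub>m</sub> − 1), and
integrates the coupled two-enzyme cycle as an ODE system.

## What is in the package

* `parsePDB()` / `writePDB()` / `selectAtoms()` — multi-model PDB
  ensembles (MODEL/ENDMDL) with a shared atom topology.
* `measureSite()`, `classifyReactive()`, `siteStats()`, `rankSites()` —
  reaction-coordinate extraction, NAC classification, product-Gaussian
  KDE maps over the (d, θ) plane, and per-site ranking.
* `superpose()` (Kabsch, proper rotation), `rmsf()` (per-residue
  fluctuation with two-pass mean refit).
* `generateEnsemble()` — synthetic conformational ensembles whose
  internal coordinates follow chosen truncated-normal distributions,
  embedded as Cartesian frames with an exact ground-truth table.
* `dIC()` / `oIC()` — fusion-enzyme descriptors: inter-tunnel centroid
  distance and inter-segment angle from user-supplied anchors.
* `mmRate()`, `apparentKm()`, `inferKi()`, `fitMM()`, `synthRateData()`,
  `cascadeParams()`, `simulateCascade()`, `timeToConversion()` —
  the kinetics arm.
* `runPipeline()` and friends — config-driven runs writing CSV/JSON
  artifacts plus a manifest (`inst/scripts/methylnac.R` is a thin CLI
  wrapper).

## Worked example

```r
library(MethylNAC)

# Printed crystal-model geometries of a gallacetophenone's three hydroxyls:
# (5.8 A, 110 deg), (3.3 A, 155 deg), (4.0 A, 160 deg)
classifyReactive(d = c(5.8, 3.3, 4.0), theta = c(110, 155, 160))
#> [1] FALSE  TRUE FALSE         # only the 3'-OH geometry is competent

# Synthetic ensemble: a tight 3'-OH site vs a looser, more distant 4'-OH
gen <- generateEnsemble(list(
  siteDistribution("3p-OH", dMean = 3.3, dSd = 0.3, thetaMean = 155, thetaSd = 10),
  siteDistribution("4p-OH", dMean = 4.6, dSd = 0.4, thetaMean = 150, thetaSd = 15)),
  n = 5000, seed = 42)
st <- lapply(gen$sites, function(s) siteStats(gen$ensemble, s))
rankSites(st)
#>    site fraction n_reactive n_frames rank   tie
#> 1 3p-OH   0.6952       3476     5000    1 FALSE
#> 2 4p-OH   0.0024         12     5000    2 FALSE

# SAH product inhibition: invert a Km shift (51.7 -> 2794 uM at 1.5 mM SAH)
ki <- inferKi(km = 51.7, kmApp = 2794, inhibitorConc = 1500)
ki
#> [1] 28.27918                  # uM; apparentKm(51.7, ki, 1500) == 2794

# Coupled OMT/HMT SAM-regeneration cycle vs direct SAM supplementation
t95_coupled <- timeToConversion(simulateCascade(cascadeParams(), tEnd = 48), 0.95)
t95_direct  <- timeToConversion(simulateCascade(
  cascadeParams(sam0 = 4000, sah0 = 0, kcatH = 0), tEnd = 48), 0.95)
c(coupled = t95_coupled, direct = t95_direct)
#>   coupled    direct
#> 24.948302  8.810643            # hours to 95% conversion
```

The fractions are exact frame-count ratios; the ranking flags exact ties.
The cascade comparison shows the qualitative regeneration penalty: with
the cofactor supplied as SAH the cycle must run through the HMT before
any methylation happens, so conversion is slower than with direct SAM —
while still escaping the strong product inhibition a stoichiometric SAH
load would otherwise impose.

## Documentation

The methods vignette (`vignettes/methylnac-methods.Rmd`) describes the
geometric model, the synthetic-data generator and its limits, the kinetic
model and every default parameter, and the numerical choices.
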
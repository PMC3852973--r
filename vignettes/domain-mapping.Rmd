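---
title: "Mapping rigid domains and flexible linkers from solution data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping rigid domains and flexible linkers from solution data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainmapr)
```

## The inference this package implements

A folded protein exposed briefly to a protease is cut only where the chain
is flexible and accessible; rigidly folded domains survive as stable
fragments. Each stable band yields two measurements: an Edman N-terminal
read (the first 3–6 residues) and an intact mass from MALDI-MS, printed at
0.1 kDa precision. Neither alone places the fragment on the sequence; the
combination does. The read pins the N-terminus by exact string match, and
the mass selects the C-terminus among the finitely many bonds the protease
can cut. Assembling the fragments that persist to the end of a digestion
time course yields a map of the chain as alternating rigid cores and
flexible linkers.

Orthogonally, gel-permeation chromatography (GPC) coupled to static light
scattering (SLS) classifies each expressed construct in solution. SLS gives
an absolute, shape-independent mass `MW_SLS`; the retention volume gives an
apparent, hydrodynamic-radius-based mass `MW_rh`. For a compact globular
monomer the two agree; a flexible or extended chain elutes far too early,
so the ratio `MW_rh / MW_SLS` is a flexibility meter that cleanly separates
rigid domains from linker-bearing constructs, while `MW_SLS / MW_th`
settles monomer versus dimer independently of shape.

The worked example shipped with the package applies the pipeline to the
ectodomain of the human amyloid precursor protein (APP, 695-residue
neuronal isoform): six (read, mass) observations from V8/Glu-C and trypsin
digests of two constructs resolve the ectodomain into two rigid cores (the
E1 and E2 domains) joined and followed by flexible acidic and juxtamembrane
linkers, with a partially flexible extension segment after E1.

## The mass engine

Masses are isotope-averaged, not monoisotopic: the observed species are
15–30 kDa intact masses, far beyond isotopic resolution. A peptide mass is
the sum of standard average residue masses plus one water (18.015 Da);
reported values are converted to kDa rounded half-up to one decimal,
matching how such tables are printed (base R's `round()` rounds half to
even and would disagree on exact half values).

Two processing rules matter for recombinant material:

* **Initiator methionine.** Bacterial methionine aminopeptidase removes the
  initiator Met when the second residue is small (A, C, G, P, S, T, V).
  `met_retained()` encodes this; `build_constructs()` applies it, so a
  Leu-starting construct keeps its Met (Edman read `MLEV`) while a
  Ser-starting one loses it (`STPD`). Fragments inherit the Met only when
  they begin at the mature chain's first residue; internal fragments never
  carry one.
* **Disulfides.** Cysteines are treated as reduced by default. Each
  declared disulfide lowers the mass by 2.016 Da, which is far below the
  0.1 kDa reporting precision for every fragment considered here, so the
  default reproduces printed tables regardless of the true topology.

Non-canonical residues are rejected outright rather than given a default
mass: a silently wrong residue mass would corrupt every downstream
boundary deduction.

## Protease rules

A `ProteaseSpec` lists P1 residues cut quickly (`p1_fast`), P1 residues cut
at a strongly reduced rate (`p1_slow`; for V8/Glu-C the Asp class, some
100–300-fold slower than Glu), P1′ residues that block cleavage (`P` for
V8 and trypsin), and P1′ residues that demote an otherwise fast site to the
slow class. Thermolysin-like enzymes that recognise the P1′ side are
described positionally via `p1prime_target`.

Two specificity choices deserve justification:

* **Glu–Glu / Glu–Asp bonds are slow for V8.** Glu-C hydrolyses bonds into
  an adjacent acidic residue far more slowly than into a neutral one. We
  therefore demote fast Glu sites whose P1′ is Glu or Asp to the slow
  class. Practically this means that in a `...E-E-S...` context the
  enzyme's observable cut is after the *second* Glu — exactly the
  behaviour seen at the `E192↓S193` boundary in the worked example, where
  a naive rule would have placed an indistinguishable-by-mass cut one
  residue earlier, between the two glutamates.
* **Default enumeration uses fast sites only.** Limited proteolysis is
  stopped long before slow sites fire, and every deduced boundary in the
  worked example falls on a fast site. `include_slow = TRUE` adds the slow
  class everywhere it matters.

## Ranking fragment candidates

For each N-terminal match, every downstream fast site on the parent
segment plus the construct C-terminus (tag included — tags are not
cleavable segments, so tag-internal bonds are never candidates) is scored
by `delta = observed − theoretical`. Candidates are ranked by `|delta|`,
ties towards the smaller fragment, with one asymmetry: candidates whose
theoretical mass exceeds `observed × (1 + tolerance)` rank after all
others. Linear-mode MALDI masses of intact species err high — matrix
adducts and incomplete desolvation add mass — so a deduced sequence
*heavier* than the measurement plus its error cannot be the weighed
species, whereas a lighter sequence plus adducts can. When no candidate
falls within tolerance the top-ranked call is still returned with
`within_tolerance = FALSE`: the nearest-possible-site fallback. In the
worked example this reproduces the one flagged row, where a 15.9 kDa
observation is assigned to the R510 site (14.8 kDa theoretical) rather
than to a heavier site 1.7 kDa above it.

The default relative tolerance is 1% (≈ 0.2–0.3 kDa on these fragments):
tight enough that all five consistent observations pass and the
nearest-site fallback row fails, loose enough for routine external
calibration error. It is an argument everywhere, never a constant.

## Assembling the domain map

*Persistence* is the structural signal: a fragment present at the final
sampled time point has resisted digestion throughout and must be rigid.
The map is built from rank-1 calls as follows:

1. Persistent fragment intervals are merged when overlapping or adjacent
   (`rigid_cores()`). Consensus across proteases and constructs falls out
   of the union — the outermost persistent termini win, and the individual
   fragments stay attached as provenance. This deliberately keeps both
   candidate N-edges of a core when different experiments disagree (e.g.
   a fragment starting at 286 and a construct starting at 295): the union
   bounds the core, the provenance records the ambiguity.
2. Gaps between cores (and between the analyzed span's edges and the
   outermost cores) become `flexible-linker` only where a cleavage bond was
   actually observed inside the gap or at its boundary — a cut is direct
   evidence of accessibility. Evidence-free gaps stay `undetermined`.
3. Nested persistent fragments sharing a terminus flag the differential
   segment as *partially flexible* (attribute `"subdomains"`): the shorter
   stable species proves the extra segment of the longer one is eventually
   trimmable. The rule is applied on both shared-N-terminus and
   shared-C-terminus pairs; in the worked example it recovers the
   extension segment after the E1 core (193–227) and the slowly trimmed
   N-terminal region of the E2 construct.

Proteolysis can only see boundaries at cleavable bonds, so a mapped core
edge may sit a residue or two outside the structural domain boundary known
from a crystal structure. Such refinements are accepted only as explicit
user annotations (`overrides` in `assemble_domains()`), never inferred.

## Hydrodynamics

* **Calibration** is the standard semi-log fit, `log10(MW) ~ Ve`, by least
  squares; a non-negative slope (larger species eluting later) warns of a
  non-ideal column. The shipped standards table carries realistic retention
  volumes for a small analytical column and is labelled *synthetic*: it
  demonstrates the calibration code, it is not instrument data.
* **SLS** is implemented in the single-angle, negligible-form-factor
  Rayleigh–Gans–Debye limit, `M = R90 / (K (dn/dc)² c)`, appropriate for
  proteins below ~100 kDa on a two-detector (RI + 90°) system, averaged
  across the elution peak weighted by concentration. `dn/dc` defaults to
  0.185 ml/g, the standard protein value, and is configurable.
* **Oligomeric state**: monomer if `MW_SLS` is within 20% of `MW_th`,
  dimer if within 20% of `2 × MW_th`, else `other`. 20% is generous — the
  largest monomer deviation in the worked example is ~9% — yet still
  separates 1× from 2× with a wide margin.
* **Shape class**: `rigid-compact` for ratios ≤ 1.5, `flexible-extended`
  for ≥ 1.8, `elongated` between. The cut-offs sit in the empirical gap of
  the worked example (rigid constructs ≤ 1.34, flexible ones ≥ 1.85) and
  are exposed as arguments because the classification is intrinsically a
  thresholded judgement.
* **Co-elution**: association would make the mixture elute *earlier* than
  either component; an intermediate retention volume (within a volume
  tolerance, default 0.01 ml) is the no-interaction outcome.
* **BLI**: equilibrium responses are fit to the one-site isotherm
  `R = Rmax·C/(Kd + C)` by Levenberg–Marquardt least squares. "No
  measurable affinity" is an explicit tri-fold criterion: the fit fails,
  or `Kd` exceeds the highest tested concentration, or the fitted
  amplitude stays below three times the replicate noise. A flat series at
  noise level therefore returns `measurable = FALSE` rather than a
  meaningless huge `Kd` with a tiny amplitude.

## The synthetic-data generator

The generator exists so every stage is testable without instrument data,
under the statistical structure the analysis assumes:

* **Chains**: rigid cores (default 2 domains of 120–200 residues) with a
  database-average composition, joined by 40–70-residue linkers enriched
  in Asp/Glu/Ser/Thr like an acidic domain. Linkers carry fixed `ESSS`/
  `ESE` edge motifs so Glu-directed proteolysis trims to within ≤ 2
  residues of the true domain edge — as on real flexible linkers — and so
  the nearest competing cleavage site lies several hundred daltons from
  the true one.
* **Digestion**: only bonds adjacent to a linker are accessible; a
  deterministic two-class kinetic threshold (`k t ≥ ln 2`, slow class
  200× slower) cuts fast sites within the first hour and leaves the slow
  class untouched at a 24 h end point. Wholly-linker pieces are transient
  (flexible peptides keep being degraded); fragments below a 3 kDa gel
  detection limit are not reported.
* **Noise defaults** are the instrument scales of the data being
  emulated: relative intact-mass sd 0.3% (MALDI), retention-volume sd
  0.01 ml, SLS sd 3%. True shape ratios are drawn from 1.0–1.3 for rigid
  and 1.8–2.8 for flexible constructs.
* **Determinism**: every generator is a pure function of its parameters
  and a single seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: nonspecific or secondary-site cleavage,
systematic (as opposed to random) mass calibration bias, gel artefacts
such as anomalous migration or double bands, partial unfolding of cores at
long digestion times, and concentration-dependent effects in GPC/SLS.
Recovery statistics on synthetic data are a check of internal soundness,
not a validation against biology.

The test suite runs the full loop — generate, digest, infer, assemble — on
100 two-domain replicates at 0.3% mass noise (≥ 90% of true boundaries
recovered within ±2 residues) and scores rank-1 fragment calls on 200
replicates (≥ 99% exact); both sizes keep the suite comfortably inside a
couple of minutes on one CPU while leaving the statistics stable. The
residual misses are single-residue ambiguities at the chain C-terminus,
where the construct end and a cleavage site one residue in differ by one
residue mass — exactly the ambiguity a real experiment has.

## Known limitations

* Boundary resolution is limited to cleavable bonds: a linker with no fast
  site near the domain edge shifts the mapped boundary outward.
* The Edman read is matched exactly; sequencing errors are not modelled.
* Single-angle SLS cannot detect the angular dependence that would flag
  very large or strongly non-ideal species.
* Theoretical masses of tagged constructs depend on the exact tag/linker
  composition, which is vector-specific; tags are user-supplied
  configuration, and tagged-construct `MW_th` values are treated as input
  data, not recomputed targets.
* `domain_map` intervals are 1-based and inclusive throughout, matching
  residue-label conventions (Leu18, Glu227, …); there are no half-open
  intervals anywhere in the public surface.
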
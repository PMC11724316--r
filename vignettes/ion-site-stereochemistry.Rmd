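---
title: "Stereochemistry of Mg2+ and K+ binding sites: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereochemistry of Mg2+ and K+ binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgion)
library(dplyr)
```

## The problem

High-resolution structures of large RNAs — ribosomes above all — are
stabilised by hundreds of chelated Mg^2+^ ions and K^+^ ions, plus tens of
thousands of water molecules. Deposited models routinely misassign this
solvent shell: Mg^2+^ ions with coordination distances far beyond the
physical first-shell limit, incomplete octahedra, K^+^ ions modelled as
Mg^2+^ (and vice versa), and density peaks that are really waters. Because
Mg^2+^ stereochemistry is exceptionally strict, most of these errors are
detectable from coordinates alone.

`mgion` implements that stereochemical screen as a reusable library: it
builds first coordination shells around every metal, scores how octahedral
each Mg^2+^ shell is, names each site with the extended MgRNA nomenclature,
scans whole structures for the motifs that anchor Mg^2+^ in nucleic acids
(bidentate phosphate clamps, head-to-tail purine N7 seats, O2'–phosphate
turns), and classifies bridged metal–metal pairs into a micro-cluster
taxonomy.

## The geometric model

A hexacoordinated Mg^2+^ has first-shell distances d(Mg...O) =
2.07 ± 0.04 Å and d(Mg...N) = 2.19 ± 0.08 Å, cis and trans coordination
angles of 90 ± 3° and 177 ± 4°, and consequently O...O separations of
2.93 ± 0.09 Å (cis) and 4.13 ± 0.07 Å (trans). Around a correctly modelled
Mg^2+^ there is an *exclusion zone*: no O/N atom should occur between the
2.3 Å edge of the acceptance window and 3.4 Å (the upper limit is 3.4
rather than 3.6 Å to accommodate highly chelated ribosomal motifs absent
from small-molecule databases). K^+^ is much softer: 6–9 ligands at
2.6–3.2 Å, with no exclusion zone.

Two consequences of the 2.93 Å cis O...O separation drive the motif
scans:

* any pair of anionic phosphate oxygens (O~ph~ = OP1/OP2) from distinct
  phosphate groups held closer than 3.4 Å is — essentially always — held
  there by a Mg^2+^ bidentate clamp, directly or through one of its
  first-shell waters;
* the only purine arrangement that brings two N7 atoms below 3.4 Å is the
  head-to-tail stack that seats a cis-2N~b~.4O~w~ ion.

Both scans therefore reduce to distance screens with a B-factor filter
(≤ 60 Å² on both atoms) to discard poorly modelled pairs.

## Parameters

All tunables live in one object; every distance is in Ångström, every
angle in degrees:

```{r}
p <- geometry_params()
str(unclass(p))
```

The defaults above *are* the study conditions; they can be overridden per
call (`geometry_params(clamp_dmax = 3.2)`) or from a plain-text
`key = value` config file via `read_geometry_params()`. Values worth
explaining:

* `mg_window = c(1.9, 2.3)`: the strict acceptance window for a Mg–O/N
  coordination distance. Its upper edge simultaneously opens the
  exclusion zone; the constructor enforces that coupling.
* `cis_trans_cut = 135`: a ligand pair at or below 135° is *cis*, above
  is *trans*. Only the modal values (90°/177°) are physically prescribed;
  135° is their midpoint, and no realistic shell sits near it.
* `distortion_correct_max = 5`, `distortion_slight_max = 10`: category
  edges for the octahedral distortion score (below).
* `trans_candidate_window = c(3.9, 4.4)`: the trans-2O~ph~ screen.
  The trans O...O separation (4.13 ± 0.07 Å) overlaps ordinary
  backbone O~ph~...O~ph~ distances, so hits are only ever reported as
  candidates; the window is the mean ± roughly 3 standard deviations.
* `mgd_max = 2.6`, `mgc_max = 3.2`, `mgb_max = 4.2`, `pair_dmax = 5.5`:
  Mg...Mg micro-cluster bin edges. The taxonomy is anchored on exemplar
  distances (MgD ≈ 2.4, MgC ≈ 2.7–2.8, MgB ≈ 3.8, MgA ≈ 4.5–5.3 Å);
  the edges interpolate between those centroids and are deliberately
  exposed as configuration, because class *boundaries* are a modelling
  choice, not an observation. MgA additionally requires a bridging
  phosphate group, and its lower bound is 4.2 Å with the typical range
  reported as 4.5–5.3 Å.
* `min_occupancy = 0.5`: atoms below this occupancy stay in the table but
  are never counted as ligands — partial occupancy is one of the factors
  that blur coordination patterns.
* `density_min = 4.0` (σ): an optional per-ion density-peak criterion.
  Density is accepted only as a sidecar annotation (TSV of
  `ion_id`, `sigma`); when absent the criterion is skipped entirely, so
  the tool never pretends to know map quality it was not given.

## The distortion score

The octahedral character of a six-ligand shell is scored as the mean
absolute deviation of its 15 ligand–ion–ligand angles from ideality
(twelve 90° slots, three 180° slots), minimised over the assignment of
ligands to octahedron vertices. Equivalently — and this is how it is
implemented — the minimisation runs over the 15 perfect matchings of six
ligands into three trans pairs, which removes any tie-breaking heuristics.
The category thresholds are < 5° ("correct"), 5–10° ("slightly
distorted") and > 10° ("highly distorted"); a shell with any other
coordination number is "not octahedral" and the value is undefined.

One genuine ambiguity: the thresholds could be read against either a
*summed* or a *mean* angular deviation. We adopted the mean, because it
makes the printed 5°/10° thresholds meaningful per angle; the summed
value (`distortion_sum`, exactly 15× the mean) is reported alongside so
the other reading can always be recovered.

An ion is **well-defined** iff it is hexacoordinated, its distortion
category is correct or slightly distorted, and its density peak — when a
sidecar is provided — is at least 4.0 σ.

## Nomenclature

Sites are named from the multiset of first-shell ligand categories in
canonical order (O~ph~ > O~r~ > O~b~ > N~b~ > O~coo~ > O~bb~ > O~cno~ >
OH~prot~ > O~w~ > N~His~), e.g. `2Oph.4Ow`. Isomer prefixes depend on the
number of non-water ligands: two → `cis-`/`trans-` by their mutual angle;
three → `fac-` if all three pairs are cis, else `mer-`; four →
`Cis-`/`Trans-` (capitalised) by the mutual angle of the two *waters*.
Mixed-category combinations take the same prefixes, and for three
non-water ligands of mixed category the fac/mer decision treats them as a
set. Ion-pair classes are written in ASCII as `MgA_uc2`, `MgK_uc3`, etc.
(`uc` for micro-cluster) so that labels survive every file format and
terminal.

## The synthetic-structure generator

Every test runs against `make_fixture()` output: small, chemically
plausible fragments built from internal-coordinate templates (P–OP
1.48 Å, OP–P–OP 119°, an idealized planar guanine, octahedra at exactly
2.07/2.19 Å) with the planted motif's target distances and angles holding
exactly at zero jitter. Gaussian jitter with a caller-chosen standard
deviation (seeded, one documented generator: R's default RNG driving
`rnorm` on every coordinate) emulates coordinate uncertainty. Ground
truth — expected labels, scan hits, pair classes — travels with every
fixture.

What the generator does *not* emulate: experimental density and map
noise, alternate conformations, correlated (TLS-like) displacement,
crystal contacts and symmetry mates, full nucleotide topology beyond what
a scan needs, or the sheer ligand-environment diversity of a ribosome.
Green tests therefore demonstrate that the rules are implemented exactly
as stated, and that detection is robust to small uncorrelated coordinate
noise — not that the thresholds themselves generalise to any particular
deposition.

A note on jitter and recovery: with ligands built at 2.07 Å, the
acceptance window [1.9, 2.3] is asymmetric (−0.17/+0.23 Å), so at 0.05 Å
per-coordinate jitter on *all* atoms roughly 1% of ligand distances slip
below the window per ligand. Shell-label recovery at that noise level is
therefore expected a little above 95% for six-ligand shells, which is
what the 200-replicate robustness tests measure; clamp detection, with
its 0.5 Å margin, is essentially immune.

## Numerical choices and degenerate inputs

* Neighbour queries run on a uniform cell grid (cell edge = query
  radius) and are required — by property test against a brute-force
  scan — to return exactly the naive result, sorted by distance.
* Plane fits: the OP1–P–OP2 plane is exact (three points); nucleobase
  planes are least-squares via SVD over the ring atoms.
* Alternate conformations: only blank or `A` altlocs are kept, because
  the analysis assumes a single conformer; hydrogens are ignored for all
  geometry (protonation is encoded statically in the non-protonated
  nitrogen template: (G)N1 and (U)N3 are never N~b~).
* Author chain/residue numbering is the reporting identity throughout.
* An ion with zero ligands yields an empty shell and flows into the
  diagnosis (`likely_water` / `likely_K_as_Mg`) rather than erroring;
  unknown residues degrade to the `other` category with a warning.
* Waters bridging two metals count as ligands of both — the pair
  taxonomy depends on it.
* `classify_pair` is symmetric in its two ions, and the distance bins
  partition the pair range: every bridged Mg–Mg pair receives exactly
  one class or an explicit machine-readable reason.
* MgD pairs (inter-metal distance ≤ 2.6 Å) always carry a
  "requires independent confirmation" note: sub-2.5 Å Mg...Mg contacts
  are extraordinary claims.

## Worked example

```{r}
fx <- make_fixture("mgC_pair")
rep <- run_diagnosis(fx$atoms)
rep
glance(rep)
rep$pairs |> select(distance, shared_waters, shared_nonwater, class_label)
```

## Problem sizes used by the shipped tests

The test-suite fixtures span 2–60 atoms per structure; the oracle
equivalence properties each run 100 seeded instances (40–60 atom clouds
for neighbour search, 720-permutation enumeration for the distortion
oracle, 4–15 ion graphs for chain components); robustness curves use 200
seeded replicates per motif. These sizes exercise every code path while
keeping the default test run fast on a laptop.

## Known limitations

* The tool flags, it never moves atoms: no re-refinement, no coordinate
  correction, no ion-position prediction into empty density.
* No symmetry-mate expansion or assembly building: clamp and pair counts
  on crystal structures with important lattice contacts will undercount.
* The `likely_water` rule is conservative and explicitly configurable;
  no published numeric rule exists for the delete-versus-reassign
  decision, so ours is a documented choice (at most two O/N contacts in
  the 2.3–3.4 Å band and none in the Mg window).
* K^+^ validation is distance-window only; no exclusion zone is applied
  to K^+^ because none is established for it.
* Zn^2+^ is screened with the Mg^2+^ window (comparable ionic radius)
  but tetrahedral Zn^2+^ sites are outside the model.
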
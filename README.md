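# mgion

Stereochemical validation and classification of Mg²⁺ (and paired K⁺)
binding sites in nucleic-acid and protein 3D structures.

High-resolution RNA structures — ribosomes above all — carry hundreds of
chelated Mg²⁺ and K⁺ ions whose solvent shells are frequently
mismodelled: coordination distances beyond the physical first-shell
limit, incomplete octahedra, K⁺ deposited as Mg²⁺, waters deposited as
ions. Because Mg²⁺ stereochemistry is strict, most of these errors are
detectable from coordinates alone. `mgion` is for structural biologists
curating such models and for method developers who need a reproducible,
scriptable implementation of the rules.

## The rules it implements

For hexacoordinated Mg²⁺: first-shell d(Mg…O) = 2.07 ± 0.04 Å and
d(Mg…N) = 2.19 ± 0.08 Å; *cis*/*trans* coordination angles
θ(O…Mg…O) ≈ 90 ± 3° / 177 ± 4°, hence O…O separations of 2.93 ± 0.09 Å
(*cis*) and 4.13 ± 0.07 Å (*trans*); an acceptance window of 1.9–2.3 Å
and an exclusion zone of 2.3–3.4 Å in which no O/N atom may sit. K⁺:
6–9 ligands at 2.6–3.2 Å. On top of these the package provides:

* **Coordination shells** with an octahedral-distortion score — the mean
  |deviation| of the 15 ligand–ion–ligand angles from ideality, minimised
  exactly over all vertex assignments — categorised `correct` (< 5°),
  `slightly_distorted` (5–10°), `highly_distorted` (> 10°).
* **Site nomenclature**: `6Ow`, `Oph.5Ow`, `cis-2Oph.4Ow`,
  `fac-3Oph.3Ow`, `Trans-4Oph.2Ow`, … with isomer prefixes decided from
  the pairwise cis/trans map.
* **Per-ion diagnosis**: `incomplete_shell`, `exclusion_zone_contact`,
  `likely_K_as_Mg`, `likely_Mg_as_K`, `likely_water`, `low_density`, …
  and a `well_defined` verdict.
* **Motif scans**: bidentate phosphate clamps via the
  d(O_ph…O_ph) < 3.4 Å rule with a B ≤ 60 Å² filter (annotated
  direct/water-mediated/none), *trans*-2O_ph candidates (3.9–4.4 Å),
  head-to-tail purine N7 seats (< 3.4 Å), and O2′(n)…OP(n+1) turn
  motifs.
* **Ion-pair taxonomy**: bridged Mg…Mg pairs as MgA/B/C/D micro-clusters
  (distance bins 4.2–5.5 / 3.2–4.2 / 2.6–3.2 / ≤ 2.6 Å, suffix = number
  of shared ligands or phosphate groups), Mg…K pairs as MgK_uc2/3, and
  assembly of pairs into ion chains.
* **A deterministic fixture generator** (`make_fixture()`) that builds
  every motif above from internal-coordinate templates with ground truth
  attached, so the whole pipeline is testable without downloading a
  single structure.

Input is mmCIF (PDBx) or PDB v3.3; everything is tibble-in/tibble-out
and pipe-friendly.

## Worked example

```r
library(mgion)

fx  <- make_fixture("mgC_pair")   # two Mg2+ bridged by an OP1 + 2 waters
rep <- run_diagnosis(fx$atoms)
rep
#> <mg_report> fixture:mgC_pair
#>   atoms: 15; metal ions: 2
#>   well-defined ions: 2 of 2
#>   clamp pairs: 0; trans candidates: 0; purine seats: 0; O2'-OP motifs: 0
#>   ion pairs: 1 in 1 chain(s)
#>   site inventory:
#>     Oph.5Ow                  2 (2 well-defined)

rep$pairs |>
  dplyr::select(distance, shared_waters, shared_nonwater, class_label)
#> # A tibble: 1 × 4
#>   distance shared_waters shared_nonwater class_label
#>      <dbl>         <int>           <int> <chr>
#> 1      2.8             2               1 MgC_uc3
```

Both ions are hexacoordinated `Oph.5Ow` sites sharing one phosphate
oxygen and two waters at an inter-metal distance of 2.8 Å — a type-III
(MgC) micro-cluster with suffix 3 for the three bridging ligands.
`tidy(rep)` gives the per-ion table, `glance(rep)` the one-row summary,
`autoplot(rep)` the site-inventory chart, and `write_report(rep, dir)`
emits JSON + TSV. A thin CLI with `diagnose`, `clamps`, `pairs` and
`fixture` subcommands ships in `inst/cli/mgion`.

To validate a real deposition:

```r
rep <- run_diagnosis("structure.cif")
tidy(rep) |> dplyr::filter(!well_defined)
```

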
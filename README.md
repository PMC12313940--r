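# hydrotriad

Geometric analysis of serine-hydrolase active sites, built around the
**water-mediated catalytic triad**: the Ser–His–(H₂O–Asp/Asn) architecture
found in ancillary-domain-containing CE20 carbohydrate esterases, in which
the catalytic acid sits ~4 Å from the His Nδ1 — too far for a direct
hydrogen bond — and a precisely coordinated water (≈2.9 Å to each side)
bridges the gap.

The package is for structural biologists and enzymologists who want to ask,
of a coordinate model: *is this a conventional triad, a water-mediated
triad, or a dyad — and could the side chains ever close the gap?* It
provides:

* **Structure I/O** — PDB and mmCIF readers (first model, altloc-resolved,
  waters separated), a PDB writer, and Cα B-factor extraction for
  catalytic residues.
* **Hydrogen-bond geometry** — distance-window partner search (N/O heavy
  atoms, default window 2.2–3.5 Å) and water-coordination analysis with a
  tetrahedrality score (mean |angle − 109.5°| over partner–O–partner
  angles).
* **Site classification** — Ser–His pairs via the Nε rule (Ser Oγ bonds
  His Nε2, never Nδ1), then a strict cascade over the third position:
  `CONVENTIONAL_TRIAD` (acid O < 3 Å from Nδ1) → `WATER_MEDIATED_TRIAD`
  (water within window of both Nδ1 and an acid O) → `MAINCHAIN_DYAD`
  (backbone O/N < 3 Å) → `BARE_DYAD`.
* **Rotamer feasibility** — exhaustive joint χ1/χ2 scanning of the His and
  acid side chains (rigid rotation of crystal coordinates, hard-sphere
  clash filter) to test whether a direct contact < 3 Å is geometrically
  attainable at all.
* **Motif screening** — substitution-aware three-residue motif matching by
  Kabsch superposition (13 mapped atoms, RMSD ≤ 2 Å, Asp/Asn/Glu/Gln
  allowed at the acid slot) plus the four-stage hydrogen-bond filter
  cascade (no direct His–acid bond; Ser is a nucleophile; Oγ–Nε2 bond;
  water bridges the gap).
* **Kinetics** — Michaelis–Menten fitting, v = Vmax·[S]/(KM+[S]), of
  chromogenic esterase assays (Beer–Lambert slope conversion, ε = 15 000
  M⁻¹cm⁻¹) with kcat, KM, kcat/KM and mutant-vs-wild-type fold changes.
* **Synthetic fixtures** — labelled miniature active sites with exact
  requested geometry, noise and B-factors, so the entire pipeline is
  testable without downloading a single structure.

## Worked example

Build the exemplar geometry (Oγ–Nε2 2.8 Å; Nδ1–acid 4.0 Å; water bonds
2.9/2.9 Å) and run the full evidence bundle:

```r
library(hydrotriad)

b <- build_site_fixture("WATER_MEDIATED_TRIAD", 2.8, 4.0, 2.9, 2.9,
                        bfactors = c(17.7, 29.7, 20.0))
analyze_site(b$structure, "A:112", "A:515", "A:513")
#> <catalytic_site> WATER_MEDIATED_TRIAD
#>   Ser: SER A:112   His: HIS A:515   acid: ASP A:513
#>   d(OG-NE2)  2.80  d(ND1-acidO)  4.00  d(ND1-water)  2.90  d(water-acidO)  2.90 A
#>   Ser nucleophile: TRUE
#>   bridge water: 4 partners, tetrahedrality 7.2 deg
#>   CA B-factors: 17.70 - 29.70 A^2
```

The classification (water-mediated, not conventional), the bridge water's
4-coordination, and the low Cα B-factors are the three structural pillars;
the rotamer scan adds the fourth — on a pair built so that no χ1/χ2
combination can beat 3.6 Å:

```r
rot <- build_rotamer_fixture(3.6, approach = "axis")
scan_min_distance(rot$structure, "A:515", "A:513", grid_step = 20)
#> <rotamer_scan> grid step 20 deg
#>   original d(ND1-acidO): 3.60 A
#>   min unconstrained:     3.60 A
#>   min clash-free:        3.60 A  at offsets (0, 0, 0, 0) deg
#>   direct contact < 3.0 A attainable: FALSE
```

Kinetics, from the bundled synthetic wild-type assay (triplicates at
0.05–4 mM substrate, generated at kcat = 9.70 s⁻¹, KM = 0.62 mM with 3%
noise — synthetic stand-in, see `inst/extdata/`):

```r
kd <- read.csv(system.file("extdata", "wt_kinetics_synthetic.csv",
                           package = "hydrotriad"))
fit <- fit_michaelis_menten(kinetics_dataset(kd$substrate_mM, kd$rate_M_per_s,
                                             enzyme_conc_M = 1e-7))
fit
#> Michaelis-Menten fit
#>   Vmax = 9.977e-07 M/s
#>   KM   = 0.7007 mM (SE 0.035)
#>   kcat = 9.977 1/s (SE 0.17)
#>   kcat/KM = 14.24 1/(s mM)

fold_changes(mm_parameters(9.70, 0.62, "WT"),
             list(D513E = mm_parameters(0.43, 2.30),
                  D513Q = mm_parameters(0.18, 9.89),
                  D513A = "inactive"))
#> Fold changes vs WT
#>  mutant km_fold kcat_fold efficiency_fold   status
#>   D513E    3.71      22.6            83.7       ok
#>   D513Q   15.95      53.9           859.6       ok
#>   D513A      NA        NA              NA inactive
```

A KM fold of 15.95 (~16-fold worse binding for the Gln mutant) and 3.71 for
the Glu mutant, with turnover collapsing 54- and 23-fold — the mutational
signature that the acid position, despite not touching the His, is
catalytically essential.

`screen_panel()` runs the motif + cascade screen over any list of structure
files (e.g. downloaded PDB/mmCIF depositions); on the built-in synthetic
panel only water-mediated sites pass all four filters.

## Command line

A thin CLI lives at `inst/cli/hydrotriad.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hydrotriad.R", package="hydrotriad"))')" \
  classify site.pdb --ser A:112 --his A:515 --acid A:513
```

Subcommands: `info`, `classify`, `coord`, `scan-rotamers`, `screen`,
`kinetics-fit`, `fixtures-make`, `fixtures-panel`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline analyses from scratch against the
installed package: it generates a seeded noisy fixture panel and measures
classifier accuracy, screens a sub-panel with a water-mediated query,
re-derives the exemplar site report and water coordination, runs the
rotamer-infeasibility scan, fits the bundled kinetics data, and prints the
mutant fold-change table, then writes the JSON report to `--out`.

## Vignette

`vignettes/water-mediated-triad.Rmd` documents the classification model and
its parameters, the synthetic stated world and what a green test does and
does not establish, the rotamer-fixture exactness trade-off, and all
numerical/degenerate-input choices.
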
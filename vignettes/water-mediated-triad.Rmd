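---
title: "Classifying water-mediated catalytic triads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying water-mediated catalytic triads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotriad)
```

## The problem

Serine hydrolases activate their nucleophilic serine through a histidine
general base. In the textbook Ser-His-Asp triad the acid hydrogen-bonds the
His Nδ1 directly (heavy-atom distance 2.5-3.0 Å), polarising the imidazole;
in Ser-His dyads a main-chain carbonyl oxygen or amide nitrogen orients the
His instead. Some SGNH-fold carbohydrate esterases present a third
arrangement: the Asp (or Asn) carboxylate sits about 4 Å from Nδ1 — too far
for a hydrogen bond — and a single, precisely coordinated water molecule
bridges the gap, bound at ~2.9 Å to Nδ1 on one side and ~2.9 Å to the acid
oxygen on the other. The water's tetrahedral coordination shell is completed
by a main-chain carbonyl from an ancillary β-sandwich domain and a second
water. Establishing that architecture from a crystal structure requires
several independent geometric arguments, and this package implements each of
them as a reusable, tested operation:

1. the Ser-His pair obeys the **Nε rule** (Ser Oγ hydrogen-bonds His Nε2,
   leaving Nδ1 free for the third partner);
2. no acid side-chain oxygen lies within direct hydrogen-bond distance
   (< 3 Å) of Nδ1;
3. a water oxygen lies within hydrogen-bond distance of both Nδ1 and an
   acid side-chain oxygen, and its coordination shell is close to
   tetrahedral;
4. no χ1/χ2 rotamer of either side chain can produce a clash-free direct
   contact below 3 Å (so the separation is not a conformational accident);
5. the catalytic Cα B-factors are low (the backbone cannot plausibly
   rearrange to close the gap);
6. mutant Michaelis–Menten kinetics show the acid position matters
   (KM and kcat fold changes).

## Classification model

`classify_third_position()` applies a strict decision cascade to a validated
Ser-His pair:

| order | rule | label |
|---|---|---|
| 1 | any Asp/Asn/Glu/Gln side-chain terminus < `direct_cutoff` from Nδ1 | `CONVENTIONAL_TRIAD` |
| 2 | water O within the H-bond window of both Nδ1 and an acid terminus | `WATER_MEDIATED_TRIAD` |
| 3 | main-chain O or N of another residue < `direct_cutoff` from Nδ1 | `MAINCHAIN_DYAD` |
| 4 | otherwise | `BARE_DYAD` |

Exactly one label is assigned; rule 1 strictly precedes rule 2, so a site
with both a direct contact and a water bridge is conventional. When several
waters bridge, the one closest to Nδ1 wins — the architecture is defined by
a *single* precisely coordinated water.

### Parameters that matter

* `direct_cutoff = 3.0` Å — the literal "direct hydrogen bond (shorter than
  3 Å)" rule; used with strict inequality everywhere, so a 3.00 Å contact
  is *not* direct.
* H-bond window `c(2.2, 3.5)` Å — 3.5 Å is the common crystallographic
  heavy-atom ceiling and 2.2 Å the lower bound below which a contact is a
  covalent-bond-or-error; the published bridge bonds (2.9 Å) sit mid-window.
  The stricter 3.0 Å rule belongs to the classifier, not the search, so the
  same partner list serves both purposes.
* tetrahedrality tolerance `angle_tol = 25`° — mean absolute deviation of
  the partner-O-partner angles from 109.5°. No published value exists;
  25° is loose enough to admit real crystallographic waters whose partners
  are chemically heterogeneous, and the fixture suite shows ideal geometry
  scores ≈ 0 and degenerate shells fail. Note the exact tetrahedral angle
  is 109.47°, so even perfect geometry scores ~0.03°.
* clash cutoff `2.5` Å — a conservative heavy-atom hard-sphere floor for the
  rotamer scan; waters are excluded from the clash set because they can
  relocate on the catalytic timescale.
* motif `rmsd_cutoff = 2.0` Å — the published motif-search cutoff; the
  matcher superposes a 13-atom set (Ser Cα/Cβ/Oγ; His Cα/Cβ/Cγ/Nδ1/Nε2;
  acid Cα/Cβ/branch-C/two termini, with Glu/Gln Cδ mapped to the branch
  slot). Cα+Cβ fix residue placement, the functional atoms fix side-chain
  orientation. Amide O/N assignment is crystallographically ambiguous, so
  both terminal orderings are tried and the smaller RMSD kept.

Hydrogens are ignored throughout: the criteria are heavy-atom distance
rules, matching how the distances are reported in crystallographic work.
Donor/acceptor angle terms are deliberately absent for the same reason.

## Rotamer feasibility scanning

`scan_min_distance()` rotates the existing crystal coordinates rigidly about
the χ1 (Cα-Cβ) and χ2 (Cβ-Cγ) axes of both residues on a joint 4-angle grid
(default 10°, i.e. 36⁴ combinations) and reports the minimum Nδ1-to-acid-
oxygen distance with and without clash filtering. Design choices:

* **rotation, not rebuild** — rotating preserves the crystal's internal
  bond geometry exactly, which is what "rotating the side chains" means;
* **backbone fixed** — justified independently by the low catalytic
  B-factors;
* **joint scan** — both side chains may move simultaneously; per-residue
  clash states are precomputed and candidate pairs are visited in ascending
  distance order, so the first mutually clash-free pair is the constrained
  minimum;
* intra-residue contacts are not counted as clashes (they are constrained
  by covalent geometry, and the 1-2/1-3 neighbours of the rotated atoms
  would otherwise always "clash");
* for Asn both Oδ1 and Nδ2 are tried as the contact terminus.

Feasibility is `min_clashfree < contact_cutoff`, strict, mirroring the
"shorter than 3 Å" rule.

## The synthetic stated world

`build_site_fixture()` constructs miniature labelled active sites from ideal
residue templates assembled in code from standard internal coordinates
(bond lengths/angles; the imidazole is a regular 1.37 Å pentagon). The His
is placed first; the Ser Oγ goes on the Nε2 in-plane lone-pair direction;
water and acid are placed on the Nδ1 side by sphere-sphere intersection so
the requested distances are realised *exactly* (to 1e-6 Å) at zero noise.
The defaults are the published exemplar geometry: Oγ-Nε2 2.8 Å, Nδ1-acid-O
4.0 Å, water bonds 2.9/2.9 Å. Optional probes (a main-chain-like carbonyl
and a second water at 2.8 Å, on directions completing a tetrahedron) stand
in for the ancillary-domain carbonyl and the second shell water.

`build_panel()` jitters the nuisance distances inside label-consistent
ranges chosen to be crystallographically sensible (direct contacts
2.5-2.9 Å, bridge bonds 2.5-3.1 Å, far-acid distances 3.7-4.5 Å, Ser-His
2.6-3.2 Å), applies a random rigid motion, and adds seeded isotropic
Gaussian noise *after* constraint satisfaction. Labels are therefore
guaranteed only in distribution at σ > 0: a conventional contact drawn at
2.89 Å can cross the 3.0 Å boundary under σ = 0.1 Å noise. The acceptance
threshold (≥ 95% at σ = 0.1 Å, n = 200) acknowledges exactly this boundary
leakage; observed accuracy is ~97%.

What a green test does establish: the decision rules, the search, the
superposition and the fit are implemented correctly, are mutually
consistent across modules, and are robust to coordinate noise of the size
seen in well-refined structures. What it does not establish: performance on
real crystallographic pathologies (disorder, alternate conformers beyond
simple altloc groups, symmetry-related waters, modelling bias), because the
generator does not emulate them.

### Rotamer fixtures: an exactness trade-off

`build_rotamer_fixture()` has two modes because a single construction
cannot be both exact and chemically clash-free. In `axis` mode the contact
approaches along the extended Cβ-Nδ1 line; since χ rotations preserve every
side-chain atom's distance to its own Cβ, both contact atoms then lie on
the Cβ-Cβ line and the triangle inequality makes the target the *certified
global minimum* of the scan. But that line passes within hard-sphere
distance of the His Cε1 for targets below ~3.3 Å, so `axis` mode is for
unattainability fixtures. In `lonepair` mode the contact approaches along
the Nδ1 lone pair — a genuine hydrogen-bond geometry, clash-free — and the
target pose is realised exactly, but other χ combinations may come closer;
the truth record carries the Cβ-Cβ slack lower bound instead of an exact
minimum. Tests assert accordingly: exact equalities in `axis` mode,
feasibility plus bounds in `lonepair` mode, and equivalence against a naive
nested-loop scan in both.

## Kinetics

`fit_michaelis_menten()` fits v = Vmax·[S]/(KM+[S]) by unweighted nonlinear
least squares (`stats::nls` under the hood), with Vmax₀ = max(v) and KM₀ =
the substrate concentration at half-maximal rate by linear interpolation.
Unweighted least squares matches the graphing-package default used for the
published fits. Rates are rescaled to order 1 internally (Vmax scales
linearly, KM is untouched), which lets noiseless synthetic data recover
parameters to 1e-6 — molar rates are ~1e-7 and would otherwise stall the
convergence test early. Non-convergence returns the last iterate flagged
`converged = FALSE` rather than throwing; all-equal rates are a degenerate
error. Standard errors come from the Jacobian-based covariance at the
optimum.

The noisy-recovery simulation draws triplicate measurements at the seven
published substrate concentrations (0.05-4 mM) with Gaussian noise of 5% of
Vmax — triplicates because that is how the assay is actually run, and the
published parameters are means of three technical replicates. Median KM
error under those conditions is ~7%, within the 10% acceptance band;
single-replicate datasets at the same noise would sit at ~13%, which is a
statement about the assay design, not the fitter.

Inactive mutants are carried as an explicit `"inactive"` sentinel and
excluded from fold-change ratios: complete inactivation has no parameters.
Fold conventions: `km_fold = KM_mut/KM_ref` (> 1 means weaker binding) and
`kcat_fold = kcat_ref/kcat_mut` (> 1 means slower turnover), so both read
"fold worse than reference".

## Numerical and degenerate-input choices

* Altloc resolution keeps the highest-occupancy conformer, ties broken by
  the alphabetically lowest altloc — the standard crystallographic
  convention. Only the first model of multi-model files is read.
* Author residue numbering is authoritative, so published residue numbers
  address the same residues here.
* Waters are recognised by residue name (HOH/WAT/H2O/DOD); a water without
  an oxygen warns.
* Kabsch superposition rejects < 3 points and collinear sets, and the
  reflection case is corrected to a proper rotation; it is tested to 1e-9
  against an independent quaternion (Horn) oracle.
* Symmetry mates are never generated; distances are intra-asymmetric-unit.
  Whether an active-site water is symmetry-related in a given deposition
  is flagged as unknowable here, not guessed.
* Whole-database motif screening is out of scope by design: database
  snapshot counts are not reproducible. `screen_panel()` screens a
  user-supplied panel of files and collapses hits to a per-target boolean.
* Both main-chain carbonyl O and amide N qualify as the main-chain-dyad
  partner (both forms occur in the dyad literature); the partner atom type
  is reported so the caller can distinguish them.
* A covalently modified Ser Oγ (e.g. a cacodylate adduct from the
  crystallisation buffer, detected as a non-water heavy atom within 1.8 Å)
  still counts as a potential nucleophile, with a warning: the exemplar
  structure's own catalytic serine carries such an adduct.

## Limitations

No energetics anywhere: hydrogen bonds are distance windows, clashes are
hard spheres, rotamers carry no library probabilities, and protonation/
tautomer states are not modelled (Nδ1 is assumed acid-facing per the Nε
rule). The kinetics module fits the plain Michaelis–Menten model only — no
substrate inhibition, no global multi-dataset fits. The fixture generator
makes miniature sites, not full proteins; decoy density around a site is
limited to what the panel provides.
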
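---
title: "Classifying kinase-domain conformations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying kinase-domain conformations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinconform)
```

## The model

Eukaryotic protein kinases share a bilobed fold: a β-sheet-rich N-lobe with
the glycine-rich loop, the β3 Ala-x-Lys and the αC helix, and a helical
C-lobe carrying the catalytic loop (H/YRD), the activation segment (DFG …
APE) and the αF helix. Catalysis requires a specific arrangement of these
elements, and crystal structures are routinely sorted into *active* and
*inactive* conformations by a small set of geometric hallmarks. This package
encodes the hallmark set used throughout the recent kinase literature:

1. **Spatial DFG placement.** The DFG-Phe ring position is summarised by two
   distances to fixed N-lobe reference atoms: D1 from the Cα of the residue
   four past the αC Glu to the Phe Cζ, and D2 from the β3-Lys Cα to the same
   Cζ. A ring buried under αC gives small D1 and large D2 (DFGin); the
   flipped arrangement gives DFGout; intermediate placements are DFGinter.
2. **Dihedral cluster.** The backbone (φ, ψ) of the residue before the DFG
   Asp ("X-DFG"), of the Asp and of the Phe, each mapped to a coarse
   Ramachandran region (A: α; B: β/extended; L: left-handed α; E: extended
   left), plus the Phe χ₁ rotamer bin (minus [−120°, 0°), plus [0°, 120°),
   trans otherwise), concatenated: BLAminus is the catalytically primed
   cluster, BLAplus a common inactive neighbour.
3. **β3-Lys/αC-Glu salt bridge** (minimum side-chain N–O distance), which
   doubles as the αC-in/out readout: a formed bridge requires the αC helix
   rotated in.
4. **Hydrophobic spines.** The regulatory spine (β4 hydrophobic, αC-Glu+4,
   DFG-Phe, catalytic-loop aromatic) must stack, and its catalytic-loop
   member is anchored to the αF-helix Asp by a hydrogen bond; the catalytic
   spine (β2/β3 hydrophobics, the adenine ring of bound nucleotide, and the
   αD/αF-region hydrophobics) reports productive nucleotide seating.
5. **Activation-segment phosphorylation**, read from modified residues
   (phosphothreonine TPO, phosphoserine SEP, phosphotyrosine PTR) between
   the DFG Asp and the APE motif.

The composed verdict is deliberately conservative: *active* only when the
salt bridge is present **and** the spatial group is DFGin **and** the cluster
is BLAminus **and** the R-spine is assembled; *indeterminate* whenever
missing atoms leave any of those four components undefined, because absence
of density (a disordered activation loop is common in inactive mutants) is
evidence of flexibility, not of any particular geometry.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| D1/D2 thresholds `t1`, `t2` | 11.0 / 11.0 | Å | the D1/D2 construction defines the groups; printed cutoffs are rarely reported with them, so the thresholds are configuration with a literature-conventional default |
| salt-bridge cutoff | 4.0 | Å | min over Lys NZ (Arg NH1/NH2/NE) × Glu OE1/OE2 (Asp OD1/OD2) |
| spine contact cutoff | 4.5 | Å | min heavy-atom distance between consecutive members |
| H-bond cutoff | 3.5 | Å | R-spine αF anchor and protein–nucleotide polar contacts |
| Ramachandran boundaries | ψ ∈ [−100, 50) is A for φ < 0; ψ ∈ [−50, 100) is L for φ ≥ 0 | degrees | rectangular approximations, configurable |
| trim defaults | 5 cycles, factor 2.0 | — | outlier rejection for superposition |

All cutoffs live in a single `kin_config()` object and are echoed verbatim
into every report, so a report is interpretable without the session that
produced it.

## Numerical choices

* **Angles.** Degrees in every public interface, normalised to (−180, 180];
  the torsion sign convention is the standard right-handed one (cis = 0),
  cross-checked in the tests against three independent implementations.
* **Altloc policy.** Highest occupancy wins, ties break toward altloc "A";
  repeated parses are bit-identical. Only model 1 of multi-model files is
  read; NMR ensembles are out of scope.
* **Missing atoms are never invented.** Absence propagates as explicit
  incompleteness flags that end in the `indeterminate` verdict, per above.
* **Superposition.** Kabsch via singular value decomposition with a
  determinant correction (proper rotations only). Trimming drops pairs
  deviating by more than `factor ×` current RMSD, refits, and repeats up to
  `cycles`; the rejection cutoff is floored at `factor × 1 µÅ` so an exactly
  superposable pair set cannot shed pairs on machine noise. Both untrimmed
  and trimmed RMSD are always reported, because published pair counts rarely
  state how outliers were handled.
* **Neighbor-Joining.** Studier–Keppler Q criterion; ties broken toward the
  lowest (row, column) index pair in the current matrix order — determinism
  is part of the public contract, in preference to bit-compatibility with
  any one external NJ implementation (whose tie-breaks are unspecified).
  Negative branch lengths are clamped to zero. On additive matrices the
  algorithm is exact; the tests verify recovery of random 4–12-taxon trees
  to 1e-9 and topological agreement with the ape implementation.
* **Bootstrap.** Column resampling with replacement, seeded; supports are
  the percentage of replicates containing each internal bipartition of the
  full-data tree (bipartitions canonicalised to the side not containing the
  alphabetically first taxon). A replicate with an undefined pairwise
  distance is redrawn, up to a retry cap.
* **Gap handling.** p-distance uses pairwise deletion of gap/X columns by
  default (complete deletion available); percent identity defaults to the
  compared-sites denominator, with alignment-columns and shorter-sequence
  policies available — published identity percentages depend on an unstated
  alignment and denominator, so these figures are treated as
  validation-only.
* **Duncan's multiple range test.** Critical ranges
  `r_p = q((1−α)^(p−1); p, df) · sqrt(MSE/n)` use studentized-range
  quantiles from `stats::qtukey` (numerical inversion of the range CDF),
  which reproduce the published Duncan tables to their printed precision;
  unbalanced designs use the harmonic mean n; the protection rule (spans
  inside a non-significant span stay non-significant) and insert-and-merge
  lettering follow the classical procedure. Amplification efficiency in
  2^−ΔΔCt is fixed at 2; per-replicate folds are taken against the
  calibrator's mean ΔCt so that error bars are computable.

## The synthetic-data generator

`build_toy_kinase()` grows an ideal-geometry backbone by internal-coordinate
chain extension (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å, ω = 180°)
realising requested φ/ψ exactly, and places the classification-defining
atoms by direct construction: the DFG-Phe Cζ on the intersection circle of
the two D1/D2 spheres (nearest the Phe Cγ), the β3-Lys NZ along the line to
the αC-Glu OE1 at the requested bridge distance, the αF-Asp carboxylate at
the requested anchor-bond distance from the catalytic-loop backbone, and
spine contact atoms along lines with the requested spacing. The default
architecture plants the conserved motifs at kinase-domain-style author
numbering (Gly loop 99/101/104, β3 Ala-x-Lys 122–124, αC-Glu 140,
catalytic-loop YRD 217, DFG 237, phospho-sites 250/253/254, APE 260, αF Asp
278) on a 201-residue chain starting at residue 95; a β-hairpin between β3
and αC keeps the two D1/D2 reference Cα atoms ~12.5 Å apart so that the
default constraints are geometrically realisable, and the builder raises an
explicit error for distance triples violating the triangle inequality.
Default geometry targets (D1/D2 = 8/14 Å, bridge 3.0 Å, spine spacing
4.0 Å, anchor bond 3.0 Å, BLA regions with χ₁ = −60°) are the canonical
active-state values; "broken" variants (bridge 6 Å, spacing 8 Å) sit far on
the other side of each cutoff.

What the toys do **not** emulate: real side-chain rotamer libraries (side
chains carry only the atoms the classifier reads), crystallographic noise,
alternate conformations, realistic ligand stereochemistry (the nucleotide is
a schematic adenine ring stacked into the C-spine plus phosphate oxygens at
the Gly loop), or sequence diversity. Passing round-trip tests therefore
demonstrates that the pipeline measures exactly what the specification
encodes — not that the thresholds are optimal for any particular
crystallographic data set; validation against deposited coordinates is
available whenever network access to the PDB is (`fetch_structure()`), and
the corresponding checks in the acceptance suite run the identical pipeline
on the downloaded entries.

The alignment simulator evolves a uniform-random root sequence along a given
tree with Poisson(branch length × rate × columns) substitutions per branch —
a deliberately minimal Jukes–Cantor-style process with no rate heterogeneity
or indels, sufficient to give NJ/bootstrap known ground truth. The Ct-table
simulator writes `Ct_target = base − log2(fold) + N(0, σ)` against a
constant-baseline reference gene, so the 2^−ΔΔCt estimator recovers folds
exactly at σ = 0.

## Design decisions that were genuinely open

* **αC-in/out as the salt-bridge proxy.** A helix-axis measurement would
  need a reference frame the classification otherwise does not require; the
  bridge and the helix position are mechanically coupled, so the bridge
  carries the αC status and is labelled as a proxy in the report.
* **Motif-scan windows** (β3 Ala-x-Lys 10–45 residues past the Gly loop;
  αC-Glu 8–25 past the β3 Lys; DFG 10–35 past the catalytic loop; APE 20–35
  past DFG) follow canonical kinase-domain architecture, measured between
  match starts; every anchor accepts an explicit override
  (`"chain:resno"`), which is also the intended route for mutants whose
  motif residue is substituted (a K→R mutation at the β3 Lys breaks the
  Ala-x-Lys scan by construction).
* **Spine membership** is resolved positionally from the scanned anchors
  (β4 hydrophobic at αC-Glu+15 ± 2, αF Asp at catalytic-loop+61 ± 2, and so
  on), with small local scans for the expected residue class; members that
  cannot be located degrade to spine incompleteness rather than a hard
  error, since partial models are the norm in crystallography. The C-spine
  C-lobe membership uses the catalytic-loop triplet (+8…+10) and αD/αF
  hydrophobics.
* **Dual roles of the DFG Asp.** The Asp both chelates the catalytic Mg²⁺
  and names the motif; the anchors record the single residue without
  asserting one nomenclature.
* **Water-mediated nucleotide contacts are excluded** by default: reported
  contact lists are direct H-bonds, and water networks vary with resolution.
* **Missing APE**: when no APE (or x-P-E) match exists in window, the
  activation segment defaults to DFG-Asp + 30 residues, the usual segment
  span.

## Problem sizes in the test and acceptance suites

The suites use 100 seeded toy-kinase specifications for the round-trip
property, 100 random fixtures per geometry oracle, 50 random trees (4–12
taxa) for NJ recovery, 100–200 bootstrap replicates on the conflict-free
alignment, and 300–500 simulation seeds for the fold-recovery study — sizes
chosen so the full property battery gives stable pass/fail behaviour while
the whole suite runs in well under a minute on one core.

## Known limitations

* The Ramachandran regions are rectangles, not density-based contours; a
  handful of borderline (φ, ψ) pairs near region boundaries can be labelled
  differently than a contour-based assignment would.
* DFGinter is a single catch-all group; no sub-clusters are assigned.
* Anchor resolution is sequence-based; heavily engineered constructs with
  duplicated motifs will need overrides (ambiguous in-window matches raise
  an error rather than guessing).
* The phospho-site reader trusts modified-residue records (TPO/SEP/PTR);
  phosphorylation annotated only in header remarks is not detected.
* No flexible or sequence-based structural alignment: superposition pairs
  residues strictly by author numbering under a chain map.
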
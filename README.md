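# kinconform

Conformational-state classification of protein kinase domain structures, with
the supporting phylogenetic and qPCR-statistics utilities used alongside such
structural studies.

## What it does, and for whom

Whether a protein kinase is captured in an **active** or **inactive**
conformation is read off a small set of structural hallmarks that structural
biologists check by hand in PyMOL: where the DFG-motif phenylalanine ring
sits, the backbone cluster of the X-DFG residues, the β3-Lys/αC-Glu salt
bridge, and whether the two hydrophobic "spines" that span the N- and C-lobes
are stacked. `kinconform` turns that checklist into a reproducible, tested
pipeline for PDB/mmCIF coordinate models — aimed at anyone characterising a
new kinase structure (e.g. a plant receptor-like cytoplasmic kinase domain
and its site-directed mutants) who wants the classification, the distances
behind it, and a machine-readable report.

The classification per structure:

* **Spatial DFG group** — with Cζ the DFG-Phe ring carbon,
  `D1 = |Cα(αC-Glu+4) − Cζ|` and `D2 = |Cα(β3-Lys) − Cζ|`;
  DFGin if `D1 ≤ t1 ∧ D2 ≥ t2`, DFGout if `D1 > t1 ∧ D2 ≤ t2`, else
  DFGinter (defaults `t1 = t2 = 11 Å`).
* **Dihedral cluster** — Ramachandran region (A/B/L/E) of the X-DFG, DFG-Asp
  and DFG-Phe backbone plus the DFG-Phe χ₁ rotamer bin
  (gauche-minus/plus/trans), concatenated into names such as **BLAminus**
  (the catalytically primed cluster) or BLAplus.
* **Salt bridge / αC status** — minimum side-chain N–O distance between the
  β3 Lys and the αC Glu (present ≤ 4.0 Å ⇔ αC "in").
* **Spine assembly** — minimum heavy-atom gaps along the regulatory spine
  (β4-Leu, αC-Glu+4 Leu, DFG-Phe, catalytic-loop aromatic, anchored by an
  H-bond to the αF-helix Asp) and the catalytic spine (completed by the
  adenine ring of a bound nucleotide); assembled when every adjacent gap
  ≤ 4.5 Å.
* **Nucleotide contacts and activation-segment phospho-sites** (modified
  residues TPO/SEP/PTR between DFG and APE).
* **Verdict** — *active* ⇔ salt bridge ∧ DFGin ∧ BLAminus ∧ R-spine
  assembled; *indeterminate* when missing density leaves a component
  undefined.

Around the classifier: Kabsch superposition with iterative outlier trimming
for inter-structure RMSD; p-distance + Neighbor-Joining phylogenies with
bootstrap supports; ORF/protein-length and average-mass arithmetic, percent
identity, motif scanning (e.g. the RIN4 `[FY]Txx[F]xK` phospho-motif); qPCR
relative expression by 2^−ΔΔCt with Duncan's multiple-range-test letters and
Student's t-tests; and a synthetic-data module that builds toy kinase
coordinate models, tree-evolved alignments and Ct tables with known ground
truth so every stage is testable offline.

## Worked example

```r
library(kinconform)

m <- build_toy_kinase(toy_kinase_spec())   # fully active toy kinase domain
a <- find_anchors(extract_sequence(m, "A"))
classify_state(m, a)
```

```
Conformation report for toy_kinase_seed1
  spatial DFG: DFGin (D1 = 8.00, D2 = 14.00 A)
  dihedral cluster: BLAminus
  salt bridge A:124-A:140: present (min N-O 3.00 A)
  R-spine: assembled;  C-spine: assembled
  nucleotide contacts: 4 residue(s); phospho-sites: 250, 253, 254
  alphaC: in;  verdict: ACTIVE
```

Reading: the DFG-Phe Cζ is 8.0 Å from the αC-Glu+4 Cα and 14.0 Å from the
β3-Lys Cα, so the Phe ring packs under the αC helix (DFGin); the X-DFG
backbone trio falls in the B, L and A Ramachandran regions with a
gauche-minus Phe χ₁ (BLAminus); Lys124–Glu140 form a 3.0 Å salt bridge (αC
in); both spines are stacked; three phosphorylated residues sit in the
activation segment — every hallmark of an active kinase, hence the verdict.
Weakening any one hallmark (e.g. `toy_kinase_spec(bridge = 6)` or
`rotamer = "plus"`) flips the verdict to inactive.

For real structures: `cmd_analyze("structure.pdb", chain = "A")` writes the
same report as JSON and markdown; `cmd_compare(a, b)` reports trimmed and
untrimmed Cα RMSD; `cmd_phylo()` and `cmd_expr()` cover the phylogeny and
expression stages. A thin shell wrapper over these functions ships at
`inst/cli/kinconform.R`.

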
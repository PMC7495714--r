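# European mtDNA haplogroup phylogeny with the 39-locus typing panel.
#
# Coordinates are rCRS (1..16569), 1-based; alleles on the heavy strand.
# Each node lists the defining SNPs of the branch leading to it (root->leaf
# order within a node).  The exact assayed panel of the original typing
# design is not public; this document is a reconstruction of the published
# macro-topology with canonical PhyloTree-style defining variants per
# branch.  The three branches with published rsIDs (H4, HV, HV0a) carry
# those variants exactly.  Users may substitute their own panel document.
name: european-mtdna-39snp-panel
root: "N"
panel:
  - 73
  - 295
  - 462
  - 489
  - 1438
  - 1719
  - 2706
  - 3010
  - 3197
  - 3348
  - 3992
  - 4216
  - 4580
  - 5004
  - 5633
  - 6221
  - 6371
  - 6776
  - 7028
  - 8269
  - 8994
  - 9055
  - 9698
  - 10238
  - 10398
  - 10463
  - 10499
  - 11467
  - 11674
  - 11812
  - 12633
  - 12705
  - 13368
  - 14070
  - 14139
  - 14766
  - 15904
  - 16270
  - 16298
nodes:
  - name: "N"
    parent: ~
    european: true
    snps: []
  - name: N1
    parent: "N"
    european: true
    snps:
      - {position: 10238, ancestral: T, derived: C}
  - name: I
    parent: N1
    european: true
    snps:
      - {position: 1719, ancestral: G, derived: A}
      - {position: 10398, ancestral: A, derived: G}
  - name: W
    parent: "N"
    european: true
    snps:
      - {position: 8994, ancestral: G, derived: A}
      - {position: 11674, ancestral: C, derived: T}
  - name: X
    parent: "N"
    european: true
    snps:
      - {position: 6221, ancestral: T, derived: C}
      - {position: 6371, ancestral: C, derived: T}
  - name: R
    parent: "N"
    european: true
    snps:
      - {position: 12705, ancestral: T, derived: C}
  - name: R0
    parent: R
    european: true
    snps:
      - {position: 73, ancestral: G, derived: A}
  - name: HV
    parent: R0
    european: true
    snps:
      - {position: 14766, ancestral: T, derived: C, rsid: rs193302980, locus_label: MT-CYB}
  - name: H
    parent: HV
    european: true
    snps:
      - {position: 2706, ancestral: G, derived: A, locus_label: MT-RNR2}
      - {position: 7028, ancestral: T, derived: C, locus_label: MT-CO1}
  - name: H1
    parent: H
    european: true
    snps:
      - {position: 3010, ancestral: G, derived: A}
  - name: H2
    parent: H
    european: true
    snps:
      - {position: 1438, ancestral: G, derived: A}
  - name: H3
    parent: H
    european: true
    snps:
      - {position: 6776, ancestral: T, derived: C}
  - name: H4
    parent: H
    european: true
    snps:
      - {position: 3992, ancestral: C, derived: T, locus_label: MT-ND1}
      - {position: 5004, ancestral: T, derived: C, rsid: rs41419549, locus_label: MT-ND2}
  - name: HV0a
    parent: HV
    european: true
    snps:
      - {position: 15904, ancestral: C, derived: T, rsid: rs35788393, locus_label: MT-TT}
  - name: V
    parent: HV0a
    european: true
    snps:
      - {position: 16298, ancestral: T, derived: C}
      - {position: 4580, ancestral: G, derived: A}
  - name: JT
    parent: R
    european: true
    snps:
      - {position: 4216, ancestral: T, derived: C}
  - name: J
    parent: JT
    european: true
    snps:
      - {position: 295, ancestral: C, derived: T}
      - {position: 489, ancestral: T, derived: C}
  - name: J1
    parent: J
    european: true
    snps:
      - {position: 462, ancestral: C, derived: T}
  - name: J1d
    parent: J1
    european: true
    snps:
      - {position: 8269, ancestral: G, derived: A}
  - name: J2a
    parent: J
    european: true
    snps:
      - {position: 10499, ancestral: A, derived: G}
  - name: J2b
    parent: J
    european: true
    snps:
      - {position: 5633, ancestral: C, derived: T}
  - name: T
    parent: JT
    european: true
    snps:
      - {position: 10463, ancestral: T, derived: C}
      - {position: 13368, ancestral: G, derived: A}
  - name: T1
    parent: T
    european: true
    snps:
      - {position: 12633, ancestral: C, derived: A}
  - name: T2
    parent: T
    european: true
    snps:
      - {position: 11812, ancestral: A, derived: G}
  - name: U
    parent: R
    european: true
    snps:
      - {position: 11467, ancestral: A, derived: G}
  - name: U1
    parent: U
    european: true
    snps:
      - {position: 14070, ancestral: A, derived: G}
  - name: U3
    parent: U
    european: true
    snps:
      - {position: 14139, ancestral: A, derived: G}
  - name: U5
    parent: U
    european: true
    snps:
      - {position: 3197, ancestral: T, derived: C}
      - {position: 16270, ancestral: C, derived: T}
  - name: U6
    parent: U
    european: true
    snps:
      - {position: 3348, ancestral: A, derived: G}
  - name: K
    parent: U
    european: true
    snps:
      - {position: 9055, ancestral: G, derived: A}
      - {position: 9698, ancestral: T, derived: C}
# Secondary-analysis grouping: phylogenetically related haplogroups are pooled
# into super-haplogroups.  Only the groupings with published evidence (JT and
# UK) pool more than one haplogroup; all remaining nodes map to themselves.
super_map:
  JT: JT
  J: JT
  J1: JT
  J1d: JT
  J2a: JT
  J2b: JT
  T: JT
  T1: JT
  T2: JT
  U: UK
  U1: UK
  U3: UK
  U5: UK
  U6: UK
  K: UK
  "N": "N"
  N1: N1
  I: I
  W: W
  X: X
  R: R
  R0: R0
  HV: HV
  H: H
  H1: H1
  H2: H2
  H3: H3
  H4: H4
  HV0a: HV0a
  V: V
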
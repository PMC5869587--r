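# rhebanchor

Rheb is a Ras-family GTPase that activates the (m)TORC1 kinase complex; its
function depends on membrane attachment, canonically through prenylation of a
C-terminal CaaX box (Cys–aliphatic–aliphatic–X). Across the eukaryote tree
this canonical anchor has repeatedly been remodelled: N-terminal fusions of
the PI3P-binding PX or FYVE domains, N-terminal myristoylation and/or
S-palmitoylation, C-terminal palmitoylation alongside the CaaX box,
replacement of the CaaX box by a four-transmembrane extension ("Rheb-TM"),
or by a tryptophan-rich tail, and outright loss of any evident anchor.

`rhebanchor` turns that comparative analysis into a tested, reusable R
pipeline for people studying GTPase membrane-attachment evolution:

* **Anchor detection** per protein sequence: CaaX box (cysteine exactly 4th
  from the C-terminus), N-myristoylation (Gly-2 only; three deterministic
  surrogate scorers, called at ≥ 2 of 3 votes), S-palmitoylation of cysteines
  (five surrogate scorers over the ±9-residue context, called at ≥ 3 positive
  votes among the non-abstaining scorers, with a-priori exclusion of
  cysteines inside conserved domains and of the CaaX cysteine), a
  Kyte–Doolittle sliding-window transmembrane caller (window 19, threshold
  1.6), and the W-rich C-terminal motif (2–3 tryptophans in the last 10
  residues, only in the absence of a CaaX box).
* **Domain scanning**: the GTPase domain via the G1/G3/G4 boxes
  (`GxxxxGK[S/T]`, `DxxG`, `[N/T]KxD` with Ras-fold spacing), the
  Rheb-diagnostic β1 arginine immediately upstream of the P-loop, and
  N-terminal PX/FYVE fingerprints.
* **Architecture classification** into a twelve-class taxonomy (A–L) defined
  by the N-terminal device set {PX, FYVE, MYR, PALM_N} and C-terminal device
  set {CAAX, PALM_C, TM, WMOTIF}, plus `UNANCHORED` and `UNCLASSIFIED`.
* **Parsimony mapping** of protein-form gains and losses on a rooted species
  tree: Dollo parsimony (single gain, minimal independent losses, `?`
  unconstrained) for presence/absence characters and Fitch/Hartigan
  minimum-change parsimony (polytomy-aware) for multistate architecture
  characters.
* **A seeded synthetic generator** that plants each architecture on a clean
  GTPase scaffold with full ground truth, replacing the original study data
  as the testbed.

## Worked example

```r
library(rhebanchor)

# plant one exemplar of every architecture class and classify them back
ex  <- rheb_exemplars(seed = 1)
res <- annotate_set(ex$proteins)
res$table[, c("id", "class_label", "n_devices", "c_devices", "tm_count")]
#>               id class_label       n_devices   c_devices tm_count
#> 1  exemplar_A_s1           A                        CAAX        0
#> 2  exemplar_B_s1           B              PX        CAAX        0
#> 3  exemplar_C_s1           C            FYVE        CAAX        0
#> 4  exemplar_D_s1           D FYVE+MYR+PALM_N                    0
#> 5  exemplar_E_s1           E        FYVE+MYR                    0
#> 6  exemplar_F_s1           F            FYVE                    0
#> 7  exemplar_G_s1           G      MYR+PALM_N                    0
#> 8  exemplar_H_s1           H             MYR                    0
#> 9  exemplar_I_s1           I          PALM_N        CAAX        0
#> 10 exemplar_J_s1           J             MYR CAAX+PALM_C        0
#> 11 exemplar_K_s1           K                          TM        4
#> 12 exemplar_L_s1           L                      WMOTIF        0
```

All twelve planted classes are recovered; the Rheb-TM exemplar (class K)
shows the four predicted transmembrane segments of its C-terminal extension,
and the apusomonad-style class J exemplar combines a CaaX box with
C-terminal palmitoylation sites (and, optionally, myristoylation — three
distinct lipid modifications on one protein).

Gain/loss mapping works from a newick tree and a tip-state table:

```r
tree <- ape::read.tree(text = "((A,B),(C,D));")
dollo_reconstruct(tree, c(A = 1, B = 1, C = 0, D = 1))
#> gain at the root, one loss on the edge to C
```

A thin command-line wrapper with `annotate` / `events` / `simulate`
subcommands is included at `inst/scripts/rhebanchor-cli.R`.

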
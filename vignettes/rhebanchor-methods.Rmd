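---
title: "Methods: anchor detection, architecture classes and gain/loss parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor detection, architecture classes and gain/loss parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhebanchor)
```

## The problem

Ras-family GTPases such as Rheb attach to membranes through devices encoded
in the regions flanking their conserved GTPase domain: canonically a
C-terminal CaaX box whose cysteine is prenylated, but in many protist
lineages also N-terminal PX or FYVE phosphoinositide-binding domains,
N-myristoylation of a glycine at position 2, S-palmitoylation of cysteines
near either terminus, C-terminal transmembrane extensions, or a
tryptophan-rich tail. `rhebanchor` (i) detects these devices on protein
sequences, (ii) classifies each protein into a twelve-class architecture
taxonomy, and (iii) reconstructs gains and losses of the resulting protein
forms on a rooted species phylogeny by parsimony. A seeded synthetic
generator provides ground-truth test data.

## Surrogate ensemble scorers

Published acylation predictors are interactive web services and cannot be
embedded in a reproducible pipeline. The package therefore keeps the
*architecture* of the original analysis — several independent scorers vote,
and a site is called only above a vote threshold, after a-priori exclusion
rules — but replaces each web tool with a small deterministic surrogate:

* **Myristoylation** (3 scorers, call at ≥ 2 votes; only Gly-2 of the
  full-length protein is ever a candidate, because internal glycines would
  require proteolytic exposure): a pattern scorer on positions 3 and 7, a
  position-weight-matrix scorer over positions 2–9 (shipped as
  `myr_pwm.tsv`), and a composition scorer on positions 6–7.
* **Palmitoylation** (5 scorers over the ±9-residue window around each
  cysteine, call at ≥ 3 positive votes among non-abstaining scorers):
  mean hydropathy ≥ 0.5; ≥ 2 basic residues; a shipped per-residue weight
  table summing positive; no proline at +1 and < 4 acidic residues; and a
  combined scorer that *abstains* when fewer than 9 residues flank the site
  — mirroring predictors that cannot evaluate near-terminal cysteines.
  Cysteines inside GTPase/FYVE/PX domain spans are excluded (`IN_DOMAIN`),
  as is the CaaX cysteine (`CAAX_CYS`, it is almost certainly prenylated).

Both weight tables are calibrated against two fixed anchors: the table must
score the myristoylation start `MGNSSDKE` positive — the one N-terminus in
this protein family whose myristoylation has been confirmed experimentally
(mass spectrometry after co-expression with N-myristoyl transferase) — and
the palmitoylation weights must score the planted cysteines of the
dual-acylation exemplar positive. The surrogates make no attempt to
reproduce the numerical scores of any published tool; they reproduce the
voting logic, the exclusion rules and the two anchored calls. All thresholds
are configuration, and tests verify that moving a threshold across a
constructed two-vote boundary case changes the call.

## CaaX, W-motif and the permissive box definition

A CaaX box is called iff the residue exactly 4th from the C-terminus is a
cysteine; prenyltransferases are specific for C-terminally located
cysteines, so internal cysteines never qualify. Because divergent boxes
occur in this family, the definition is deliberately permissive about the
two "a" positions; a `strict` flag records whether both are in
{A,V,L,I,F,M,C,S,T}. The tryptophan motif is 2 or 3 W residues within the
last 10 residues (window configurable; the motif is terminal in all known
members) and is suppressed whenever a CaaX box is present — a prenylatable
terminus takes precedence.

## Transmembrane caller

`call_tm_segments()` is a classic Kyte–Doolittle sliding-window caller:
window 19, threshold 1.6 (the standard heuristics for transmembrane
detection with this scale), centre-assigned means, maximal qualifying runs
expanded by half a window, merged across gaps < 5 residues, minimum segment
length 15. No topology model is attempted. Window sums are computed in exact
integer tenths (the scale has one decimal), so threshold ties cannot flip
with summation order. The defaults were calibrated so that the shipped
four-block Rheb-TM template yields exactly four segments; during that
calibration it emerged that charged loops shorter than 15 residues between
21-residue hydrophobic blocks are bridged by the ±9 segment expansion and
merge into a single segment, so the generator's template uses 17-residue
loops — comfortably apart, while each block is still called individually.

## Domain scanning

The GTPase domain is recognised from three G boxes in order — G1
`GxxxxGK[S/T]`, G3 `DxxG` starting 40–110 residues after G1, G4 `[N/T]KxD`
starting 10–60 residues after G3 — with the hit span padded −10/+40 to
approximate the full fold; over-padding is intentional, since its main
consumer is the palmitoylation exclusion rule and over-exclusion is the
safe direction. Rheb-likeness additionally requires an arginine in the 10
residues immediately upstream of G1 (the β1 strand precedes the P-loop in
the Ras fold). PX (`RR[F/Y]SDF`) and FYVE (`RRHHCRxCG` plus ≥ 2 further
`CxxC` pairs) are searched only within a 60-residue window N-terminal to
the GTPase span — how far upstream such fusions begin is an open choice;
60 residues covers a compact zinc-finger-sized module. Wildcards never
match the ambiguity character `X`: an unknown residue is never evidence.
Patterns ship as a replaceable text file; real-world use can substitute
richer profiles without touching code.

## Architecture classes

Classification is a pure lookup from the two device sets (see
`?architecture_label`): A–L, `UNANCHORED` for a Rheb-like protein with no
device at all (a real situation — one diplonemid paralog has lost the
prenylation motif without gaining anything detectable), `UNCLASSIFIED` for
everything else, including proteins that fail the Rheb-likeness test.
Class J is keyed on its C-terminal set {CAAX, PALM_C} with any N-terminal
set, because its two known members differ in N-myristoylation; class K is
keyed on {TM} alone. The mapping is total and deterministic: the test suite
enumerates all 16 × 16 device-set combinations. The classifier reports the
full device trace so borderline cases (e.g. an N-terminal extension whose
cysteines fall short of the vote threshold) can be audited rather than
silently forced into a class.

## Parsimony

Presence/absence characters use **Dollo parsimony**: the single gain is
placed at the MRCA of the tips carrying the character; a loss is charged on
every edge from a retaining node to a child whose subtree contains no
presence but at least one definite absence. Missing data (`?`) is
unconstrained and never forces a loss — an unsequenced transcriptome must
not inflate loss counts. This placement provably minimises losses under the
single-gain constraint, and the tests verify equality with exhaustive
enumeration of all single-gain labelings on trees of up to 7 leaves.

Multistate architecture characters use **Fitch parsimony** generalised to
polytomies (Hartigan's method: a node's candidate set is the set of states
attaining the maximal count over its children's sets, adding
children-minus-maximum to the change count). The top-down pass returns one
optimal labeling with ties broken towards the lexicographically smallest
state — determinism for testing; all co-optimal labelings share the change
count, which is what is reported. Dollo was chosen for gene/form presence
(a complex fusion protein is gained once and lost repeatedly), Fitch where
repeated transitions are plausible; the event report records the method per
character.

## The synthetic generator

`make_scaffold()` emits a ~174-residue Rheb-like core: planted G1/G3/G4
boxes at fixed offsets satisfying the scanner's spacing windows, the β1
arginine two residues before G1, a 12-residue hypervariable tail, and
filler drawn from {A,E,Q,S,T,K,N,V,L,D}. The filler alphabet excludes every
residue required by a shipped fingerprint (C, G, R, H, F, W) and the
strongly hydrophobic I/M, so devices cannot arise by chance; a
rejection-resampling pass removes the remaining boundary-straddling
accidental matches (in practice only spurious `[N/T]KxD` occurrences are
possible). `plant_architecture()` adds the class-specific blocks: the
verified `MGNSSDKE` start for myristoylation classes, a dual-acylation
start with cysteines at positions 3 and 7, 60-residue FYVE/PX blocks,
`CVVM` CaaX boxes, a class-J tail with one or two cysteines 9–13 residues
upstream of the CaaX cysteine, the four-transmembrane extension with the
relict internal CaaX cysteine placed in a charged linker (conserved in real
Rheb-TM sequences, but deliberately in a context that fails the
palmitoylation vote, as its internal position makes prenylation
impossible), and the tryptophan tail. Mutations at a configurable
per-residue rate touch filler positions only; planted critical positions
are protected, because the generator tests detector logic, not the
mutational robustness of the motifs themselves.

What the generator does *not* emulate: real sequence divergence (no
substitution matrices, no indels), compositional heterogeneity, partial or
misassembled transcripts, or genuinely ambiguous boxes. Passing the
round-trip tests therefore shows that the detectors implement their
definitions correctly and compose correctly — not that the surrogate
scorers would match web-server predictions on real proteins.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 12 exemplars per seed for
round-trips (50 seeds at substitution rate 0.02 for the regression guard);
1,000 random sequences for the CaaX oracle and 200 for the transmembrane
oracle; 25 random trees of 4–7 leaves for the brute-force parsimony
comparisons (exhaustive enumeration is exponential, so small trees are
where an oracle is honest); a 30-leaf tree × 200 simulation seeds for
loss-set recovery, counting only *identifiable* replicates — those where
every loss edge's parent retains a present descendant and the MRCA of
present tips is still the gain node; outside that class the true history is
not the most parsimonious one and no method could recover it exactly.
Degenerate inputs are defined rather than erroneous: sequences shorter than
the window yield no segments, an all-absent character has no gain and zero
losses, `loss_prob = 1` kills every lineage below the gain. All randomness
flows from explicit integer seeds, and generation restores the caller's RNG
state.

## Known limitations

* The surrogate scorers are calibrated to two anchors only; their
  false-positive/negative behaviour on real, divergent sequences is
  uncharacterised by design.
* Domain detection is fingerprint-based; a degenerate FYVE domain lacking
  the canonical core would be missed (no profile HMMs).
* A single hydropathy caller stands in for the two transmembrane predictors
  a careful analysis would cross-check; borderline fourth segments can be
  sensitive to the threshold, which is why it is configuration.
* Parsimony operates on a fixed input tree; tree inference, reconciliation
  and likelihood-based ancestral reconstruction are out of scope.
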
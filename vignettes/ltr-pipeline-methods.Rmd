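---
title: "Methods: mining, classifying and dating LTR retrotransposons"
author: "tetraltr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, classifying and dating LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tetraltr` re-implements, as a tested pipeline, the standard survey protocol
for full-length LTR retrotransposons in compact fish genomes:

1. **Detection** — candidate elements are paired similar direct repeats
   (the two LTRs) bounding a 4–10 kb span.
2. **Annotation** — six-frame ORF discovery, domain detection (Gag, a Pol
   core, RT, RH, INT, Env), DDE-triad localisation inside the integrase,
   structural layout typing, and the *full-length* verdict: LTRs at both
   ends, an encoded protein longer than 500 aa, and a detectable RT domain.
3. **Classification** — greedy clustering at ≥ 50% nucleotide identity,
   center-star consensus per cluster, LTR boundary refinement, family and
   superfamily assignment against a reference panel (Gypsy ⊃ Gmr, Mag,
   V-clade, CsRN1, Barthez; ERV ⊃ Orthoretrovirinae, Epsilon retrovirus;
   plus BEL-PAO and Copia), and a neighbor-joining tree of Pol proteins as
   classification support.
4. **Dating** — Kimura two-parameter divergence K converted to an insertion
   time t = K / (2 r) in millions of years with r = 1e-8
   substitutions/site/year, and per-family age landscapes (genome coverage
   per age bin).

A synthetic-genome generator implants elements of known family geometry,
copy class and age, so that every stage is verified against ground truth at
desk scale.

# Detection

Exact k-mer seeds (default k = 13) shared by two loci whose separation is
compatible with the element-span window are merged per diagonal and
extended without gaps under an X-drop rule (match +1, mismatch −2, drop
threshold 30).  Identity is matches / alignment length over the extended
repeat.  Overlapping candidates are resolved by identity × length score
with a leftmost tie-break.  Two consequences worth stating explicitly:

* Because the two LTRs are *direct* repeats, the search is
  reverse-complement symmetric: a forward-strand pass provably finds every
  pair a reverse-strand pass would, with mapped coordinates, so only one
  strand is scanned.  A test asserts this invariance.
* Ungapped extension over- or under-runs termini by a few bp where the
  flanking sequence happens to match.  The TG…CA terminal motif is
  therefore annotated within ±3 bp of the called boundary.  Motif and
  target-site duplication are annotations, never filters.

The element-length filter keeps spans in [4000, 10000] bp, **inclusive** at
both ends — the permissive reading of a "4 kb to 10 kb" window; the bounds
are configuration, not constants.  Flank extension (default 4000 bp,
clipped at contig edges) supplies context for ORF scanning.

# Domain models

Domain detection scores position-specific log-odds matrices (bits against a
uniform residue background; consensus emission probability 0.7 per column)
by affine-gap local dynamic programming, reporting hits at ≥ 25 bits
(configurable; at these model lengths a ~70%-identity match scores > 100
bits while shuffled proteins stay far below threshold, so the default is
uncritical).  The bundled models are **synthetic stand-ins**, shipped as a
documented TSV (`domain_models_synthetic.tsv`), not distillations of any
curated alignment database; the generator embeds the same cores in its
template ORFs, which is exactly what makes detection verifiable offline.
Consequently, passing tests demonstrate that the scanning machinery works,
not that these particular matrices would recover domains in real genomes —
for real data one would re-derive the column scores from a curated seed
alignment and re-run the identical code path.

The integrase model designates its catalytic columns (D, D, E with the
canonical D2→E spacing of 35 aa).  `locate_dde()` projects those columns
through the hit alignment, picks the nearest actual D/D/E residues (window
±8 aa, ordering enforced, leftmost-D1 tie-break, total deviation
minimised), and flags the triad canonical iff the observed D2→E spacing
equals 35.  The BEL-PAO template deliberately carries a spacing of 42, so
the non-canonical branch is exercised by ground truth.  The spacing is
reported, never filtered on.

# Clustering and consensus

Greedy clustering processes sequences longest-first (ties by id) and joins
the first centroid at ≥ 50% identity — the "joins at exactly 50%" boundary
is intentional and tested.  Identity is global (Needleman–Wunsch) matches /
alignment columns including terminal gaps.  Gap penalties for DNA identity
are deliberately stiff (open 10, extend 2): with cheap gaps, *unrelated*
DNA aligns at ≈ 50% identity and the 50% threshold stops separating
families; with stiff gaps the unrelated baseline sits near 30–35% while
within-family identity at the divergences in scope stays ≥ 85%.

The consensus is center-star around the longest member: members are
globally aligned to the center and projected onto its columns (insertions
relative to the center are dropped — exact here because the generator is
substitution-only).  Per column the majority symbol wins, ties among bases
go to the lexicographically smallest base, majority-gap columns are
dropped.  One documented consequence: with exactly two members every
disagreeing column is a tie, so the consensus mixes the two haplotypes and
can synthesize stop codons that neither member carries.  Clusters of three
or more members do not have this problem, which is one reason the upstream
survey protocol refined only clusters of ≥ 3 sequences; the bundled
analysis scripts use three copies per family.

LTR refinement follows that protocol shape: for clusters of ≥ 3 members the
termini are re-called by a repeat-pair search on the consensus restricted to
spans covering most of it; smaller clusters adopt the terminus of the best
locally-aligning already-refined LTR (≥ 70% identity over ≥ half the LTR),
else they are flagged — flagged, never dropped.

Family assignment is best-hit identity of the cluster's RT-bearing protein
against the panel, with structural overrides resolved in favour of
structure and the support level recorded: an Env-bearing layout forces the
ERV superfamily; a fused gag-pol ORF restricts to Gmr/Mag.  Best hits below
20% identity yield "unclassified" (superfamily from structure when
determinable).  The bundled panel is synthetic (one Pol per family, built
deterministically from the family templates) and is labelled as such in its
filename and headers.  The neighbor-joining tree on (100 − identity)/100
distances replaces maximum-likelihood tree building deliberately: the tree
is classification support, not a phylogenetic result; negative NJ branch
lengths are clamped to zero.

# The molecular clock, in both directions

The dating convention is t = K / (2 r): K is the K2P-corrected divergence,
r = 1e-8 substitutions per site per year, t is reported in My.  The
generator inverts this convention *exactly*, which requires care:

* **Process.** `mutate_copy()` samples end states from the closed-form K2P
  category probabilities at the target distance (transition/transversion
  rate ratio κ, default 2 — a typical vertebrate nuclear value).  Multiple
  hits are therefore included, and `kimura2p()` is self-inverting in
  expectation: an acceptance test checks the inversion against an
  independent simulation (numerical matrix exponential of the rate matrix)
  at 10^4 sites.
* **Two channels, one clock.**  On the t = K/2r convention a copy's
  divergence from its consensus is 2rt, while each LTR accumulates rt per
  lineage so that the two LTRs of one copy diverge from *each other* by
  2rt.  A single uniform per-site rate cannot satisfy both at once
  (uniform 2rt everywhere would put the inter-LTR divergence at 4rt).  The
  generator therefore mutates the internal region at distance 2rt and each
  LTR at rt, making both estimator channels exactly invertible:
  `estimate_age("inter_ltr")` aligns the two LTRs;
  `estimate_age("vs_consensus")` aligns internal regions (LTRs excluded
  there, since their mutual divergence is the other channel).  Acceptance
  tests recover ages 0.5, 2 and 8 My within 3 standard errors over 100
  replicates in **both** modes.
* **Purifying selection.**  At 10% divergence a > 1000-aa ORF would almost
  surely gain a nonsense substitution, so full (active) copies are mutated
  ORF-preservingly: a substitution creating an in-frame premature stop is
  redrawn, a destroyed terminal stop is reverted.  This is the standard
  assumption that elements which remained intact were under selection;
  truncated/decayed copies are mutated freely.  The redraw touches ~4% of
  in-ORF substitutions and perturbs κ negligibly relative to the 3-SE
  acceptance bands.

Saturated alignments (1 − 2P − Q ≤ 0) yield `NA` ages with a warning and
are excluded from landscapes with a logged count.  Landscapes use 1-My bins
by default; a family is flagged "recently active" when its modal bin starts
below 5 My.  Both are configurable.

# What the generator emulates — and what it does not

Emulated: element geometries spanning the observed ranges (consensus
4.3–9.9 kb, LTRs 174–1116 bp), all four structural layouts including the
Gmr/Mag gag-pol fusion and Env-bearing Epsilon retroviruses, per-copy
divergence under a known clock with known κ, truncated copies (one LTR plus
30–60% of the internal region lost) and solo LTRs, target-site
duplications, i.i.d. background of configurable GC.

Not emulated: insertions/deletions (the divergence machinery is
substitution-exact by design; K2P on gapped alignments excludes gap
columns, but boundary jitter from indels is untested), nested insertions,
recombination dynamics that actually *produce* solo LTRs, low-complexity
and satellite background, lineage-specific rate variation, CpG effects.
Detection precision on i.i.d. background is therefore an upper bound on
real-genome precision, and the acceptance numbers say nothing about
parameterisation equivalence with any external miner on real assemblies.

Implants are placed uniformly, non-overlapping, with a minimum 10 kb gap.
The gap is a study condition, not a tuning knob: two same-family copies
closer than the element-span bound would offer a chimeric LTR pairing
(3'-LTR of one copy with 5'-LTR of the next) that is *structurally
indistinguishable* from a genuine element — the expected inter-copy LTR
divergence equals the intra-copy one.  Real full-length elements are far
sparser (hundreds of copies over gigabases) than any desk-scale benchmark,
so the spacing is also the realistic regime.

# Problem sizes

The test suite runs a ~600 kb benchmark (24 implants, five families), 100
age-recovery replicates per age in both channels, a 40-instance clustering
oracle suite, and the fixture-table checks; it completes in about three
minutes on one CPU.  The acceptance script builds a ~750 kb nine-family
genome (20 implants), runs the full pipeline on it and recomputes every
reported quantity from scratch in under two minutes.  The analysis scripts
use three copies per family (~900 kb) so the consensus and refinement paths
operate in their intended regime.  These sizes were chosen as the smallest
at which every stage operates in its intended regime — multi-seed
detection, ≥ 3-member consensus building, 3-SE recovery bands.

# Known limitations

* Substitution-only decay; no frameshift/pseudogene repair on decayed ORFs.
* Domain models and reference panel are synthetic; no claim of equivalence
  to profiles derived from curated alignment databases, no E-value
  calibration of bit scores.
* Boundary calls carry a few bp of jitter; dinucleotide-resolution
  polishing (and U3/R/U5 sub-partitioning of LTRs) is out of scope.
* The NJ tree carries no bootstrap support and is not intended to
  reproduce a published topology.
* Funnel counts on synthetic data mirror the *shape* of a genome survey's
  identification funnel; the published absolute counts depend on real
  assemblies and external-tool parameterisations that are out of scope
  here, and are checked instead at the aggregation level against bundled
  table transcriptions.
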
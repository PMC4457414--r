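---
title: "Introner-like elements, intron landscapes and parallel intron gains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Introner-like elements, intron landscapes and parallel intron gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilescape)
```

## The problem

Spliceosomal introns are usually gained so rarely that an intron position
shared between two species is read as ancestral. Introner-Like Elements
(ILEs) break that assumption: they are invasive spliceosomal introns that
multiply within a genome, leaving dozens to hundreds of near-identical
copies in unrelated genes. In dothideomycete fungi ILEs are recent or still
active, and because the youngest copies are nearly identical they can be
tracked directly: a family of near-identical introns is a set of recent
gains, not a set of conserved ancestral positions. When such a gained ILE
sits a handful of nucleotides away from a regular spliceosomal intron (RSI)
conserved in a distant clade, the classical reading would be "intron
sliding" of one ancestral intron; for an ILE that reading is untenable, and
the parsimonious interpretation is two independent, *parallel* intron
gains.

`ilescape` implements that whole chain of reasoning as testable code:

1. **ILE families** — cluster intron sequences by pairwise identity, build
   IUPAC consensus sequences, assign new sequences to families, and rate
   family activity.
2. **Primers** — derive family-specific or degenerate primer pairs from
   conserved stretches of a family alignment, and predict amplicons by
   in-silico PCR (the screen used to find ILEs in unsequenced genomes).
3. **Landscape** — project intron positions of an orthologue set onto the
   shared protein alignment, classify every position against the species
   phylogeny, detect sliding candidates and call parallel gains.
4. **Simulator** — forward-simulate gene families along a phylogeny with
   ILE/RSI gain, loss and substitution, with a ground-truth event log, so
   that every stage above can be benchmarked without external data.

## Coordinates and projection

All gene coordinates are 0-based, half-open genomic intervals; all intron
arithmetic happens in transcript orientation, so minus-strand genes are
handled once, at the gene-model boundary. An intron is located by its
`cds_offset`, the number of coding nucleotides 5' of it; the intron phase is
`cds_offset mod 3`.

Cross-species comparison needs a common frame: the protein alignment of the
orthologue set. An intron with offset $o$ lands in codon $\lfloor o/3
\rfloor$ of its own protein; its projected position is the pair (alignment
column of that codon, phase), summarised by the scalar *alignment-frame
offset* $\mathrm{afo} = 3c + p$. A phase-0 intron is assigned to the codon
*following* it, which makes `afo` strictly increasing along a gene and
makes the projection invertible (the package property-tests the round trip
under random gap placement). Distances between positions — including the
15-nt sliding window — are measured as differences of `afo`, i.e. in the
alignment frame: gaps count through columns, not through either species'
ungapped sequence, because that is the only frame in which positions of
different species are comparable.

## Families and classification

Two introns are linked when their pairwise identity exceeds the clustering
threshold (default 0.80); families are the connected components of that
relation (single linkage), which reads the threshold as a connectivity
criterion. Identity comes from a global, end-gap-free alignment with match
+1, mismatch 0, gap −1; the denominator is the alignment length including
internal gaps (a switch excludes gapped columns instead, and the choice is
recorded in output metadata). End-gap-free alignment avoids penalising
trimmed amplicon sequences. Because co-optimal alignments can place gaps
differently depending on argument order, the implementation aligns every
pair in a canonical orientation, making identity exactly symmetric.

The consensus of a family is built per column from the aligned members: the
majority base where one base reaches 50% without a tie, otherwise the
smallest IUPAC code covering all bases at frequency ≥ 25%; all-gap columns
are dropped. Assignment of a query to a family is IUPAC-aware (a base
matches any code containing it) and requires a configurable minimum
identity (default 0.70).

Intron classification is hierarchical: a family hit makes an intron an
**ILE**; otherwise length decides — introns of at least 70 bp are
**degenerate-ILE candidates** (ILE-scale length without recognisable family
identity, as seen for 81/87-bp introns next to 50–55-bp RSIs), introns of
40–60 bp are **RSIs**, anything else is unclassified. A family whose best
member pair reaches 98% identity is reported **active** (still
multiplying); families without such a pair are degenerate, and singletons
are undetermined.

One rule is deliberately stricter than naive clustering: a built family
only counts as an *ILE* family when its members span at least two distinct
loci (gene × position). Near-identical copies *in unrelated places* are the
defining ILE property; without the rule, homologous copies of a single
conserved RSI position across closely related species would masquerade as a
family and poison downstream classification.

## Primer design and in-silico PCR

Primer design scans the family member alignment for gap-free windows
(default 18 columns) with at most four variable columns, ranks them by
number of variable columns and then by the length of the invariant run at
the 3' end, and encodes each window as the per-column IUPAC code; the
degeneracy of a primer is the product of its code sizes. The forward primer
is the best window starting in the 5' half, the reverse primer the reverse
complement of the best non-overlapping window further 3' (stored 5'→3' as
synthesized). In-silico PCR finds every locus where the forward primer
matches the sense strand and the reverse primer the antisense strand
downstream within the amplicon cap (default 1,000 bp), with IUPAC-aware
mismatch counting and an exact-match requirement over the 3'-terminal 3 nt
of each primer — the standard 3'-anchoring of real PCR. Matching is
verified in the tests against a per-offset sliding-window oracle. No
melting-temperature or secondary-structure modelling is attempted.

## The landscape and its classification

The landscape of an orthologue set is the matrix of projected positions ×
species with states PRESENT / ABSENT / MISSING. MISSING — a species with no
orthologue, a partial gene model, or a gap in its alignment row at the
position's column — removes the species from that position's denominator:
absence of evidence is not intron loss. A species whose spliced CDS
contains an internal stop codon is flagged as a putative pseudogene.

Positions with at least one carrier are classified against the rooted
species tree in strict precedence:

1. **CONSERVED** — present in every scored species;
2. **SINGLE_PRESENCE** — present in exactly one;
3. **SINGLE_PRESENCE_IN_CLADE** — the carriers are exactly the scored
   members of one monophyletic clade (≥ 2 leaves);
4. **SINGLE_ABSENCE** — absent in exactly one;
5. **PRESENCE_ABSENCE_POLYMORPHISM** — everything else.

The precedence order is a design decision (the categories are usually drawn
without a tie-break); single absence is tested before generic polymorphism
because the two patterns carry different evolutionary readings. The
monophyly test is implemented via the MRCA of the carriers and is
property-tested against an oracle that enumerates every clade of random
trees.

**Sliding candidates** are unordered pairs of positions strictly closer
than 15 nt in the alignment frame (the window is configurable; the bound is
strict). **Parallel gains** are called for a sliding pair when one side
carries only ILE-class introns and the partner carries RSI-class introns in
species outside the clade spanned by the ILE carriers — a young intron next
to an old one in a distant lineage. If the partner's outside introns are
only degenerate-ILE candidates the call is downgraded to
`POSSIBLE_PARALLEL`; an ILE occupying *the same* position as an RSI
elsewhere is flagged `ambiguous_coincident` and never called automatically.
The parallel-gain frequency is reported as 100 × (parallel ILE-side
positions) / (polymorphic positions), with numerator and denominator
printed so alternative denominators remain auditable.

### Boundary refinement

Manual curation of misaligned exon–intron–exon boundaries — needed when two
introns sit a few nucleotides apart in different species — is replaced by a
deterministic, logged snap rule. A projected position may snap onto an
existing position carried by ≥ 2 other species at most one codon away
(configurable), but only when the junction-anchored identity of the exonic
flanks (default 12 nt per side) strictly exceeds the identity implied by
the current projection; exact ties leave the position unchanged and are
flagged ambiguous. Every decision is logged in the landscape's
`refinements` table, and `refine = FALSE` disables the step.

## The simulator

The simulator is the package's source of ground truth. Each gene starts as
a stop-free random CDS (default 1,500 nt, uniform codon usage over the 61
sense codons) with a configurable number of ancestral introns (default 2).
Along every branch of the species tree (branch lengths = expected
substitutions/site), Poisson numbers of events are drawn per gene:

* **ILE gain** (default 0.5 /gene/unit): a copy of a seed family consensus,
  mutated per site at the copy-mutation rate (default 0.01), inserted at a
  uniform unoccupied coding position — no proto-splice-site bias (a
  deliberate simplification; bias is biologically debated and off by
  default);
* **RSI gain** (default 0.3): a random 45–60-bp GT..AG intron;
* **loss** (default 0.15): precise excision of a random intron (the only
  loss mode, matching the clean absence patterns losses leave);
* substitutions (default 0.05 /site/unit) in exons (rejecting changes that
  create stop codons) and intron interiors (GT/AG boundaries protected).

Because insertions never alter the CDS, all leaf CDSs of a gene have equal
length and the emitted protein alignments are gap-free — which also means
the simulator does *not* exercise alignment error: gapped, misaligned rows
occur in real data and are covered instead by the projection property tests
and the refinement unit tests. Other features of real data the simulator
does not emulate: indels in exons, rate heterogeneity across sites and
branches, non-canonical splice sites, within-species polymorphism (one
haploid representative per species), and paralogy. Passing the recovery
benchmark therefore demonstrates the correctness of the pipeline's logic
under its stated assumptions, not robustness to orthology or alignment
errors.

The true event log is the contract: replaying it from the root reproduces
every leaf's gene structure exactly (a tested invariant). The
`make_parallel_gain_fixture()` companion is a hand-constructed 10-species
orthologue set encoding the canonical configuration — three ILE copies 1, 8
and 3 nt (alignment frame) from RSI positions conserved in a distant clade,
plus distractor positions covering every category, one species emitted on
the minus strand — with per-position ground truth, and a negative control
without the ILEs.

## Recovery benchmarking

Position-level gain/loss calls are derived from each gene's landscape by
Dollo-style parsimony: the gain point of a position is the MRCA of its
carriers; a gain is called when that clade does not span all scored species,
a loss when a scored species inside the clade lacks the intron. Calls are
scored against the *leaf-observable* events of the true log — a gain whose
intron survives in at least one leaf, a loss at a position still occupied in
at least one other leaf. Events invisible at the leaves (a gain erased by a
later loss in every carrier) are unrecoverable in principle and excluded
from the truth set; this is stated here because it defines what the
reported precision and recall mean. The benchmark pools 20 replicate
histories of 10 species × 20 genes at the default rates (roughly 50 true
events each, ~1,000 pooled); the pipeline recovers them at ≥ 0.97 precision
and recall, with the residual errors coming from deep losses that make an
ancestral position look clade-restricted.

## Numerical choices and degenerate inputs

* Thresholds (see `ile_params()`): clustering 0.80 and activity 0.98 are
  anchored to the observed identity scales of ILE families; assignment
  0.70, RSI range 40–60 bp, long-intron 70 bp, sliding window 15 nt,
  refinement shift 1 codon and 12-nt flanks are package defaults, all
  configurable and echoed into report headers.
* Intron structural floor: inter-exon gaps must be ≥ 4 nt (donor +
  acceptor); models violating exon disjointness are structural errors
  naming the gene. CDS lengths not divisible by 3 mark a model *partial*
  rather than failing, and partial models contribute MISSING cells only.
* Tie-breaks are deterministic everywhere: family ordering by size then
  lexicographic member id, assignment ties by family order, refinement ties
  flagged ambiguous and left unsnapped, primer-window ties by position.
* Empty inputs fail loudly (`build_families()`, `run_pipeline()`);
  positions with no carrier are dropped with a warning; a zero parallel-gain
  denominator yields an undefined (NA) frequency, not zero.
* Identity of an empty overlap alignment is defined as 0.
* All randomness flows through explicit seeds (`withr::with_seed`); the
  same seed gives byte-identical simulations and reports.

## Problem sizes

The shipped analyses and tests use 10-species trees, 20 genes of 1,500 nt,
20 replicate seeds for the recovery benchmark, 1,000-case property loops
for projection and classification oracles, and 100 random 5-kb templates
for the PCR oracle — sizes chosen so the full suite exercises every claim
in minutes on a laptop while keeping Monte-Carlo noise far from the tested
margins.

## Known limitations

* No probabilistic ancestral-state reconstruction (Dollo/ML rate models);
  the parsimony calls mirror the narrative style of the underlying
  analysis and are an obvious extension point.
* No de-novo genome-wide ILE discovery and no orthologue detection;
  orthologue sets, alignments and trees are inputs.
* Degenerate primer design optimises conservation only — no melting
  temperature, dimer or hairpin screening.
* The parallel-gain frequency inherits the ambiguity of its denominator
  (which positions count as polymorphic); the package always reports the
  counts alongside the percentage.
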
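---
title: "Methods: comparative CRISPR/cas analysis with crispratlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative CRISPR/cas analysis with crispratlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

crispratlas re-implements, as a tested pipeline, a comparative analysis of
CRISPR/cas systems across closely related enterobacterial genomes: de novo
array detection anchored to core genes, cas operon subtype annotation and
decay assessment, a cross-genome spacer atlas, proto-spacer matching in
mobile elements, anti-CRISPR (cas-targeting) detection, and divergence-time
estimation.  A synthetic-genome generator plants the full architecture with
a ground-truth ledger, so every stage is testable without external data.

This vignette documents the models, the algorithmic choices made where the
design was genuinely open, the generator's assumptions, and the limits of
what the synthetic tests demonstrate.

# Array detection

## The detector's definition of an array

An array is a maximal run of at least `min_repeats` (default 3) repeat
copies of one common length `L` in `[19, 38]` bp, separated by spacers of
`[19, 48]` bp.  Detection is seed-and-chain:

1. **Seeding.** Exact `seed_word`-mers (default 8 bp) whose consecutive
   occurrences recur at an array-like period (repeat+spacer, 38-86 bp) form
   candidate runs.  Runs describing the same region are clustered and the
   run with most members represents the region.
2. **Boundary refinement.** Columns relative to the seed positions belong
   to the repeat while at most one consecutive pair of copies disagrees in
   them (no disagreement allowed for 3-copy runs).  Tolerating a single
   disagreeing pair keeps the 3'-degenerate terminal repeat (a near-
   universal feature of these arrays) from truncating the repeat unit,
   while two or more disagreeing pairs at a column mark the spacer
   boundary.
3. **Validation.** Runs are split where an inter-copy gap leaves the
   spacer range (an IS insertion or a missing spacer); each part must keep
   `min_repeats` copies.
4. **End extension.** Each end is extended with windows at spacer distance
   whose identity to the running column-modal consensus reaches
   `min_chain_identity` (default 0.75).  This recovers degenerate terminal
   repeats that lost the seed word, and makes runs maximal: a reported
   array cannot be extended by another qualifying copy.
5. **Selection.** Candidate arrays are made non-overlapping greedily, more
   repeats first, then leftmost.

The companion test suite re-implements this definition as a naive
brute-force enumeration and asserts exact agreement on contigs up to 10 kb.

The defaults mirror the published defaults of the CRISPR Recognition Tool
(8 bp seed, at least 3 repeats, repeat 19-38 bp, spacer 19-48 bp); the
`min_chain_identity` floor of 0.75 is this package's choice: repeat copies
within one enterobacterial array are near-identical, and at 0.75 the
probability that random 29-mers chain by chance is negligible
(binomial tail of 22+ matches in 29 at p = 1/4, roughly 1e-8 per window
pair), while copies mutated to 90% identity still chain.

## Fuzzy rescue

Single or strongly degenerate repeats escape the seed-and-chain detector;
`fuzzy_find()` scans a region with a known consensus at 60% identity and
*identical length* (no indels), on both strands, and
`assemble_rescued()` groups the units into arrays, joining across an
IS-sized insert (flagged `is_disrupted`) and flagging lone units
`single_repeat`.  The printed ambiguity position of the CRISPR1/2 repeat
family (IUPAC W) matches A or T during rescue.

## Identity conventions

Identity is Hamming matches over equal-length windows; any non-ACGT
character counts as a mismatch (conservative matching).  No indels are
considered anywhere in repeat or proto-spacer matching.

## Terminal degeneracy and orientation

A terminal repeat is degenerate when it differs from the consensus in at
least two positions of its distal third while internal repeats stay
near-exact.  All 5'/3' logic is evaluated after orientation: the leader
end is 5'.  Orientation defaults to the contig forward strand until
`find_leader()` assigns a side.

## Palindromicity

The published analysis folds repeats into RNA secondary structures and
reports free energies; this package deliberately does not reproduce
folding.  Instead `palindromicity()` reports the maximum number of nested
Watson-Crick pairs (minimum hairpin loop 3) over `floor(n/2)`.  GU wobble
pairs are excluded *by design*: including them would make the score depend
on which strand is examined, whereas the Watson-Crick score is invariant
under reverse complementation -- the natural requirement for a DNA repeat
statistic.  The score is a structural-propensity index, not an energy.

# Locus anchoring and the core genome

Orthologs are unique pairwise reciprocal best hits with at least 60%
amino-acid similarity and under 20% protein length difference.  Similarity
is the fraction of global-alignment columns with a positive BLOSUM62
score ("positives"), the conventional reading of "similarity" as opposed
to identity.  Candidate best hits are ranked by alignment score; the
positives threshold is evaluated on reciprocal candidates.

The published refinement step ("distribution of similarity ... and gene
order conservation") is qualitative; this package's reconstruction keeps a
pair when, on each side, at least one of its two nearest *mapped*
neighbours pairs with a neighbour of the partner gene, or when its
similarity exceeds the 95th percentile of pair similarities.
Neighbourhoods are taken over genes that have an RBH mapping so that genes
flanking a lineage-specific insertion or deletion (for example a decayed
cas operon) are not spuriously dropped.

The core genome intersects the pairwise lists through a reference genome
and then verifies all-pairs transitive consistency; families failing it
are dropped.  Arrays are anchored by the unordered pair of nearest
flanking core genes within 30 kb (tRNA genes, which carry no protein,
anchor by conserved name): cysD-cysJ is CRISPR1, cysJ-ygcF CRISPR2,
clpS-tRNA-Ser CRISPR3 and tRNA-Ser-infA CRISPR4.  Unordered matching makes
the label invariant under contig reverse complementation.

## Leaders

The leader is identified by conservation asymmetry: the flank
(default 120 bp) whose cross-genome mean identity exceeds the opposite
flank's by 0.15 and reaches the 0.70 conservation floor (the figure
reported for cross-genus leader conservation).  The flank window equals
the generator's default leader length; a longer window dilutes the
conserved fraction and biases the AT-fraction estimate downwards, so 120
bp is the default and both are configurable.  A locus observed in a
single genome cannot reach significance.

# cas annotation

Intact genes are called from annotated CDS by best-hit similarity
(positives fraction, floor 0.35) against bundled reference protein sets:
the Ecoli subtype (cas2, cas1, cse3, cas5, cse4, cse2, cse1, cas3) and
the Ypest subtype (cas1, cas3, csy1, csy2, csy3, csy4).  The bundled
references are deterministic *synthetic* proteins with realistic lengths
-- they exercise the machinery end-to-end and are the same sequences the
generator plants, so annotation is tested against a known truth; users
supply their own curated references for real data via `load_cas_refs()`.
The original profile-HMM search (e-value and positive-score thresholds)
has no direct analogue here; best-hit similarity against references is a
documented methodological substitution.

Pseudogenes are recovered from raw sequence: each reference coding
sequence is probed across the genome (24-mer probes, both strands), and
candidate loci are locally aligned.  A locus is pseudo when it shows a
frameshift (indel not a multiple of 3), an internal stop in the reference
frame, or covers less than 80% of the reference (the truncation cutoff is
this package's quantification of "truncations").  Matches shorter than
120 bp are discarded -- cas-derived CRISPR spacers would otherwise appear
as spurious relics.  The same scan doubles as the "absence elsewhere"
check, since it is genome-wide.

An operon is `complete` iff every canonical gene is intact and
co-oriented; `partial` covers everything from a single pseudogene to a
cas3 relic; `absent` means no call.  An operon links to a locus when its
span lies within 5 kb of an array boundary.

# Spacer atlas and proto-spacers

Spacers cluster by exact sequence after strand normalisation (the
lexicographically smaller of sequence and reverse complement).  Singleton
status is assessed after collapsing strains closer than 0.02%
substitutions/site to one representative per group.  The polarity
statistic is the mean index-from-leader of singletons minus that of
shared spacers; its null band comes from permuting spacer positions
within each array.

Proto-spacers are substitution-only matches at identity strictly above
95%: a 32 bp spacer tolerates at most one mismatch, and two mismatches
(31.25/32 = 0.9375) never match.  Hits inside the querying arrays
themselves are excluded.  Chromosome hits subclassify as prophage or cas
when inside labelled spans; inter-repeat segments longer than the spacer
maximum (IS inserts, the conserved CRISPR2 insert) are logged and excluded
from the atlas.

Anti-CRISPR: an array is flagged when at least one spacer matches a cas
reference coding sequence of subtype S above 95% identity while the
genome's subtype-S operon is absent; a strict mode (`allow_relic`) also
accepts partial relics.  Spacers matching cas genes of a subtype the
genome still carries are reported as self-targeting conflicts, unflagged.

# Divergence statistics

Distances are p-distances.  At the 0.02% grouping threshold the
multiple-hit correction is below 0.02% relative, so the uncorrected
distance is model-robust; a Jukes-Cantor toggle exists.  Whole-genome
comparison is appropriate for the colinear synthetic strains (unrelated
genomes saturate near 0.75, far above any grouping threshold);
`distance_matrix(method = "core")` compares concatenated core genes
instead.  Groups are single-linkage components of edges strictly below
the threshold.

Two dating estimators:

* **Molecular clock.** `years = d / mu` with mu = 7.6e-10
  substitutions/site/year; d = 0.0002 gives 263,158 years, consistent
  with the coarse published figure of 250,000.
* **Conservative neutral accumulation.** Per-site polymorphism input per
  generation `r = (U/G) * (1 + rho)`, with genomic mutation rate
  U = 1e-3/generation, genome size G = 5 Mb, and recombination
  contributing rho = 2.5 times the mutational input; d = 0.0002 gives
  285,714 generations (300,000 at one significant figure) and, at 40 h
  per generation and 8,766 h per Julian year, 1,304 years ("over
  1,300").  Both estimators are exactly linear in d and return 0 at
  d = 0.

The repeat-count association between CRISPR1 and CRISPR2 is the squared
Pearson correlation with a one-sided permutation p-value (add-one
smoothed, default 10,000 permutations), replacing an unstated parametric
test.

# The synthetic world

`generate_world()` plants, per genome: a conserved core-gene backbone
(cysD, cysJ, ygcF, clpS, tRNA-Ser, infA, aat analogs plus eight fillers,
~2% coding divergence between genomes, stop-codon-safe); CRISPR arrays
between the canonical anchors built from the two printed repeat consensi;
an AT-rich (0.7) 120 bp leader conserved per locus (~2% divergence); cas
operons in intact, partial (frameshift/truncation pseudogenes), relic or
absent states; an IS-disrupted CRISPR2; a prophage copy and owned
plasmids for self-targeting scenarios; and, in cas-less genomes, a
CRISPR3 whose spacers are windows of Ypest cas coding sequences (the
anti-CRISPR scenario, with one anchor spacer shared by all carriers).
Spacers average 32 bp (clipped to 28-36); a quarter of private spacers
carry recorded provenance from a 40-element phage/plasmid/chromosome
pool, 40% of them with exactly one planted mismatch.  Ancestral spacer
stacks sit trailer-side and are shared across genomes; private spacers
are added at the leader end (`polarity = "uniform"` shuffles the order as
a null model).  A close strain pair diverges at 1e-4 substitutions/site
with arrays excluded from mutation, matching the observation that very
close strains carry identical arrays.

Where the source analysis quantifies nothing (leader length and AT
fraction, degeneracy extent, spacer-sharing depth), the defaults above
are one-time choices of plausible values, stated here and configurable;
they were not tuned against test outcomes.

**Boundary identifiability.** Planted arrays are constructed so that
consecutive spacers differ in their first and last characters (and
likewise at the leader and trailing junctions).  This guarantees that the
column just outside each repeat is never conserved across copies, so the
detector's boundary rule has a unique answer and recovery can be asserted
*exactly*.  Provenance spacers satisfy the constraint by window selection
rather than editing, leaving their mismatch budget intact.  Real genomes
offer no such guarantee: on real data, single-base boundary ambiguity is
possible whenever flanking bases happen to agree across copies, and the
recovery tests here do not speak to that case.  Terminal 3' degeneracy
(last 5 bp of the final repeat) is applied to arrays of at least 4
repeats, since a 3-copy run cannot distinguish a degenerate terminal from
a spacer column.

Randomness: one global seed drives derived per-genome streams; identical
seeds give byte-identical worlds.

## What the synthetic tests do not show

The background is i.i.d. uniform sequence: no skews, no microsatellites,
no rearrangements, no real mobilome diversity.  Gene content is fixed up
to the configured states; there is no horizontal transfer beyond the
anti-CRISPR scenario, no codon-aware evolution, and no indel evolution.
Detector recovery and matching results on these worlds demonstrate
algorithmic correctness under the stated model, not performance on real
assemblies.

# Problem sizes and determinism

The bundled demo world is 6 genomes of 1 Mb with a 40-element pool --
large enough for every architectural feature yet small enough that the
complete pipeline runs in minutes on one CPU.  Unit tests use 130-150 kb
genomes with the same architecture.  The permutation tests default to
499-10,000 permutations depending on context.  All outputs are
deterministic given the configuration seed; report tables are written so
identical inputs give byte-identical files.

# Known limitations

* Proto-spacer matching is substitution-only; a bona fide gapped match
  is invisible.
* Repeat rescue requires identical length, as in the original fuzzy
  search; length-polymorphic repeats are not recovered.
* cas calling depends on the supplied references; the bundled synthetic
  set supports testing, not real-data annotation.
* The leader finder assumes alignable, colinear flanks (no indel
  handling) and a fixed window.
* p-distance grouping presumes near-clonal strains; the package performs
  no phylogenetic reconstruction by design.
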
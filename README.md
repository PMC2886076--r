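# crispratlas

Comparative analysis of CRISPR/cas systems across closely related
bacterial genomes, for microbial genomicists studying the evolution of
adaptive immunity in enterobacteria (*Escherichia*/*Salmonella*-like
settings).

The package covers the full comparative workflow as one tested pipeline:

* **Array detection** — seed-and-chain discovery of repeat/spacer arrays
  (8 bp seed, ≥3 repeats of 19–38 bp, spacers of 19–48 bp), with a
  consensus-guided fuzzy rescue for single or degenerate repeats (60%
  identity at identical length) and flagging of the 3′-degenerate
  terminal repeat and IS-disrupted arrays.
* **Locus anchoring** — reciprocal-best-hit orthologs (≥60% amino-acid
  similarity, <20% length difference, synteny-refined), a core genome by
  intersection of pairwise lists, and array labels from flanking core
  genes: *cysD–cysJ* (CRISPR1), *cysJ–ygcF* (CRISPR2), *clpS–tRNA-Ser*
  (CRISPR3), *tRNA-Ser–infA* (CRISPR4). Leaders are the conserved,
  AT-rich flank, identified by contrast with the opposite flank.
* **cas annotation** — Ecoli-subtype (cas2, cas1, cse3, cas5, cse4,
  cse2, cse1, cas3) and Ypest-subtype (cas1, cas3, csy1–csy4) operons,
  with pseudogene recovery from raw sequence (frameshift, internal stop,
  or <80% reference coverage) and complete/partial/absent verdicts.
* **Spacer atlas** — cross-genome spacer clusters (exact match after
  strand normalisation), singleton statistics after collapsing strains
  closer than 0.02% substitutions/site, leader-polarity of new spacers,
  and duplication calls.
* **Proto-spacers** — substitution-only matching at identity >95%
  (a 32 bp spacer tolerates one mismatch) against phage, plasmid and
  chromosomal targets; genic/strand context; self-targeting; and
  **anti-CRISPR** detection: arrays whose spacers match cas genes of a
  subtype the genome lacks.
* **Divergence dating** — p-distances, single-linkage strain grouping at
  0.02%, and two estimators: the molecular clock *t = d/μ* with
  μ = 7.6×10⁻¹⁰ substitutions/site/year, and a conservative neutral
  dating from *r = (U/G)(1+ρ)* with U = 10⁻³ mutations/generation,
  G = 5 Mb and ρ = 2.5.

A first-class synthetic-genome generator (`generate_world()`) plants the
entire architecture — core-gene backbone, arrays from the two canonical
repeat consensi, leaders, cas operons in all decay states, IS insertions,
spacer provenance from a mobilome pool, close strain pairs, anti-CRISPR
genomes — together with a ground-truth ledger, so every stage is testable
without external data.

## Worked example

```r
library(crispratlas)

w <- generate_world(world_config(
  n_genomes = 3, genome_length = 130000, seed = 47,
  pool = list(n_phage = 6, n_plasmid = 4, n_chromosome = 2)))
w
#> <crispr_world> 3 genomes, 12 pool elements, 9 planted arrays

arr <- detect_genome_arrays(w$genomes[[1]])
for (a in arr) print(a)
#> <crispr_array> g01.arr1 unanchored - 9 repeats x 29 bp, 9323 - 9836
#> <crispr_array> g01.arr2 unanchored - 11 repeats x 29 bp, 21190 - 21827
#> <crispr_array> g01.arr3 unanchored - 6 repeats x 28 bp, 28085 - 28413

arr[[1]]$consensus$seq          # the 29 bp CRISPR1/2 repeat family
#> [1] "CGGTTTATCCCCGCTGGCGCGGGGAACAC"
anchor_locus(arr[[1]], w$genomes[[1]])
#> [1] "CRISPR1"

clock_years(2e-4)               # 0.02% divergence on the molecular clock
#> [1] 263157.9
neutral_generations(2e-4)$generations   # conservative neutral dating
#> [1] 285714.3
```

The first genome carries three arrays: two with the 29 bp repeat of the
CRISPR1/CRISPR2 family (the detected consensus resolves the ambiguous
A/T position of the printed consensus) and one with the 28 bp repeat of
the CRISPR3/CRISPR4 family. The dating estimates say that strains
differing by 0.02% of sites diverged roughly 263,000 years ago on the
clock, or — under maximally conservative neutral accumulation — at least
~286,000 generations (about 1,300 years) ago.

`run_all(pipeline_config(world = world_config(...), out_dir = "out"))`
executes every stage end-to-end and writes the report bundle
(arrays, spacer atlas and clusters, proto-spacer hits, cas calls,
leaders, anti-CRISPR flags, strain groups, divergence estimates) as
deterministic TSV tables. A thin command-line wrapper is installed as
`exec/crispratlas` with `synth` and `run` subcommands.

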
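---
title: "Methods: defense systems, spaceromes and virus-host networks from assembled metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defense systems, spaceromes and virus-host networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagenet)
options(phagenet.quiet = TRUE)
```

phagenet is the interpretation layer that sits downstream of assembly,
ORF prediction, HMM scanning, read mapping, CRISPR array detection and
viral-contig calling in a multi-community metagenome study — for example a
set of sponge holobionts and the surrounding seawater. All of those upstream
steps are consumed as files (FASTA, GFF3, TSV/CSV tables); everything from
there to the biological summaries — defense-system calls, normalized
abundances, non-redundant spacer and virus catalogues, protospacer matches
with PAM flanks, and the community-community virus-host network — is
computed by this package. This vignette explains each model, its parameters,
and the design choices behind the numerically sensitive parts.

## Defense-system calling

ORFs are indexed 0-based per contig in coordinate order (ties broken by end
coordinate), because the calling rule is stated in ORF counts, not base
pairs. After discarding hits with E-value at or above `evalue_max` (default
`1e-10`), each ORF keeps only its lowest-E-value profile; exact ties resolve
to the lexicographically first profile id so results cannot depend on input
row order. A putative defense system is then a chain of assigned ORFs of one
system type on one contig in which consecutive members are separated by
strictly fewer than `max_gap = 5` intervening ORFs, with at least two
members and at least two distinct profiles.

Two readings deserve a note:

* **Gap rule.** "Separated by less than 5 ORFs" is interpreted as
  `orf_index difference - 1 < max_gap`; the boundary case (exactly five
  intervening ORFs) does *not* chain. The bound is configurable.
* **Chaining.** The rule as stated describes pairs; we close it
  transitively (single-linkage along the contig), the minimal closure under
  which "a system" is one locus. A brute-force subset-enumeration oracle in
  the test suite confirms that, under single-linkage, maximal valid chains
  are exactly what the implementation emits.
* **E-value cutoff.** The threshold is printed ambiguously in the
  literature this convention comes from ("10 × 10⁻¹⁰" reads as 1e-9); we
  default to 1e-10 and expose `evalue_max`.

Chains that fail either condition are discarded as systems but their
members still count as *defense genes*; both gene-count conventions
(all retained assignments vs members of called systems only) are available,
with all-assignments the default. Strand is ignored throughout: defense
operons are compact and the calling rule is purely positional.

Defense *islands* merge calls on one contig whose ORF spans lie within
`island_gap = 10` ORFs of each other (transitively, allowing overlap). An
island needs at least two calls and, by default, at least two distinct
system types — tandem copies of one system are a different phenomenon from
the co-clustering of unlike systems that "defense island" denotes. Set
`require_multi_system = FALSE` to count tandem arrays too.

## Normalized abundance

Raw counts of genes and systems are simple counts. The normalized weight of
an item on contig $c$ in sample $s$ is

$$ w_c \;=\; \frac{\mathrm{covdepth}_c \times 10^{12}}{L_s \, N_s} $$

where $\mathrm{covdepth}_c$ is the contig's mean per-base coverage depth,
$L_s$ the total assembly length (by default restricted to contigs of at
least 5 kb, the same size filter the assembly analysis uses; configurable
to the whole assembly), $N_s$ the total mapped reads, and $10^{12}$ a fixed
scaling constant shared by all samples so that normalized values land in
the numeric range of raw counts. Mean depth is computed from
`samtools depth`-style sparse tables: absent positions count as zero and
the denominator is always the full contig length, which keeps the statistic
well-defined whether or not zero rows were emitted. The formula is linear
in depth and inversely linear in $L$ and $N$; the test suite asserts these
scaling laws exactly, and the unit-weight limit
($\mathrm{covdepth} = L N / 10^{12}$) recovers raw counting.

## Clustering and dereplication

Spacers (identity > 0.95, coverage > 0.95) and viral contigs
(identity > 0.95, coverage > 0.8) are collapsed with the same greedy
incremental clusterer: sequences are visited longest-first (ties by id) and
each joins the first representative it matches on either strand, else
founds a cluster. Identity follows the global-identity convention —
matching columns of the best local alignment divided by the length of the
*shorter* sequence — so for a 32-nt spacer "identity > 0.95" means at most
one mismatch; coverage is the aligned fraction of the shorter sequence.
Pairwise alignment is delegated to `Biostrings::pairwiseAlignment`
(match +2, mismatch −3, gap open 5, extend 2); for sequences of 100 bp or
more a shared-16-mer prefilter skips pairs that cannot reach 0.95 identity
(at that identity the longest exact run is at least 19 bp by pigeonhole).
The greedy protocol is deterministic, and order-invariance of the
representative set is tested.

## Protospacer search

The matcher is a short-query seed-and-extend search in the blastn style,
with word size 8, no low-complexity masking, and query-coverage and
E-value filters. Both spacer strands are scanned against the forward
contig; every shared 8-mer defines a diagonal, and on each diagonal the
maximum-scoring ungapped segment under +2/−3 is found exactly (Kadane's
algorithm), which is what an ungapped X-drop extension converges to.
Matches must cover at least 95% of the spacer and reach a Karlin–Altschul
E-value ≤ 10 with $\lambda$ solved numerically for the score matrix at
uniform base composition and $K = 0.41$ (the standard tabulated value for
+2/−3; at spacer-scale scores the E-value filter is insensitive to $K$ to
within orders of magnitude). Coordinates are reported 1-based inclusive on
the forward strand. Gapped alignment is deliberately omitted: 32-nt
protospacers essentially never gap, and the cost of the omission is
quantified in tests by comparison against a full Smith–Waterman oracle.
That comparison also documents the matcher's one designed blind spot: a
site whose every 8-mer is disrupted is invisible to word seeding even
though full alignment still finds it.

PAM extraction reports *both* dinucleotides immediately flanking a match,
in protospacer orientation (reverse-complemented for minus-strand matches),
padding with `N` at contig ends. No side is privileged as "the" PAM — for
type I-F systems the classical CC motif is 5′ of the protospacer, but the
classification is left to the user.

## The interaction network

Each protospacer match connects the community that contributed the spacer
to the community whose viral contig carries the protospacer. Edges carry
three statistics: total matches (distinct spacer–contig–site triples),
distinct matching spacers, and distinct matched contigs. Spacers and
contigs are counted at the *cluster* level by default so that identical
spacers recovered repeatedly, or near-identical contig copies, are not
double-counted; raw-id counting is available. Spacers recovered from
viral-fraction metagenomes (cells small enough to pass the 0.22 µm filter)
are attributed to their sample's spacerome node rather than given nodes of
their own, keeping one node pair per community. Per spacer source, the
edge with the most matching spacers is flagged, and an intra- versus
inter-community summary reports whether within-community interactions
dominate. The per-contig dossier aggregates, for one viral contig cluster:
distinct matching spacers per community, their arrays and Cas types,
match positions within arrays (two or more runs separated by unmatched
spacers are flagged, since array position is a rough timeline of
acquisition), a PAM census deduplicated per spacer, and depth fold-changes
across the samples carrying the cluster.

## The synthetic-data generator

Every downstream stage is tested against communities with planted ground
truth, generated deterministically from a seed. Design choices, and what
they do and do not emulate:

* **Background sequence** is i.i.d. uniform over ACGT. No compositional or
  low-complexity structure is modelled: the matcher runs without dust
  masking, so low-complexity artifacts are irrelevant to the properties
  under test, and none of the calling rules are sequence-composition
  dependent. Consequently, passing tests say nothing about repeat-rich or
  skewed-GC real data.
* **ORFs** are tiled non-overlapping at a configurable density (default
  ~1/kb) with uniform random strand; real gene structure (overlaps, codon
  bias) is not emulated because the defense-calling rule only consumes
  ordinals.
* **Planted systems** receive hits with E-values log-uniform in
  [1e-50, 1e-15]; noise hits are Bernoulli per ORF at `noise_hit_rate` per
  100 ORFs with E-values log-uniform in [1e-12, 1e-2], so roughly a fifth
  of them survive the 1e-10 cutoff and genuinely stress the chaining rule.
* **Protospacer planting** writes PAM + (mutated) spacer + PAM into a viral
  contig at a collision-free position. With `preserve_seed = TRUE` the
  mutation draw is rejected until an exact 8-mer survives *and* no proper
  prefix or suffix of the site scores ≤ 0 under +2/−3. The second condition
  matters: a substitution at or near a spacer end makes every
  maximum-scoring local aligner (oracle included) trim the site, so the
  recoverable protospacer would be shorter than the planted one and could
  fall below 95% query coverage for reasons unrelated to matcher
  sensitivity. Planted truth should be detectable by the method under
  test; negative controls disable the flag.
* **Pseudo viral callers** vote per contig under a Bernoulli agreement
  model (sensitivity on true viral contigs, false-positive rate on planted
  decoys), giving the 2-of-3 vote nontrivial cases. Scenarios that isolate
  the matcher or the network use perfect callers so that recovery failures
  can only come from the stage under test.
* **Depth** is either constant per contig (exact fold-changes, used
  wherever ratios are asserted) or per-position Poisson with zero rows
  omitted (exercising the zero-fill convention).

Problem sizes in the shipped tests and acceptance script — four
communities, a few contigs of 4–9 kb each, 100 kb contigs for the matcher
benchmark, twenty seeds for the noisy-recall estimate — were chosen as the
smallest sizes at which every rule (gap boundaries, both clustering
threshold pairs, strand symmetry, cluster-level counting) is exercised with
planted positives and negatives.

## Degenerate inputs and tie-breaks

Empty hit tables, empty spacer sets and empty edge lists all produce valid
empty outputs with declared row/column universes. Zero depth denominators
in fold-changes are reported as infinite with a flag rather than an error.
All tie-breaks (equal E-values, equal-length cluster representatives,
equal best edges) are lexicographic and therefore order-invariant; the
suite permutes inputs to verify this.

## Known limitations

* The matcher is ungapped and word-seeded; heavily mutated or indel-bearing
  protospacers are missed by design (quantified against the
  Smith–Waterman oracle).
* The greedy clusterer is representative-based like cd-hit, not optimal
  clustering; membership can depend on the longest-first visiting order in
  borderline cases, exactly as in the tool it mirrors.
* $L$ and $N$ are consumed as per-sample scalars; the package does not
  parse BAMs and cannot recompute them.
* Verdict voting treats a missing tool verdict as a negative vote, the
  conservative reading of "recognized by at least two pipelines".
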
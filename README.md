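# phagenet

Defense systems, CRISPR spaceromes and virus–host networks from assembled
metagenomes.

## What it does, and for whom

In a multi-community metagenome study — several host-associated microbial
communities plus the surrounding water, each sequenced in a cellular
("bacterial") and a virion-enriched ("viral") size fraction — the upstream
toolchain (assembler, ORF predictor, hmmsearch, read mapper, CRISPR array
detector, viral-contig callers) produces tables, not biology. phagenet is
the interpretation layer that turns those tables into the study's results:

* **Antiphage defense annotation** — per-ORF HMM profile hits are filtered
  (E-value < 1e-10), resolved to the best profile per ORF, and chained into
  putative defense systems: ≥ 2 ORFs of one system, consecutive members
  separated by fewer than 5 intervening ORFs, ≥ 2 distinct profiles.
  Co-clustered systems are merged into defense islands.
* **Normalized abundance** — each gene or system is weighted by its
  contig's coverage depth: `covdepth × 10¹² / (L × N)`, with `L` the
  (size-filtered) assembly length and `N` the mapped reads of its sample,
  giving cross-sample comparable heat-map tables.
* **Virus catalogue** — contigs called viral by ≥ 2 of 3 external tools
  are dereplicated (greedy clustering, identity > 0.95 over > 0.8 of the
  shorter sequence) into a non-redundant set, with cross-sample and
  cross-fraction sharing matrices.
* **Spacerome** — CRISPR spacers are clustered (identity and coverage
  > 0.95), shared across samples, and searched against viral contigs with
  a word-size-8, dust-free, ungapped seed-and-extend matcher (≥ 95% query
  coverage, Karlin–Altschul E ≤ 10); both flanking dinucleotides of every
  protospacer are reported as PAM candidates, and match positions within
  arrays are profiled.
* **Interaction network** — a bipartite community–community virus–host
  network whose directed edges carry three statistics: total
  spacer–protospacer matches, distinct matching spacers (cluster-level),
  and distinct matched viral contigs; plus intra- vs inter-community
  summaries and per-contig dossiers (spacers, Cas types, array positions,
  PAM census, depth fold-changes).
* **Synthetic communities** — a generator that plants defense operons,
  CRISPR arrays, protospacer sites with chosen PAMs and mutation loads,
  shared contigs with chosen depths, and noisy hits/verdicts, recording
  everything in a truth manifest. The whole pipeline is testable end to
  end without any external data.

## Worked example

Generate a two-community scenario with one planted Zorya and one planted
BREX system, and three protospacers (1 mismatch each, CC/GG flanks) planted
from the IP spacerome into an HP viral contig — then recover all of it:

```r
library(phagenet)
cfg <- scenario_config(
  communities = c("IP", "HP"), contig_length = c(8000L, 10000L),
  planted_systems = data.frame(community = c("IP", "HP"),
                               system_name = c("Zorya", "BREX"),
                               n_genes = c(2L, 3L)),
  planting = data.frame(spacer_source = "IP", contig_source = "HP",
                        n_sites = 3L, mismatches = 1L, pam_5p = "CC",
                        pam_3p = "GG", strand = "+"),
  seed = 7)
sc <- generate_scenario(cfg)

calls <- call_defense_systems(filter_and_resolve_hits(
  annotate_hits(sc$hits, sc$mapping)))
calls[, c("contig_id", "system_name", "n_members", "member_orf_indices", "min_evalue")]
#>   contig_id system_name n_members member_orf_indices   min_evalue
#> 1    HP_b01        BREX         3              0,1,3 9.875483e-44
#> 2    IP_b01       Zorya         2                0,3 1.309697e-43

vir <- sc$contigs[sc$contigs$fraction == "viral", ]
m <- find_protospacers(sc$spacers, vir)
m[, c("spacer_id", "contig_id", "strand", "contig_start", "contig_end",
      "mismatches", "flank_5p", "flank_3p")]
#>     spacer_id contig_id strand contig_start contig_end mismatches flank_5p flank_3p
#> 1 IP_arr1_s00    HP_v01      +         1991       2022          1       CC       GG
#> 2 IP_arr1_s01    HP_v01      +         1929       1960          1       CC       GG
#> 3 IP_arr1_s02    HP_v01      +         1760       1791          1       CC       GG

build_network(m, sc$spacers, vir)$edges
#>   spacer_source contig_source total_matches n_matching_spacers n_matched_contigs is_max_for_source
#> 1            IP            HP             3                  3                 1              TRUE
```

The two planted systems come back as exactly one call each (the chained
member ORFs and the best member E-value are shown); the three planted
protospacers are found at 1 mismatch with their CC 5′ flank — the motif a
type I-F CRISPR system requires — and aggregate into a single IP→HP edge:
3 matches, 3 distinct spacers, 1 viral contig. With per-sample
normalization contexts (`normalization_context(L, N)`),
`normalized_count_table()` turns the calls into depth-weighted abundance
tables.

The same stages run end to end from files via `run_pipeline("run.yaml",
"out/")` (see `?validate_run_config` for the schema) or the thin wrapper in
`inst/scripts/phagenet`.

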
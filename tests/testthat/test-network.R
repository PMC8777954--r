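mk_match <- function(spacer_id, contig_id, start, sample = "B",
                     flank5 = "CC", flank3 = "GG") {
  data.frame(spacer_id = spacer_id, contig_id = contig_id, contig_sample = sample,
             strand = "+", contig_start = start, contig_end = start + 31L,
             spacer_start = 1L, spacer_end = 32L, aligned_len = 32L,
             mismatches = 0L, identity_fraction = 1, aligned_query_fraction = 1,
             score = 64, evalue = 1e-12, flank_5p = flank5, flank_3p = flank3,
             stringsAsFactors = FALSE)
}

test_that("edge statistics follow the match/spacer/contig counting definitions", {
  spacers <- make_spacers(setNames(random_dna(2, 32), c("sA1", "sA2")), sample = "A")
  contigs <- make_contigs(setNames(random_dna(1, 200), "vB1"), sample = "B")
  # one spacer hits two sites in one contig: (2, 1, 1)
  m <- rbind(mk_match("sA1", "vB1", 10), mk_match("sA1", "vB1", 100))
  e <- build_network(m, spacers, contigs)$edges
  expect_equal(nrow(e), 1L)
  expect_equal(unlist(e[, c("total_matches", "n_matching_spacers", "n_matched_contigs")],
                      use.names = FALSE), c(2L, 1L, 1L))
  # two spacers hit the same contig once each: (2, 2, 1)
  m2 <- rbind(mk_match("sA1", "vB1", 10), mk_match("sA2", "vB1", 100))
  e2 <- build_network(m2, spacers, contigs)$edges
  expect_equal(unlist(e2[, c("total_matches", "n_matching_spacers", "n_matched_contigs")],
                      use.names = FALSE), c(2L, 2L, 1L))
})

test_that("total matches are conserved and node sizes reflect input counts", {
  set.seed(30)
  spacers <- rbind(make_spacers(setNames(random_dna(3, 32), paste0("a", 1:3)), sample = "A"),
                   make_spacers(setNames(random_dna(2, 32), paste0("b", 1:2)), sample = "B",
                                array_id = "arrB"))
  contigs <- rbind(make_contigs(setNames(random_dna(2, 200), c("vA1", "vA2")), sample = "A"),
                   make_contigs(setNames(random_dna(1, 200), "vB1"), sample = "B"))
  m <- rbind(mk_match("a1", "vA1", 10, sample = "A"),
             mk_match("a1", "vB1", 10),
             mk_match("a2", "vB1", 60),
             mk_match("b1", "vB1", 120))
  net <- build_network(m, spacers, contigs)
  expect_equal(sum(net$edges$total_matches), nrow(m))
  ns <- net$node_sizes
  expect_equal(ns$size[ns$kind == "spacerome" & ns$sample == "A"], 3L)
  expect_equal(ns$size[ns$kind == "virome" & ns$sample == "B"], 1L)
  # locality: dropping one community's matches removes exactly its edges
  net2 <- build_network(m[m$spacer_id != "b1", ], spacers, contigs)
  expect_true(all(net2$edges$spacer_source == "A"))
  expect_equal(sum(net2$edges$total_matches), 3L)
})

test_that("cluster-level spacer counting never exceeds raw counting", {
  set.seed(31)
  s <- random_dna(1, 32)
  spacers <- make_spacers(c(x1 = s, x2 = s), sample = "A")  # identical pair
  contigs <- make_contigs(setNames(random_dna(1, 300), "vB1"), sample = "B")
  m <- rbind(mk_match("x1", "vB1", 10), mk_match("x2", "vB1", 100))
  cl <- cluster_sequences(setNames(spacers$sequence, spacers$spacer_id), 0.95, 0.95)
  raw <- build_network(m, spacers, contigs)$edges
  clustered <- build_network(m, spacers, contigs, spacer_clusters = cl)$edges
  expect_equal(raw$n_matching_spacers, 2L)
  expect_equal(clustered$n_matching_spacers, 1L)
  expect_lte(clustered$n_matching_spacers, raw$n_matching_spacers)
  expect_equal(clustered$total_matches, raw$total_matches)  # sites unaffected
})

test_that("intra-dominance summary compares within- vs between-community matches", {
  edges <- data.frame(
    spacer_source = c("A", "A", "B", "B"), contig_source = c("A", "B", "B", "A"),
    total_matches = c(5L, 2L, 1L, 3L),
    n_matching_spacers = c(3L, 2L, 1L, 2L),
    n_matched_contigs = c(2L, 1L, 1L, 1L),
    is_max_for_source = TRUE, stringsAsFactors = FALSE)
  s <- intra_vs_inter_summary(edges)
  tA <- s$table[s$table$spacer_source == "A", ]
  tB <- s$table[s$table$spacer_source == "B", ]
  expect_true(tA$intra_dominant)                 # 5 > 2
  expect_false(tB$intra_dominant)                # 1 < 3: spacers point elsewhere
  expect_equal(tB$best_inter_target, "A")
  expect_equal(s$fraction_intra_dominant, 0.5)
})

test_that("the per-contig dossier recounts match statistics exactly", {
  set.seed(32)
  spacers <- make_spacers(setNames(random_dna(4, 32), paste0("s", 1:4)),
                          sample = "IP", positions = 0:3)
  members <- c("vc_IP", "vc_HP")
  contigs <- rbind(make_contigs(setNames(random_dna(1, 300), "vc_IP"),
                                sample = "IP", mean_depth = 10),
                   make_contigs(setNames(random_dna(1, 300), "vc_HP"),
                                sample = "HP", mean_depth = 90))
  m <- rbind(mk_match("s1", "vc_IP", 10, "IP"), mk_match("s1", "vc_HP", 10, "HP"),
             mk_match("s2", "vc_IP", 60, "IP", flank5 = "AA"),
             mk_match("s2", "vc_HP", 60, "HP", flank5 = "AA"),
             mk_match("s3", "vc_HP", 120, "HP"))
  d <- contig_interaction_report(members, m, spacers, contigs)
  ip <- d$per_community$IP
  expect_equal(ip$n_matching_spacers, 3L)
  expect_equal(ip$total_matches, 5L)
  # PAM census deduplicates identical sites across cluster members
  expect_equal(as.integer(ip$pam_census_5p[c("CC", "AA")]), c(2L, 1L))
  expect_equal(ip$cas_types, "I-F")
  fc <- d$depth_fold_changes
  expect_equal(fc$ratio[fc$numerator == "HP" & fc$denominator == "IP"], 9)

  # contig with no matches: empty dossier
  d0 <- contig_interaction_report("vc_none", m[0, ], spacers, contigs[0, ])
  expect_equal(length(d0$per_community), 0L)
  expect_null(d0$depth_fold_changes)
})
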
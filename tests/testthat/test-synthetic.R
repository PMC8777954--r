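test_that("planted systems appear as chained hits and are listed in the manifest", {
  cfg <- scenario_config(
    communities = "A", n_contigs = 1L, contig_length = c(6000L, 6000L),
    n_viral_contigs = 1L, n_arrays = 1L,
    planted_systems = data.frame(community = "A", system_name = "Zorya",
                                 n_genes = 2L, stringsAsFactors = FALSE),
    seed = 5)
  sc <- generate_scenario(cfg)
  expect_equal(nrow(sc$manifest$planted_systems), 1L)
  zor <- sc$hits[grepl("^Zorya", sc$hits$profile), ]
  expect_gte(nrow(zor), 2L)
  idx <- sort(zor$orf_index)
  expect_true(all(diff(idx) - 1L < 5L))          # callable under the gap rule
  expect_true(all(zor$evalue <= 1e-15))
  # and the calling machinery recovers it
  calls <- call_defense_systems(filter_and_resolve_hits(
    annotate_hits(sc$hits, sc$mapping)))
  expect_equal(calls$system_name, "Zorya")
})

test_that("the planted PAM census is mirrored in the manifest", {
  pl <- rbind(
    data.frame(spacer_source = "A", contig_source = "A", n_sites = 9L,
               mismatches = 0L, pam_5p = "CC", pam_3p = "GG", strand = "+",
               stringsAsFactors = FALSE),
    data.frame(spacer_source = "A", contig_source = "A", n_sites = 1L,
               mismatches = 0L, pam_5p = "AA", pam_3p = "GG", strand = "+",
               stringsAsFactors = FALSE))
  cfg <- scenario_config(communities = "A", n_arrays = 2L, spacers_per_array = 6L,
                         planting = pl, seed = 6)
  sc <- generate_scenario(cfg)
  census <- table(sc$manifest$planted_sites$pam_5p)
  expect_equal(as.integer(census[c("CC", "AA")]), c(9L, 1L))
})

test_that("fixture generation is byte-identical under a fixed seed", {
  cfg <- scenario_config(communities = c("A", "B"),
                         planted_systems = data.frame(
                           community = "A", system_name = "RM", n_genes = 2L,
                           stringsAsFactors = FALSE),
                         planting = data.frame(
                           spacer_source = "A", contig_source = "B", n_sites = 2L,
                           mismatches = 1L, pam_5p = "CC", pam_3p = "GG",
                           strand = "+", stringsAsFactors = FALSE),
                         noise_hit_rate = 3, depth_model = "poisson", seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_scenario(cfg, d1)
  generate_scenario(cfg, d2)
  expect_identical(unname(hash_dir(d1)), unname(hash_dir(d2)))
})

test_that("protospacer mutation plants exact Hamming distances", {
  set.seed(8)
  sp <- random_dna(1, 32)
  expect_identical(mutate_protospacer(sp, 0), sp)
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (k in c(1, 2, 5)) {
    mut <- mutate_protospacer(sp, k)
    expect_equal(hamming(sp, mut), k)
    # an exact 8-mer window survives in preserve mode
    w <- function(x) substring(x, 1:(nchar(x) - 7), 8:nchar(x))
    expect_true(any(w(mut) %in% w(sp)))
  }
})

test_that("noise hits scale with the configured rate and cannot fake systems at rate 0", {
  base <- function(rate, seed) scenario_config(
    communities = c("A", "B"), n_contigs = 6L, contig_length = c(8000L, 12000L),
    noise_hit_rate = rate, n_arrays = 0L, spacers_per_array = 0L, seed = seed)
  sc0 <- generate_scenario(base(0, 9))
  expect_equal(nrow(sc0$hits), 0L)               # no systems planted, no noise
  calls0 <- call_defense_systems(filter_and_resolve_hits(
    annotate_hits(sc0$hits, sc0$mapping)))
  expect_equal(nrow(calls0), 0L)
  n_lo <- sum(vapply(1:5, function(s) nrow(generate_scenario(base(5, s))$hits), numeric(1)))
  n_hi <- sum(vapply(1:5, function(s) nrow(generate_scenario(base(40, s))$hits), numeric(1)))
  expect_gt(n_hi, n_lo)
})

test_that("infeasible planting is rejected with a config error", {
  cfg <- scenario_config(communities = "A", n_viral_contigs = 1L,
                         viral_contig_length = c(40L, 40L),
                         spacers_per_array = 2L,
                         planting = data.frame(
                           spacer_source = "A", contig_source = "A", n_sites = 1L,
                           mismatches = 0L, pam_5p = "CC", pam_3p = "GG",
                           strand = "+", stringsAsFactors = FALSE),
                         seed = 10)
  expect_error(generate_scenario(cfg), "longer than target contig")
})

test_that("shared contigs are copied identically with per-sample depths", {
  cfg <- scenario_config(
    communities = c("IP", "HP"), n_viral_contigs = 1L,
    shared_contigs = list(list(prefix = "phage", samples = c("IP", "HP"),
                               length = 2000L, depths = c(IP = 10, HP = 90))),
    seed = 11)
  sc <- generate_scenario(cfg)
  a <- sc$contigs[sc$contigs$id == "phage_IP", ]
  b <- sc$contigs[sc$contigs$id == "phage_HP", ]
  expect_identical(a$sequence, b$sequence)
  expect_equal(a$mean_depth, 10)
  expect_equal(b$mean_depth, 90)
})
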
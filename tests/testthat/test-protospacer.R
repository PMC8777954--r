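embed_at <- function(contig, insert, at) {
  stopifnot(at + nchar(insert) - 1 <= nchar(contig))
  substr(contig, at, at + nchar(insert) - 1) <- insert
  contig
}

test_that("a verbatim spacer is found once with full identity and coverage", {
  set.seed(10)
  sp <- random_dna(1, 32)
  contig <- embed_at(random_dna(1, 5000), sp, 1201)
  m <- find_protospacers(make_spacers(c(s1 = sp)), make_contigs(c(v1 = contig)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "+")
  expect_equal(c(m$contig_start, m$contig_end), c(1201L, 1232L))
  expect_equal(m$identity_fraction, 1)
  expect_equal(m$aligned_query_fraction, 1)
  expect_equal(m$mismatches, 0L)
})

test_that("a reverse-complement embed is reported on strand - with forward coordinates", {
  set.seed(11)
  sp <- random_dna(1, 32)
  contig <- embed_at(random_dna(1, 5000), revcomp(sp), 3001)
  m <- find_protospacers(make_spacers(c(s1 = sp)), make_contigs(c(v1 = contig)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "-")
  expect_equal(c(m$contig_start, m$contig_end), c(3001L, 3032L))
  expect_equal(m$identity_fraction, 1)
})

test_that("reverse-complementing every contig flips strands and reflects coordinates", {
  set.seed(12)
  spacers <- make_spacers(setNames(random_dna(3, 32), paste0("s", 1:3)))
  contig <- random_dna(1, 4000)
  contig <- embed_at(contig, spacers$sequence[1], 101)
  contig <- embed_at(contig, revcomp(spacers$sequence[2]), 2001)
  cc <- make_contigs(c(v1 = contig))
  m_fwd <- find_protospacers(spacers, cc)
  cc_rc <- cc; cc_rc$sequence <- revcomp(cc$sequence)
  m_rc <- find_protospacers(spacers, cc_rc)
  expect_equal(nrow(m_fwd), nrow(m_rc))
  len <- nchar(contig)
  key_fwd <- paste(m_fwd$spacer_id, m_fwd$strand, m_fwd$contig_start, m_fwd$contig_end)
  key_ref <- paste(m_rc$spacer_id, chartr("+-", "-+", m_rc$strand),
                   len - m_rc$contig_end + 1L, len - m_rc$contig_start + 1L)
  expect_setequal(key_fwd, key_ref)
  # PAM flanks are strand-symmetric: same dinucleotides in protospacer orientation
  expect_setequal(paste(m_fwd$spacer_id, m_fwd$flank_5p, m_fwd$flank_3p),
                  paste(m_rc$spacer_id, m_rc$flank_5p, m_rc$flank_3p))
})

test_that("planted sites at 0-2 mismatches match the Smith-Waterman oracle exactly", {
  set.seed(13)
  n_sp <- 8
  spacers <- make_spacers(setNames(random_dna(n_sp, 32), paste0("s", 1:n_sp)))
  contig <- random_dna(1, 20000)
  at <- 500 + (seq_len(n_sp) - 1) * 2400
  mm <- rep(0:2, length.out = n_sp)
  strands <- rep(c("+", "-"), length.out = n_sp)
  for (i in seq_len(n_sp)) {
    proto <- mutate_protospacer(spacers$sequence[i], mm[i])
    ins <- if (strands[i] == "+") proto else revcomp(proto)
    contig <- embed_at(contig, ins, at[i])
  }
  cc <- make_contigs(c(v1 = contig))
  m <- find_protospacers(spacers, cc)
  expect_equal(nrow(m), n_sp)                      # recall 1.0, no duplicates
  for (i in seq_len(n_sp)) {
    row <- m[m$spacer_id == spacers$spacer_id[i], ]
    expect_equal(nrow(row), 1L)
    orc <- oracle_protospacer(spacers$sequence[i], contig, strands[i])
    expect_equal(row$strand, strands[i])
    expect_equal(row$contig_start, orc$contig_start)
    expect_equal(row$contig_end, orc$contig_end)
    expect_equal(row$score, orc$score)
    expect_equal(row$aligned_len - row$mismatches, orc$matches)
  }
})

test_that("disrupting every seed word defeats the word-seeded matcher but not full alignment", {
  set.seed(14)
  sp <- random_dna(1, 32)
  broken <- disrupt_protospacer_words(sp, word_size = 8)
  # no 8-mer survives
  w <- function(x) substring(x, 1:(nchar(x) - 7), 8:nchar(x))
  expect_false(any(w(broken) %in% w(sp)))
  contig <- embed_at(random_dna(1, 5000), broken, 2001)
  m <- find_protospacers(make_spacers(c(s1 = sp)), make_contigs(c(v1 = contig)))
  expect_equal(nrow(m), 0L)                        # documented sensitivity gap
  orc <- oracle_protospacer(sp, contig, "+")
  expect_gte(orc$matches, 28L)                     # SW still sees the site
})

test_that("no matches arise from unplanted uniform sequence (false-positive bound)", {
  set.seed(15)
  spacers <- make_spacers(setNames(random_dna(10, 32), paste0("s", 1:10)))
  cc <- make_contigs(setNames(random_dna(2, 100000), c("v1", "v2")))
  m <- find_protospacers(spacers, cc)
  expect_equal(nrow(m), 0L)
})

test_that("PAM flanks are reported in protospacer orientation with N padding at ends", {
  set.seed(16)
  sp <- random_dna(1, 32)
  # ...AACC[protospacer]GGTT... on the forward strand
  contig <- paste0(random_dna(1, 96), "AACC", sp, "GGTT", random_dna(1, 96))
  cc <- make_contigs(c(v1 = contig))
  m <- find_protospacers(make_spacers(c(s1 = sp)), cc)
  expect_equal(m$flank_5p, "CC")
  expect_equal(m$flank_3p, "GG")

  # same site on the minus strand: flanks computed from the reverse complement
  contig2 <- paste0(random_dna(1, 96), "AACC", revcomp(sp), "GGTT", random_dna(1, 96))
  m2 <- find_protospacers(make_spacers(c(s1 = sp)), make_contigs(c(v1 = contig2)))
  expect_equal(m2$strand, "-")
  expect_equal(m2$flank_5p, "CC")
  expect_equal(m2$flank_3p, "GG")

  # protospacer at position 1: 5' flank padded with N
  contig3 <- paste0(sp, random_dna(1, 200))
  m3 <- find_protospacers(make_spacers(c(s1 = sp)), make_contigs(c(v1 = contig3)))
  expect_equal(m3$flank_5p, "NN")
})

test_that("array position profiles detect runs at array start and both ends", {
  set.seed(17)
  spacers <- make_spacers(setNames(random_dna(10, 32), paste0("s", 0:9)),
                          positions = 0:9)
  mk_matches <- function(pos) data.frame(
    spacer_id = paste0("s", pos), contig_id = "v1", contig_sample = "S",
    strand = "+", contig_start = 1L, contig_end = 32L, stringsAsFactors = FALSE)
  p1 <- array_position_profile(mk_matches(0:2), spacers)
  expect_equal(p1$n_runs, 1L)
  expect_false(p1$multi_run)
  expect_equal(p1$matched_positions, "0,1,2")

  p2 <- array_position_profile(mk_matches(c(0, 1, 8, 9)), spacers)
  expect_equal(p2$n_runs, 2L)
  expect_true(p2$multi_run)

  expect_equal(nrow(array_position_profile(mk_matches(0)[0, ], spacers)), 0L)
})

test_that("self-matches to the source array contig are suppressed", {
  set.seed(18)
  sp <- random_dna(1, 32)
  contig <- embed_at(random_dna(1, 2000), sp, 501)
  spacers <- make_spacers(c(s1 = sp))
  spacers$array_contig <- "v1"
  m <- find_protospacers(spacers, make_contigs(c(v1 = contig)))
  expect_equal(nrow(m), 0L)
  spacers$array_contig <- NA_character_
  expect_equal(nrow(find_protospacers(spacers, make_contigs(c(v1 = contig)))), 1L)
})
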
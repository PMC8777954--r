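# helpers to build assignment tables tersely
mk_hits <- function(orf, profile, system, evalue, contig = "c1") {
  data.frame(contig_id = contig, orf_index = as.integer(orf),
             profile_id = profile, system_name = system,
             gene_name = profile, evalue = evalue, stringsAsFactors = FALSE)
}

test_that("hit resolution keeps the lowest-E-value profile per ORF", {
  h <- rbind(mk_hits(4, "ZorA_p1", "Zorya", 1e-30),
             mk_hits(4, "BrxC_p1", "BREX", 1e-12))
  a <- filter_and_resolve_hits(h, evalue_max = 1e-10)
  expect_equal(nrow(a), 1L)
  expect_equal(a$profile_id, "ZorA_p1")
  expect_equal(a$system_name, "Zorya")
})

test_that("the E-value threshold is exclusive and drops weak single hits", {
  h <- mk_hits(1, "P1", "RM", 1e-5)
  expect_equal(nrow(filter_and_resolve_hits(h, evalue_max = 1e-10)), 0L)
  # boundary: evalue == threshold is excluded ('<' rule)
  h2 <- mk_hits(1, "P1", "RM", 1e-10)
  expect_equal(nrow(filter_and_resolve_hits(h2, evalue_max = 1e-10)), 0L)
  expect_equal(nrow(filter_and_resolve_hits(h2, evalue_max = 1e-9)), 1L)
})

test_that("exact E-value ties resolve to the lexicographically first profile, regardless of row order", {
  h <- rbind(mk_hits(3, "Zeta_p", "Zeta", 1e-20),
             mk_hits(3, "Alpha_p", "Alpha", 1e-20))
  for (perm in list(1:2, 2:1)) {
    a <- filter_and_resolve_hits(h[perm, ], evalue_max = 1e-10)
    expect_equal(a$profile_id, "Alpha_p")
  }
})

test_that("system calling applies the intervening-ORF gap rule literally", {
  # 3 intervening ORFs (< 5): one call
  h <- rbind(mk_hits(3, "ZorA", "Zorya", 1e-30), mk_hits(7, "ZorB", "Zorya", 1e-25))
  calls <- call_defense_systems(filter_and_resolve_hits(h), max_gap = 5)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$member_orf_indices, "3,7")
  expect_equal(calls$n_members, 2L)
  expect_equal(calls$min_evalue, 1e-30)

  # 5 intervening ORFs: not < 5, no call
  h2 <- rbind(mk_hits(3, "ZorA", "Zorya", 1e-30), mk_hits(9, "ZorB", "Zorya", 1e-25))
  expect_equal(nrow(call_defense_systems(filter_and_resolve_hits(h2), max_gap = 5)), 0L)
})

test_that("chaining is transitive and requires two distinct profiles", {
  h <- rbind(mk_hits(2, "P1", "BREX", 1e-30), mk_hits(6, "P1", "BREX", 1e-28),
             mk_hits(10, "P2", "BREX", 1e-25))
  a <- filter_and_resolve_hits(h)
  calls <- call_defense_systems(a, max_gap = 5)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_members, 3L)
  expect_equal(calls$member_orf_indices, "2,6,10")
  expect_identical(canon_calls(calls), oracle_call_systems(a, 5))

  # same chain with a single profile everywhere: discarded
  h1p <- rbind(mk_hits(2, "P1", "BREX", 1e-30), mk_hits(6, "P1", "BREX", 1e-28),
               mk_hits(10, "P1", "BREX", 1e-25))
  expect_equal(nrow(call_defense_systems(filter_and_resolve_hits(h1p), 5)), 0L)
})

test_that("random small contigs: calls equal brute-force subset enumeration", {
  set.seed(101)
  systems <- c("Zorya", "BREX", "RM")
  for (rep in 1:30) {
    n_orfs <- sample(4:15, 1)
    n_hits <- sample(2:min(8, n_orfs), 1)
    orf <- sort(sample(0:(n_orfs - 1), n_hits))
    sys <- sample(systems, n_hits, replace = TRUE)
    prof <- paste0(sys, "_p", sample(1:3, n_hits, replace = TRUE))
    h <- mk_hits(orf, prof, sys, 10^runif(n_hits, -40, -12),
                 contig = sprintf("rc%02d", rep))
    a <- filter_and_resolve_hits(h)
    expect_identical(canon_calls(call_defense_systems(a, max_gap = 5)),
                     oracle_call_systems(a, max_gap = 5))
  }
})

test_that("increasing max_gap never shrinks the set of ORFs covered by calls", {
  set.seed(202)
  covered <- function(calls) {
    if (!nrow(calls)) return(integer(0))
    sort(unique(unlist(lapply(strsplit(calls$member_orf_indices, ","), as.integer))))
  }
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    orf <- sort(sample(0:19, n))
    h <- mk_hits(orf, paste0("P", sample(1:3, n, replace = TRUE)), "RM",
                 10^runif(n, -40, -12))
    a <- filter_and_resolve_hits(h)
    prev <- integer(0)
    for (g in c(1, 3, 5, 8, 12)) {
      cur <- covered(call_defense_systems(a, max_gap = g))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("island detection merges co-clustered systems transitively", {
  calls <- data.frame(
    contig_id = "c1", system_name = c("RM", "BREX"),
    n_members = 2L, member_orf_indices = c("1,3", "6,9"),
    member_profiles = "x,y", first_orf = c(1L, 6L), last_orf = c(3L, 9L),
    min_evalue = 1e-20, stringsAsFactors = FALSE)
  isl <- detect_islands(calls, island_gap = 10)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$n_systems, 2L)
  expect_equal(c(isl$first_orf, isl$last_orf), c(1L, 9L))

  # single call: no island
  expect_equal(nrow(detect_islands(calls[1, ], island_gap = 10)), 0L)

  # three calls pairwise within gap merge into one island
  calls3 <- rbind(calls, within(calls[1, ], {
    system_name <- "CBASS"; first_orf <- 14L; last_orf <- 16L
    member_orf_indices <- "14,16"
  }))
  isl3 <- detect_islands(calls3, island_gap = 10)
  expect_equal(nrow(isl3), 1L)
  expect_equal(isl3$n_systems, 3L)

  # tandem copies of one system are not an island unless another type joins
  same <- calls; same$system_name <- c("RM", "RM")
  expect_equal(nrow(detect_islands(same, island_gap = 10)), 0L)
  expect_equal(nrow(detect_islands(same, island_gap = 10,
                                   require_multi_system = FALSE)), 1L)
})

test_that("count tables count systems as calls and genes as assignments", {
  h <- rbind(mk_hits(c(0, 1), c("ZorA", "ZorB"), "Zorya", 1e-30, contig = "cA"))
  a <- filter_and_resolve_hits(h)
  calls <- call_defense_systems(a)
  cs <- c(cA = "A")
  expect_equal(count_defense(calls, a, cs, by = "system")["A", "Zorya"], 1L)
  expect_equal(count_defense(calls, a, cs, by = "gene")["A", "Zorya"], 2L)

  # empty input with declared universes gives an all-zero table
  empty <- count_defense(calls[0, ], a[0, ], cs, by = "system",
                         samples = c("A", "B"), systems = c("Zorya", "RM"))
  expect_equal(dim(empty), c(2L, 2L))
  expect_true(all(empty == 0L))
})

test_that("singleton hits count as genes by default but not under calls-only counting", {
  h <- rbind(mk_hits(c(0, 1), c("ZorA", "ZorB"), "Zorya", 1e-30, contig = "cA"),
             mk_hits(30, "RM_p1", "RM", 1e-30, contig = "cA"))
  a <- filter_and_resolve_hits(h)
  calls <- call_defense_systems(a)
  cs <- c(cA = "A")
  g_all <- count_defense(calls, a, cs, by = "gene")
  expect_equal(g_all["A", "RM"], 1L)
  g_in <- count_defense(calls, a, cs, by = "gene", genes_in_calls_only = TRUE)
  expect_false("RM" %in% colnames(g_in) && g_in["A", "RM"] > 0)
  expect_equal(g_in["A", "Zorya"], 2L)
})

test_that("outputs are invariant to hit-table row permutation", {
  set.seed(303)
  n <- 10
  h <- mk_hits(sort(sample(0:14, n)), paste0("P", sample(1:4, n, TRUE)),
               sample(c("RM", "BREX"), n, TRUE), 10^runif(n, -40, -12))
  ref <- call_defense_systems(filter_and_resolve_hits(h))
  for (rep in 1:5) {
    perm <- sample(n)
    got <- call_defense_systems(filter_and_resolve_hits(h[perm, ]))
    expect_identical(got, ref)
  }
})
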
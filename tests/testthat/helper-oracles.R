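# Independent oracles used across the suite. They deliberately share no code
# with the implementation paths they check.

options(phagenet.quiet = TRUE)

# ---- brute-force defense-system caller -------------------------------------
# Enumerates every subset of assigned ORFs per (contig, system); a subset is
# valid when it has >= 2 members, >= 2 distinct profiles, and every pair of
# consecutive members has (orf_index difference - 1) < max_gap. Maximal valid
# subsets (not contained in a larger valid subset) are the calls.
oracle_call_systems <- function(assignments, max_gap = 5L) {
  grp <- paste(assignments$contig_id, assignments$system_name, sep = "\r")
  out <- list()
  for (g in split(assignments, grp)) {
    g <- g[order(g$orf_index), , drop = FALSE]
    n <- nrow(g)
    if (n > 20L) stop("oracle limited to 20 assigned ORFs per system")
    valid <- list()
    for (mask in seq_len(2^n - 1L)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
      if (length(sel) < 2L) next
      idx <- g$orf_index[sel]
      if (any(diff(idx) - 1L >= max_gap)) next
      if (length(unique(g$profile_id[sel])) < 2L) next
      valid[[length(valid) + 1L]] <- sel
    }
    if (!length(valid)) next
    maximal <- Filter(function(a) !any(vapply(valid, function(b)
      length(b) > length(a) && all(a %in% b), logical(1))), valid)
    maximal <- unique(lapply(maximal, sort))
    for (sel in maximal) {
      out[[length(out) + 1L]] <- data.frame(
        contig_id = g$contig_id[1L], system_name = g$system_name[1L],
        member_orf_indices = paste(g$orf_index[sel], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig_id = character(0), system_name = character(0),
                      member_orf_indices = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$system_name, res$member_orf_indices), , drop = FALSE]
}

# canonical form of implementation calls for comparison with the oracle
canon_calls <- function(calls) {
  res <- calls[, c("contig_id", "system_name", "member_orf_indices")]
  res <- res[order(res$contig_id, res$system_name, res$member_orf_indices), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- plain-R Smith-Waterman ------------------------------------------------
# Linear gap cost; returns the best local alignment with match count and the
# aligned span on each sequence. Used as the alignment oracle for the greedy
# clusterer (which internally relies on Biostrings), on short sequences only.
sw_r <- function(a, b, match = 2, mismatch = -3, gap = -7) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ac[i] == bc[j]) match else mismatch
      h <- max(0, H[i, j] + s, H[i, j + 1L] + gap, H[i + 1L, j] + gap)
      H[i + 1L, j + 1L] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best == 0) return(list(score = 0, matches = 0L, a_span = 0L, b_span = 0L,
                             a_start = NA, a_end = NA, b_start = NA, b_end = NA))
  # traceback
  i <- bi; j <- bj; matches <- 0L
  a_end <- bi; b_end <- bj
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    s <- if (ac[i] == bc[j]) match else mismatch
    if (H[i + 1L, j + 1L] == H[i, j] + s) {
      if (ac[i] == bc[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (H[i + 1L, j + 1L] == H[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = best, matches = matches,
       a_start = i + 1L, a_end = a_end, b_start = j + 1L, b_end = b_end,
       a_span = a_end - i, b_span = b_end - j)
}

# ---- brute-force greedy clustering oracle ----------------------------------
# Same greedy protocol as cluster_sequences (longest-first, first matching
# representative) but with the plain-R Smith-Waterman as comparator.
oracle_cluster <- function(seqs, identity, coverage, both_strands = TRUE) {
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- as.character(seqs[ord])
  reps <- integer(0)
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    q <- seqs[i]; nq <- nchar(q)
    hit <- 0L
    for (r in seq_along(reps)) {
      cand <- if (both_strands) c(q, phagenet::revcomp(q)) else q
      ok <- FALSE
      for (qq in cand) {
        al <- sw_r(qq, seqs[reps[r]])
        if (al$matches / nq >= identity && al$a_span / nq >= coverage) {
          ok <- TRUE; break
        }
      }
      if (ok) { hit <- r; break }
    }
    if (hit > 0L) assign_to[i] <- hit
    else { reps <- c(reps, i); assign_to[i] <- length(reps) }
  }
  data.frame(member_id = ids, representative_id = ids[reps[assign_to]],
             cluster = assign_to, stringsAsFactors = FALSE)
}

# comparable canonical form of a clustering: sorted member sets
canon_clusters <- function(cl) {
  sets <- lapply(split(cl$member_id, cl$cluster), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1L))])
}

# ---- full Smith-Waterman protospacer oracle --------------------------------
# Independent route for the seed-and-extend matcher: Biostrings local
# alignment of the spacer (given strand) against a contig, reporting subject
# coordinates. Effectively ungapped through prohibitive gap costs, matching
# the matcher's alignment model while sharing none of its code.
oracle_protospacer <- function(spacer_seq, contig_seq, strand = "+") {
  q <- if (strand == "+") spacer_seq else phagenet::revcomp(spacer_seq)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(q), subject = Biostrings::DNAString(contig_seq),
    type = "local", substitutionMatrix = sm, gapOpening = 1000, gapExtension = 1000)
  s <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       contig_start = Biostrings::start(s), contig_end = Biostrings::end(s),
       matches = Biostrings::nmatch(aln),
       aligned_len = Biostrings::end(s) - Biostrings::start(s) + 1L)
}

# ---- misc helpers ----------------------------------------------------------
hash_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- basename(names(h))
  h
}

# a minimal in-memory contig table
make_contigs <- function(seqs, sample = "S", fraction = "viral",
                         mean_depth = NA_real_) {
  data.frame(id = names(seqs), sample = sample, fraction = fraction,
             sequence = unname(seqs), length = nchar(seqs),
             mean_depth = mean_depth, stringsAsFactors = FALSE)
}

# a minimal spacer table
make_spacers <- function(seqs, sample = "S", array_id = "arr1",
                         positions = seq_along(seqs) - 1L) {
  data.frame(spacer_id = names(seqs), sample = sample, fraction = "bacterial",
             array_id = array_id, position_in_array = positions,
             sequence = unname(seqs), cas_type = "I-F",
             array_contig = NA_character_, stringsAsFactors = FALSE)
}
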
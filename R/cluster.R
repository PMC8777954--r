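# Greedy incremental sequence clustering in the cd-hit style: sequences are
# visited longest-first and each one joins the first existing cluster whose
# representative it matches at the identity/coverage thresholds, else founds
# a new cluster. Identity uses the global-identity convention: matching
# positions of the best local alignment divided by the length of the SHORTER
# sequence; coverage is the aligned fraction of the shorter sequence.

# best local alignment of the shorter sequence against a representative;
# returns c(identity, coverage) under the conventions above
.pair_stats <- function(short_seq, rep_seq, both_strands = TRUE) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  ns <- nchar(short_seq)
  best <- c(identity = 0, coverage = 0)
  cand <- if (both_strands) c(short_seq, revcomp(short_seq)) else short_seq
  for (q in cand) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(q), subject = Biostrings::DNAString(rep_seq),
      type = "local", substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
    nm <- Biostrings::nmatch(aln)
    p <- Biostrings::pattern(aln)
    cov <- (Biostrings::end(p) - Biostrings::start(p) + 1) / ns
    id <- nm / ns
    if (id > best[["identity"]] ||
        (id == best[["identity"]] && cov > best[["coverage"]]))
      best <- c(identity = id, coverage = cov)
  }
  best
}

.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Greedy incremental sequence clustering
#'
#' Sequences are sorted by length descending (ties by id) and each joins the
#' first cluster whose representative it matches at `identity` over at least
#' `coverage` of the shorter sequence (both strands when `both_strands`),
#' else founds a new cluster. Deterministic under these tie-breaks; the
#' representative is always the longest member (founding order). For long
#' sequences a shared 16-mer prefilter skips hopeless alignments (a shared
#' 16-mer is a necessary condition for >= 0.95 identity over sequences of
#' 100 bp or more).
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param identity minimum identity fraction, in (0, 1].
#' @param coverage minimum aligned fraction of the shorter sequence.
#' @param both_strands also try the reverse complement.
#' @return data.frame with `member_id`, `representative_id`, `cluster`
#'   (integer, founding order); thresholds attached as attributes.
#' @export
cluster_sequences <- function(seqs, identity = 0.95, coverage = 0.95,
                              both_strands = TRUE) {
  stopifnot(identity > 0, identity <= 1, coverage > 0, coverage <= 1)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) .stopf("seqs must have unique names")
  if (length(seqs) == 0L)
    return(structure(data.frame(member_id = character(0),
                                representative_id = character(0),
                                cluster = integer(0), stringsAsFactors = FALSE),
                     identity = identity, coverage = coverage))
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- as.character(seqs[ord])
  use_prefilter <- identity >= 0.95
  rep_idx <- integer(0)          # indices (into sorted order) of representatives
  rep_kmers <- list()            # cached 16-mer sets (fwd of representative)
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    q <- seqs[i]
    qlen <- nchar(q)
    qk <- if (use_prefilter && qlen >= 100L)
      unique(c(.kmers(q, 16L), .kmers(revcomp(q), 16L))) else NULL
    hit <- 0L
    for (r in seq_along(rep_idx)) {
      if (!is.null(qk) && !any(qk %in% rep_kmers[[r]])) next
      st <- .pair_stats(q, seqs[rep_idx[r]], both_strands)
      if (st[["identity"]] >= identity && st[["coverage"]] >= coverage) {
        hit <- r; break
      }
    }
    if (hit > 0L) {
      assign_to[i] <- hit
    } else {
      rep_idx <- c(rep_idx, i)
      rep_kmers[[length(rep_idx)]] <- .kmers(q, 16L)
      assign_to[i] <- length(rep_idx)
    }
  }
  structure(data.frame(member_id = ids, representative_id = ids[rep_idx[assign_to]],
                       cluster = assign_to, stringsAsFactors = FALSE),
            identity = identity, coverage = coverage)
}

#' Cross-sample sharing matrix over sequence clusters
#'
#' `cell[s1, s2]` counts clusters containing at least one member from each of
#' the two samples; the diagonal counts clusters with any member from the
#' sample (the sample's non-redundant sequence count).
#'
#' @param clusters cluster data.frame from [cluster_sequences()].
#' @param member_samples named character vector: member id -> sample.
#' @param samples optional sample universe (declares all-zero rows).
#' @return symmetric integer matrix, samples x samples.
#' @export
shared_matrix <- function(clusters, member_samples, samples = NULL) {
  samp <- unname(member_samples[clusters$member_id])
  if (nrow(clusters) && anyNA(samp))
    .stopf("member(s) without sample mapping: %s",
           paste(unique(clusters$member_id[is.na(samp)]), collapse = ", "))
  samples <- sort(unique(c(samples, samp)))
  m <- matrix(0L, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (cl in split(samp, clusters$cluster)) {
    present <- unique(cl)
    for (a in present) for (b in present)
      m[a, b] <- m[a, b] + 1L
  }
  m
}
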
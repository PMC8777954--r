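# Consensus viral-contig calling and dereplication. A contig is considered
# viral when at least `min_votes` of the external caller verdicts are
# positive (2-of-3 by default); missing verdicts are conservative negative
# votes. The voted set is collapsed to a non-redundant catalogue with the
# greedy clusterer at identity 0.95 over coverage 0.8 of the shorter
# sequence.

#' Consensus viral call by tool vote
#'
#' @param verdicts data.frame with `contig_id`, `tool`, `is_viral` (one row
#'   per contig and tool; duplicates are an error). A contig absent from a
#'   tool's verdicts counts as a negative vote from that tool.
#' @param min_votes minimum number of positive verdicts.
#' @return character vector of viral contig ids (sorted).
#' @export
vote_viral <- function(verdicts, min_votes = 2L) {
  key <- paste(verdicts$contig_id, verdicts$tool, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- verdicts[duplicated(key), , drop = FALSE][1L, ]
    .stopf("duplicate verdict for contig '%s' from tool '%s'",
           dup$contig_id, dup$tool)
  }
  votes <- tapply(verdicts$is_viral, verdicts$contig_id, sum)
  viral <- sort(names(votes)[votes >= min_votes])
  .log("viral vote: %d of %d contigs pass (>= %d votes)",
       length(viral), length(votes), min_votes)
  viral
}

#' Dereplicate voted viral contigs into a non-redundant set
#'
#' Delegates to [cluster_sequences()] with the viral-catalogue thresholds
#' (identity 0.95, coverage 0.8 of the shorter sequence).
#'
#' @param contigs contig data.frame restricted to the voted viral set.
#' @param identity,coverage clustering thresholds.
#' @return list with `clusters` (the membership data.frame) and
#'   `representatives` (contig data.frame of cluster representatives).
#' @export
dereplicate_viral <- function(contigs, identity = 0.95, coverage = 0.8) {
  seqs <- contigs$sequence
  names(seqs) <- contigs$id
  cl <- cluster_sequences(seqs, identity = identity, coverage = coverage)
  reps <- contigs[match(unique(cl$representative_id), contigs$id), , drop = FALSE]
  rownames(reps) <- NULL
  .log("dereplication: %d contigs -> %d representatives", nrow(contigs), nrow(reps))
  list(clusters = cl, representatives = reps)
}

#' Viral sharing matrix across samples, plus the fraction overlap
#'
#' As [shared_matrix()] over dereplication clusters, with an additional
#' count of clusters containing members from both the bacterial and the
#' viral size fraction (the Venn intersection of the two fractions'
#' catalogues).
#'
#' @param clusters cluster data.frame from [dereplicate_viral()].
#' @param contigs contig data.frame covering every member (for `sample` and
#'   `fraction`).
#' @param samples optional sample universe.
#' @return list with `matrix` (sample x sample) and
#'   `n_cross_fraction_clusters`.
#' @export
viral_shared_matrix <- function(clusters, contigs, samples = NULL) {
  member_samples <- contigs$sample
  names(member_samples) <- contigs$id
  m <- shared_matrix(clusters, member_samples, samples = samples)
  frac <- contigs$fraction[match(clusters$member_id, contigs$id)]
  cross <- vapply(split(frac, clusters$cluster),
                  function(f) all(c("bacterial", "viral") %in% f), logical(1))
  list(matrix = m, n_cross_fraction_clusters = sum(cross))
}
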
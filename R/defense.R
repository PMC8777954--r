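# Defense-gene and defense-system calling from per-ORF HMM profile hits.
#
# Rules: hits with E-value below a cutoff are kept; an ORF hit by several
# profiles is assigned to the lowest-E-value profile; a putative system is a
# chain of >= 2 assigned ORFs of one system on one contig, consecutive
# members separated by strictly fewer than `max_gap` intervening ORFs, and
# carrying >= 2 distinct profiles.

#' Filter hits and resolve each ORF to its best profile
#'
#' Retains hits with `evalue < evalue_max`, then assigns every ORF its
#' lowest-E-value profile. Exact E-value ties are broken deterministically by
#' lexicographic `profile_id` (tie count logged), so the result is invariant
#' to input row order.
#'
#' @param hits hit data.frame from [read_hit_table()].
#' @param evalue_max E-value cutoff (exclusive). Default `1e-10`.
#' @return data.frame with one row per retained ORF: `contig_id`,
#'   `orf_index`, `profile_id`, `system_name`, `gene_name`, `evalue`.
#' @export
filter_and_resolve_hits <- function(hits, evalue_max = 1e-10) {
  stopifnot(evalue_max > 0)
  h <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (nrow(h) == 0L) return(h[, , drop = FALSE])
  # deterministic best-per-ORF: order by evalue then profile_id, keep first
  h <- h[order(h$contig_id, h$orf_index, h$evalue, h$profile_id), , drop = FALSE]
  key <- paste(h$contig_id, h$orf_index, sep = "\r")
  first <- !duplicated(key)
  ties <- tapply(h$evalue, key, function(e) sum(e == min(e)) > 1L)
  if (any(ties)) .log("%d ORF(s) with exact E-value ties resolved by profile id", sum(ties))
  out <- h[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call putative defense systems by chaining co-located assigned ORFs
#'
#' Per contig and system, assigned ORFs are chained transitively
#' (single-linkage along the contig): consecutive assigned ORFs join one
#' chain when the number of intervening ORFs (`orf_index` difference - 1) is
#' strictly less than `max_gap`. Chains with at least two member ORFs and at
#' least two distinct profiles become calls; other chains are discarded
#' (their members still count as defense genes).
#'
#' @param assignments resolved per-ORF assignments from
#'   [filter_and_resolve_hits()].
#' @param max_gap maximum number of intervening ORFs, exclusive bound.
#' @return data.frame with one row per call: `contig_id`, `system_name`,
#'   `n_members`, `member_orf_indices` (comma-joined), `member_profiles`
#'   (comma-joined sorted unique), `first_orf`, `last_orf`, `min_evalue`.
#' @export
call_defense_systems <- function(assignments, max_gap = 5L) {
  empty <- data.frame(contig_id = character(0), system_name = character(0),
                      n_members = integer(0), member_orf_indices = character(0),
                      member_profiles = character(0), first_orf = integer(0),
                      last_orf = integer(0), min_evalue = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(assignments) == 0L) return(empty)
  a <- assignments[order(assignments$contig_id, assignments$system_name,
                         assignments$orf_index), , drop = FALSE]
  grp <- paste(a$contig_id, a$system_name, sep = "\r")
  calls <- lapply(split(seq_len(nrow(a)), grp), function(i) {
    x <- a[i, , drop = FALSE]
    gap_break <- c(FALSE, diff(x$orf_index) - 1L >= max_gap)
    chain <- cumsum(gap_break)
    do.call(rbind, lapply(split(seq_len(nrow(x)), chain), function(j) {
      m <- x[j, , drop = FALSE]
      if (nrow(m) < 2L || length(unique(m$profile_id)) < 2L) return(NULL)
      data.frame(contig_id = m$contig_id[1L], system_name = m$system_name[1L],
                 n_members = nrow(m),
                 member_orf_indices = paste(m$orf_index, collapse = ","),
                 member_profiles = paste(sort(unique(m$profile_id)), collapse = ","),
                 first_orf = min(m$orf_index), last_orf = max(m$orf_index),
                 min_evalue = min(m$evalue), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) return(empty)
  out <- out[order(out$contig_id, out$first_orf, out$system_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect defense islands from co-clustered system calls
#'
#' Calls on one contig whose ORF spans are separated by at most `island_gap`
#' intervening ORFs are merged transitively. Islands must contain at least
#' two calls; with `require_multi_system = TRUE` (default) also at least two
#' distinct system types, reflecting co-clustering of different defense
#' systems rather than tandem copies of one.
#'
#' @param calls output of [call_defense_systems()].
#' @param island_gap maximum number of intervening ORFs between consecutive
#'   call spans (inclusive bound).
#' @param require_multi_system require >= 2 distinct system types per island.
#' @return data.frame with `contig_id`, `n_systems`, `system_names`
#'   (comma-joined), `first_orf`, `last_orf`.
#' @export
detect_islands <- function(calls, island_gap = 10L, require_multi_system = TRUE) {
  empty <- data.frame(contig_id = character(0), n_systems = integer(0),
                      system_names = character(0), first_orf = integer(0),
                      last_orf = integer(0), stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  cs <- calls[order(calls$contig_id, calls$first_orf, calls$last_orf), , drop = FALSE]
  out <- do.call(rbind, lapply(split(seq_len(nrow(cs)), cs$contig_id), function(i) {
    x <- cs[i, , drop = FALSE]
    # transitive merge over span gaps; spans may overlap (gap < 0)
    reach <- cummax(c(x$last_orf[1L], x$last_orf))[seq_len(nrow(x))]
    gap_break <- c(FALSE, x$first_orf[-1L] - reach[-nrow(x)] - 1L > island_gap)
    isl <- cumsum(gap_break)
    do.call(rbind, lapply(split(seq_len(nrow(x)), isl), function(j) {
      m <- x[j, , drop = FALSE]
      if (nrow(m) < 2L) return(NULL)
      if (require_multi_system && length(unique(m$system_name)) < 2L) return(NULL)
      data.frame(contig_id = m$contig_id[1L], n_systems = nrow(m),
                 system_names = paste(m$system_name, collapse = ","),
                 first_orf = min(m$first_orf), last_orf = max(m$last_orf),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Raw counts of defense genes or systems per sample and system type
#'
#' System counts count [call_defense_systems()] calls; gene counts count
#' resolved ORF assignments. By default gene counts include singleton hits
#' that did not join any call (`genes_in_calls_only = FALSE`); the flag
#' restricts them to ORFs inside called systems.
#'
#' @param calls output of [call_defense_systems()].
#' @param assignments output of [filter_and_resolve_hits()].
#' @param contig_samples named character vector mapping contig id to sample.
#' @param by count `"system"` calls or `"gene"` assignments.
#' @param genes_in_calls_only restrict gene counts to called members.
#' @param samples,systems optional row/column universes (so empty inputs
#'   still yield a fully declared all-zero table).
#' @return integer matrix, samples x system types.
#' @export
count_defense <- function(calls, assignments, contig_samples,
                          by = c("system", "gene"),
                          genes_in_calls_only = FALSE,
                          samples = NULL, systems = NULL) {
  by <- match.arg(by)
  if (by == "system") {
    df <- calls
  } else if (genes_in_calls_only) {
    keep <- vapply(seq_len(nrow(assignments)), function(i) {
      j <- calls$contig_id == assignments$contig_id[i] &
        calls$system_name == assignments$system_name[i]
      any(vapply(strsplit(calls$member_orf_indices[j], ","), function(v)
        as.character(assignments$orf_index[i]) %in% v, logical(1)))
    }, logical(1))
    df <- assignments[keep, , drop = FALSE]
  } else {
    df <- assignments
  }
  samp <- df$sample
  if (is.null(samp)) samp <- unname(contig_samples[df$contig_id])
  if (nrow(df) && anyNA(samp))
    .stopf("contig(s) without a sample mapping: %s",
           paste(unique(df$contig_id[is.na(samp)]), collapse = ", "))
  samples <- sort(unique(c(samples, samp)))
  systems <- sort(unique(c(systems, df$system_name)))
  tab <- matrix(0L, length(samples), length(systems),
                dimnames = list(samples, systems))
  if (nrow(df)) {
    t0 <- table(factor(samp, levels = samples),
                factor(df$system_name, levels = systems))
    tab[] <- as.integer(t0)
  }
  tab
}
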
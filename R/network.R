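# Bipartite community-community virus-host network. Every protospacer match
# connects the community that contributed the spacer (spacerome node) to the
# community whose viral contig carries the protospacer (virome node). Edges
# carry three statistics: the total number of spacer-protospacer matches,
# the number of distinct matching spacers (counted at the cluster level so
# identical spacers recovered repeatedly are not double-counted), and the
# number of distinct matched viral contigs (cluster level likewise).

#' Build the community-community interaction network
#'
#' One directed edge per (spacer source, contig source) pair with at least
#' one protospacer match. `total_matches` counts distinct
#' (spacer, contig, site) triples; `n_matching_spacers` counts distinct
#' spacer clusters (raw spacer ids when `spacer_clusters` is `NULL`);
#' `n_matched_contigs` counts distinct contig clusters (raw ids when
#' `contig_clusters` is `NULL`). Per spacer source, the edge(s) with the
#' largest `n_matching_spacers` get `is_max_for_source = TRUE`. Node sizes
#' report the spacer count and viral contig count per sample.
#'
#' @param matches match data.frame from [find_protospacers()].
#' @param spacers spacer data.frame (maps spacer to source sample; spacers
#'   recovered from the viral size fraction are attributed to their sample's
#'   spacerome node).
#' @param contigs viral contig data.frame (maps contig to source sample).
#' @param spacer_clusters optional cluster data.frame from
#'   [cluster_sequences()] over the spacers.
#' @param contig_clusters optional cluster data.frame over the contigs.
#' @return list with `edges` (CommunityEdge data.frame) and `node_sizes`
#'   (`sample`, `kind`, `size`).
#' @export
build_network <- function(matches, spacers, contigs,
                          spacer_clusters = NULL, contig_clusters = NULL) {
  node_sizes <- rbind(
    if (nrow(spacers)) data.frame(sample = sort(unique(spacers$sample)),
                                  kind = "spacerome", stringsAsFactors = FALSE),
    if (nrow(contigs)) data.frame(sample = sort(unique(contigs$sample)),
                                  kind = "virome", stringsAsFactors = FALSE))
  if (!is.null(node_sizes) && nrow(node_sizes)) {
    node_sizes$size <- ifelse(
      node_sizes$kind == "spacerome",
      as.integer(table(spacers$sample)[node_sizes$sample]),
      as.integer(table(contigs$sample)[node_sizes$sample]))
  }
  empty <- data.frame(spacer_source = character(0), contig_source = character(0),
                      total_matches = integer(0), n_matching_spacers = integer(0),
                      n_matched_contigs = integer(0), is_max_for_source = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(matches) == 0L) return(list(edges = empty, node_sizes = node_sizes))
  sp_sample <- spacers$sample[match(matches$spacer_id, spacers$spacer_id)]
  if (anyNA(sp_sample))
    .stopf("spacer(s) without a source sample: %s",
           paste(unique(matches$spacer_id[is.na(sp_sample)]), collapse = ", "))
  co_sample <- contigs$sample[match(matches$contig_id, contigs$id)]
  if (anyNA(co_sample))
    .stopf("contig(s) without a source sample: %s",
           paste(unique(matches$contig_id[is.na(co_sample)]), collapse = ", "))
  sp_unit <- if (is.null(spacer_clusters)) matches$spacer_id else {
    cl <- spacer_clusters$representative_id[match(matches$spacer_id,
                                                  spacer_clusters$member_id)]
    ifelse(is.na(cl), matches$spacer_id, cl)
  }
  co_unit <- if (is.null(contig_clusters)) matches$contig_id else {
    cl <- contig_clusters$representative_id[match(matches$contig_id,
                                                  contig_clusters$member_id)]
    ifelse(is.na(cl), matches$contig_id, cl)
  }
  site_key <- paste(matches$spacer_id, matches$contig_id, matches$strand,
                    matches$contig_start, matches$contig_end, sep = "\r")
  grp <- paste(sp_sample, co_sample, sep = "\r")
  edges <- do.call(rbind, lapply(split(seq_len(nrow(matches)), grp), function(i) {
    data.frame(spacer_source = sp_sample[i[1L]], contig_source = co_sample[i[1L]],
               total_matches = length(unique(site_key[i])),
               n_matching_spacers = length(unique(sp_unit[i])),
               n_matched_contigs = length(unique(co_unit[i])),
               stringsAsFactors = FALSE)
  }))
  edges <- edges[order(edges$spacer_source, edges$contig_source), , drop = FALSE]
  mx <- tapply(edges$n_matching_spacers, edges$spacer_source, max)
  edges$is_max_for_source <- edges$n_matching_spacers ==
    as.numeric(mx[edges$spacer_source])
  rownames(edges) <- NULL
  list(edges = edges, node_sizes = node_sizes)
}

#' Intra- versus inter-community interaction summary
#'
#' For each spacer source with any edge: the total matches of its
#' within-community edge, the best total matches over edges to other
#' communities, and whether the intra edge strictly dominates. Sources
#' without edges are excluded (and logged).
#'
#' @param edges edge data.frame from [build_network()].
#' @return list with `table` (per-source summary) and
#'   `fraction_intra_dominant`.
#' @export
intra_vs_inter_summary <- function(edges) {
  if (nrow(edges) == 0L)
    return(list(table = data.frame(spacer_source = character(0),
                                   intra_matches = integer(0),
                                   best_inter_matches = integer(0),
                                   best_inter_target = character(0),
                                   intra_dominant = logical(0),
                                   stringsAsFactors = FALSE),
                fraction_intra_dominant = NaN))
  out <- do.call(rbind, lapply(split(edges, edges$spacer_source), function(e) {
    src <- e$spacer_source[1L]
    intra <- e$total_matches[e$contig_source == src]
    intra <- if (length(intra)) intra[1L] else 0L
    inter <- e[e$contig_source != src, , drop = FALSE]
    if (nrow(inter)) {
      k <- which.max(inter$total_matches)
      bi <- inter$total_matches[k]; bt <- inter$contig_source[k]
    } else {
      bi <- 0L; bt <- NA_character_
    }
    data.frame(spacer_source = src, intra_matches = intra,
               best_inter_matches = bi, best_inter_target = bt,
               intra_dominant = intra > bi, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  list(table = out, fraction_intra_dominant = mean(out$intra_dominant))
}

#' Per-community dossier for one viral contig cluster
#'
#' For a contig cluster of interest, summarises per spacer-source community:
#' the distinct matching spacers, their arrays and Cas types, positions
#' within arrays (via [array_position_profile()]), and a PAM census of the
#' flanking dinucleotides (deduplicated per spacer, so identical copies of a
#' site across cluster members count once). Depth fold-changes across the
#' samples carrying cluster members are appended via [depth_fold_change()].
#'
#' @param member_ids contig ids forming the cluster of interest.
#' @param matches match data.frame from [find_protospacers()].
#' @param spacers spacer data.frame.
#' @param contigs contig data.frame with `mean_depth` set for the members.
#' @return list with `members`, `per_community` (named list), and
#'   `depth_fold_changes` (`NULL` when fewer than two samples carry the
#'   cluster).
#' @export
contig_interaction_report <- function(member_ids, matches, spacers, contigs) {
  m <- matches[matches$contig_id %in% member_ids, , drop = FALSE]
  sp <- spacers[match(m$spacer_id, spacers$spacer_id), , drop = FALSE]
  per_comm <- lapply(split(seq_len(nrow(m)), sp$sample), function(i) {
    mm <- m[i, , drop = FALSE]
    ss <- sp[i, , drop = FALSE]
    uniq <- !duplicated(paste(mm$spacer_id, mm$flank_5p, mm$flank_3p, sep = "\r"))
    list(n_matching_spacers = length(unique(mm$spacer_id)),
         arrays = sort(unique(ss$array_id)),
         cas_types = sort(unique(stats::na.omit(ss$cas_type))),
         positions = array_position_profile(mm, spacers),
         pam_census_5p = table(mm$flank_5p[uniq]),
         pam_census_3p = table(mm$flank_3p[uniq]),
         total_matches = nrow(mm))
  })
  mem <- contigs[contigs$id %in% member_ids, , drop = FALSE]
  dfc <- NULL
  if (length(unique(mem$sample)) >= 2L && !anyNA(mem$mean_depth)) {
    depths <- tapply(mem$mean_depth, mem$sample, mean)
    dfc <- depth_fold_change(stats::setNames(as.numeric(depths), names(depths)))
  }
  list(members = sort(member_ids), per_community = per_comm,
       depth_fold_changes = dfc)
}
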
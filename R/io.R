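# Readers and writers for every external format the pipeline touches.
# Coordinates are 1-based inclusive everywhere (GFF/BLAST convention).

#' Read assembled contigs from FASTA
#'
#' Sequences are uppercased and U is mapped to T. With `iupac_strict = TRUE`
#' only A/C/G/T/N are accepted; otherwise any IUPAC ambiguity code is kept.
#' Duplicate record ids are rejected.
#'
#' @param path FASTA file.
#' @param sample sample label attached to every contig.
#' @param fraction `"bacterial"` or `"viral"` size fraction.
#' @param iupac_strict reject ambiguity codes other than N.
#' @return data.frame with columns `id`, `sample`, `fraction`, `sequence`,
#'   `length`, `mean_depth` (NA until [read_depth_table()] fills it).
#' @export
read_contig_fasta <- function(path, sample = "sample", fraction = c("bacterial", "viral"),
                              iupac_strict = TRUE) {
  fraction <- match.arg(fraction)
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) == 0L || !hdr[[1L]])
    .stopf("%s: line 1: expected FASTA header ('>')", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (any(ids == "")) {
    bad <- which(hdr)[ids == ""][1L]
    .stopf("%s: line %d: empty FASTA header", path, bad)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    .stopf("%s: duplicate contig id '%s'", path, dup)
  }
  rec <- cumsum(hdr)
  seqlines <- lines[!hdr]
  seqs <- vapply(split(seqlines, rec[!hdr])[as.character(seq_along(ids))],
                 paste, character(1), collapse = "")
  seqs[is.na(seqs)] <- ""
  empty <- which(nchar(seqs) == 0L | !nzchar(gsub("\\s", "", seqs)))
  if (length(empty)) {
    .stopf("%s: line %d: record '%s' has an empty sequence",
           path, which(hdr)[empty[1L]], ids[empty[1L]])
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  seqs <- chartr("U", "T", seqs)
  allowed <- if (iupac_strict) .STRICT else .IUPAC
  has_bad <- grepl(sprintf("[^%s]", paste(allowed, collapse = "")), seqs)
  if (any(has_bad)) {
    i <- which(has_bad)[1L]
    .stopf("%s: line %d: record '%s' contains non-%s character(s)",
           path, which(hdr)[i] + 1L, ids[i], if (iupac_strict) "ACGTN" else "IUPAC")
  }
  # round-trip through DNAStringSet guarantees a valid nucleotide alphabet
  seqs <- as.character(Biostrings::DNAStringSet(seqs))
  .log("read %d contigs from %s", length(ids), path)
  data.frame(id = ids, sample = sample, fraction = fraction,
             sequence = unname(seqs), length = nchar(seqs),
             mean_depth = NA_real_, stringsAsFactors = FALSE)
}

#' Write contigs to FASTA
#'
#' @param contigs contig data.frame (see [read_contig_fasta()]).
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(contigs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(contigs$sequence)
  names(ss) <- contigs$id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read ORF coordinates from GFF3
#'
#' Keeps `CDS` features, orders them per contig by start (ties by end) and
#' assigns the 0-based ordinal `orf_index` the defense-calling gap rule
#' operates on.
#'
#' @param path GFF3 file (seqid/source/type/start/end/score/strand columns).
#' @return data.frame with `contig_id`, `orf_index`, `start`, `end`, `strand`.
#' @export
read_orf_gff <- function(path) {
  if (!file.exists(path)) .stopf("GFF file not found: %s", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "CDS", , drop = FALSE]
  orfs <- data.frame(contig_id = as.character(g$seqid),
                     start = as.integer(g$start), end = as.integer(g$end),
                     strand = as.character(g$strand), stringsAsFactors = FALSE)
  if (any(orfs$start > orfs$end)) .stopf("%s: CDS with start > end", path)
  orfs <- orfs[order(orfs$contig_id, orfs$start, orfs$end), , drop = FALSE]
  orfs$orf_index <- as.integer(stats::ave(orfs$start, orfs$contig_id, FUN = seq_along) - 1)
  rownames(orfs) <- NULL
  .log("read %d ORFs on %d contigs from %s", nrow(orfs),
       length(unique(orfs$contig_id)), path)
  orfs[, c("contig_id", "orf_index", "start", "end", "strand")]
}

#' Write ORF coordinates as GFF3
#'
#' @param orfs ORF data.frame (see [read_orf_gff()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orf_gff <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tphagenet\tCDS\t%d\t%d\t.\t%s\t0\tID=%s_orf%d",
                   orfs$contig_id, orfs$start, orfs$end, orfs$strand,
                   orfs$contig_id, orfs$orf_index)
  writeLines(lines, con)
  invisible(path)
}

#' Read a profile-to-system/gene mapping table
#'
#' Sidecar TSV resolving HMM profile ids to the defense system and gene they
#' represent (columns `profile`, `system`, `gene`).
#'
#' @param path TSV file with a header.
#' @return data.frame with `profile_id`, `system_name`, `gene_name`.
#' @export
read_profile_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("profile", "system", "gene")
  if (!all(need %in% names(m)))
    .stopf("%s: mapping table needs columns %s", path, paste(need, collapse = ", "))
  if (anyDuplicated(m$profile)) .stopf("%s: duplicate profile id in mapping", path)
  if (any(!nzchar(m$system))) .stopf("%s: empty system name in mapping", path)
  data.frame(profile_id = m$profile, system_name = m$system,
             gene_name = m$gene, stringsAsFactors = FALSE)
}

#' Read a per-ORF profile hit table
#'
#' hmmsearch-tblout-like TSV with header columns `contig`, `orf_index`,
#' `profile`, `evalue`. Hits whose profile is absent from `mapping` are
#' excluded with a warning carrying the excluded count.
#'
#' @param path TSV file.
#' @param mapping mapping data.frame from [read_profile_map()].
#' @return data.frame with `contig_id`, `orf_index`, `profile_id`,
#'   `system_name`, `gene_name`, `evalue`.
#' @export
read_hit_table <- function(path, mapping) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(evalue = "character"))
  if (nrow(h) == 0L) {
    return(data.frame(contig_id = character(0), orf_index = integer(0),
                      profile_id = character(0), system_name = character(0),
                      gene_name = character(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  need <- c("contig", "orf_index", "profile", "evalue")
  if (!all(need %in% names(h)))
    .stopf("%s: hit table needs columns %s", path, paste(need, collapse = ", "))
  ev <- suppressWarnings(as.numeric(h$evalue))
  if (anyNA(ev)) {
    bad <- which(is.na(ev))[1L]
    .stopf("%s: row %d: non-numeric E-value '%s'", path, bad, h$evalue[bad])
  }
  if (any(ev <= 0)) .stopf("%s: non-positive E-value", path)
  key <- paste(h$contig, h$orf_index, h$profile, sep = "\r")
  if (anyDuplicated(key)) .stopf("%s: duplicate (contig, orf, profile) hit row", path)
  h$evalue <- ev
  out <- annotate_hits(h, mapping, context = path)
  .log("read %d profile hits from %s (%d excluded)", nrow(out), path, nrow(h) - nrow(out))
  out
}

#' Resolve raw hit records through a profile mapping
#'
#' Turns raw hit rows (`contig`, `orf_index`, `profile`, `evalue`) — as read
#' from a hit TSV or produced by [generate_scenario()] — into annotated hits
#' carrying the system and gene of each profile. Hits on unmapped profiles
#' are excluded with a warning.
#'
#' @param hits raw hit data.frame.
#' @param mapping mapping data.frame from [read_profile_map()].
#' @param context label used in messages.
#' @return annotated hit data.frame (see [read_hit_table()]).
#' @export
annotate_hits <- function(hits, mapping, context = "hits") {
  if ("profile" %in% names(mapping) && !"profile_id" %in% names(mapping)) {
    mapping <- data.frame(profile_id = mapping$profile,
                          system_name = mapping$system,
                          gene_name = mapping$gene, stringsAsFactors = FALSE)
  }
  idx <- match(hits$profile, mapping$profile_id)
  unknown <- is.na(idx)
  if (any(unknown)) {
    .warnf("%s: %d hit(s) with unknown profile excluded (%s)", context,
           sum(unknown), paste(unique(hits$profile[unknown]), collapse = ", "))
  }
  out <- data.frame(contig_id = hits$contig, orf_index = as.integer(hits$orf_index),
                    profile_id = hits$profile,
                    system_name = mapping$system_name[idx],
                    gene_name = mapping$gene_name[idx],
                    evalue = hits$evalue,
                    stringsAsFactors = FALSE)[!unknown, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a profile hit table
#' @param hits hit data.frame (columns `contig_id`, `orf_index`, `profile_id`, `evalue`).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(contig = hits$contig_id, orf_index = hits$orf_index,
                    profile = hits$profile_id,
                    evalue = formatC(hits$evalue, format = "e", digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fill per-contig mean coverage depth from a samtools-depth-like table
#'
#' Headerless 3-column TSV `(contig, 1-based position, depth)`. Positions
#' absent from the table count as depth 0; the denominator is always the full
#' contig length, reproducing `samtools depth`-then-average-over-length
#' semantics. Contigs with no rows get mean depth 0.
#'
#' @param path depth TSV.
#' @param contigs contig data.frame.
#' @return `contigs` with `mean_depth` set.
#' @export
read_depth_table <- function(path, contigs) {
  d <- tryCatch(utils::read.delim(path, header = FALSE,
                                  col.names = c("contig", "pos", "depth"),
                                  stringsAsFactors = FALSE),
                error = function(e) data.frame(contig = character(0),
                                               pos = integer(0), depth = numeric(0)))
  contigs$mean_depth <- 0
  if (nrow(d)) {
    known <- d$contig %in% contigs$id
    if (any(!known))
      .warnf("%s: %d depth row(s) for unknown contig(s) ignored", path, sum(!known))
    d <- d[known, , drop = FALSE]
    len <- contigs$length[match(d$contig, contigs$id)]
    if (any(d$pos < 1L | d$pos > len)) {
      bad <- which(d$pos < 1L | d$pos > len)[1L]
      .stopf("%s: position %d outside contig '%s' (length %d)",
             path, d$pos[bad], d$contig[bad], len[bad])
    }
    sums <- tapply(d$depth, d$contig, sum)
    i <- match(names(sums), contigs$id)
    contigs$mean_depth[i] <- as.numeric(sums) / contigs$length[i]
  }
  contigs
}

#' Write a per-base depth table
#' @param depth data.frame with columns `contig`, `pos`, `depth`; zero-depth
#'   rows may be omitted.
#' @param path output TSV (headerless).
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CRISPR spacer table
#'
#' CRISPRCasTyper-like TSV with header columns `spacer_id`, `sample`,
#' `fraction`, `array_id`, `position_in_array` (0 = array start as reported
#' by the detector), `sequence`, and optionally `cas_type` and
#' `array_contig`. Sequences are uppercased; lengths outside the sanity
#' bounds are rejected.
#'
#' @param path TSV file.
#' @param min_len,max_len spacer length sanity bounds.
#' @return spacer data.frame.
#' @export
read_spacer_table <- function(path, min_len = 15L, max_len = 80L) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spacer_id", "sample", "fraction", "array_id", "position_in_array", "sequence")
  if (!all(need %in% names(s)))
    .stopf("%s: spacer table needs columns %s", path, paste(need, collapse = ", "))
  if (anyDuplicated(s$spacer_id)) .stopf("%s: duplicate spacer id", path)
  s$sequence <- toupper(s$sequence)
  len <- nchar(s$sequence)
  if (any(len < min_len | len > max_len)) {
    bad <- which(len < min_len | len > max_len)[1L]
    .stopf("%s: spacer '%s' length %d outside [%d, %d]",
           path, s$spacer_id[bad], len[bad], min_len, max_len)
  }
  if (!"cas_type" %in% names(s)) s$cas_type <- NA_character_
  if (!"array_contig" %in% names(s)) s$array_contig <- NA_character_
  s$position_in_array <- as.integer(s$position_in_array)
  .log("read %d spacers in %d arrays from %s", nrow(s),
       length(unique(s$array_id)), path)
  s
}

#' Write a CRISPR spacer table
#' @param spacers spacer data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_spacer_table <- function(spacers, path) {
  utils::write.table(spacers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read viral-caller verdict tables
#'
#' CSV with header `contig,tool,is_viral` (one row per contig and tool;
#' `is_viral` parsed as logical). Several files are concatenated.
#'
#' @param paths one or more CSV files.
#' @return data.frame with `contig_id`, `tool`, `is_viral`.
#' @export
read_verdict_table <- function(paths) {
  v <- do.call(rbind, lapply(paths, function(p) {
    x <- utils::read.csv(p, stringsAsFactors = FALSE)
    need <- c("contig", "tool", "is_viral")
    if (!all(need %in% names(x)))
      .stopf("%s: verdict table needs columns %s", p, paste(need, collapse = ", "))
    x
  }))
  data.frame(contig_id = v$contig, tool = v$tool,
             is_viral = as.logical(v$is_viral), stringsAsFactors = FALSE)
}

#' Write a viral-caller verdict table
#' @param verdicts data.frame with `contig_id`, `tool`, `is_viral`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_verdict_table <- function(verdicts, path) {
  out <- data.frame(contig = verdicts$contig_id, tool = verdicts$tool,
                    is_viral = verdicts$is_viral)
  utils::write.csv(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the community-community network as GraphML (+ TSV twin)
#'
#' Nodes are bipartite: every community appears as a `spacerome` node (spacer
#' source) and/or a `virome` node (viral-contig source), distinguished by the
#' `source_kind` attribute. Edges carry the three interaction statistics.
#'
#' @param edges edge data.frame from [build_network()].
#' @param path output `.graphml` path; a `.tsv` twin is written alongside.
#' @param node_sizes optional data.frame with `sample`, `kind`
#'   (`spacerome`/`virome`), `size` used as node attributes.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(edges, path, node_sizes = NULL) {
  sp <- unique(edges$spacer_source)
  vi <- unique(edges$contig_source)
  nodes <- data.frame(
    name = c(sprintf("spacerome:%s", sp), sprintf("virome:%s", vi)),
    sample = c(sp, vi),
    source_kind = c(rep("spacerome", length(sp)), rep("virome", length(vi))),
    stringsAsFactors = FALSE)
  if (!is.null(node_sizes)) {
    key <- paste(node_sizes$kind, node_sizes$sample, sep = ":")
    nodes$size <- node_sizes$size[match(paste(nodes$source_kind, nodes$sample, sep = ":"), key)]
  }
  el <- if (nrow(edges)) {
    data.frame(from = sprintf("spacerome:%s", edges$spacer_source),
               to = sprintf("virome:%s", edges$contig_source),
               total_matches = edges$total_matches,
               n_matching_spacers = edges$n_matching_spacers,
               n_matched_contigs = edges$n_matched_contigs,
               is_max_for_source = edges$is_max_for_source,
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0))
  }
  g <- igraph::graph_from_data_frame(el, directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  tsv <- sub("\\.graphml$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  utils::write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network GraphML back into an edge table
#'
#' Inverse of [write_network_graphml()]; used for round-trip checks.
#'
#' @param path `.graphml` file.
#' @return edge data.frame with the three interaction statistics.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) == 0L) {
    return(data.frame(spacer_source = character(0), contig_source = character(0),
                      total_matches = integer(0), n_matching_spacers = integer(0),
                      n_matched_contigs = integer(0), is_max_for_source = logical(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(spacer_source = sub("^spacerome:", "", el$from),
             contig_source = sub("^virome:", "", el$to),
             total_matches = as.integer(el$total_matches),
             n_matching_spacers = as.integer(el$n_matching_spacers),
             n_matched_contigs = as.integer(el$n_matched_contigs),
             is_max_for_source = as.logical(el$is_max_for_source),
             stringsAsFactors = FALSE)
}
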
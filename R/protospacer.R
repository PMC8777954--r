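# Short-query protospacer search: seed-and-extend in the blastn style.
# Every exact word (default 8 nt) shared between a spacer (either strand)
# and a contig seeds an ungapped extension on that diagonal; the emitted
# local alignment is the maximum-scoring segment under a +2/-3
# match/mismatch score (Kadane on the diagonal), filtered by query coverage
# and a Karlin-Altschul E-value. Low-complexity masking is deliberately
# absent (dust off), as spacers are short and masking would cost recall.

# Karlin-Altschul lambda for uniform base composition: solves
# sum_ij p_i p_j exp(lambda * s_ij) = 1, i.e.
# (1/4) e^(reward*lambda) + (3/4) e^(penalty*lambda) = 1
.ka_lambda <- function(reward = 2, penalty = -3) {
  f <- function(l) 0.25 * exp(reward * l) + 0.75 * exp(penalty * l) - 1
  stats::uniroot(f, c(1e-6, 5), tol = 1e-12)$root
}

# K is taken from the standard ungapped blastn table for +2/-3 (0.41); only
# the order of magnitude matters at spacer-scale scores.
.KA_K <- 0.41

# all overlapping words of a sequence, in position order
.words <- function(seq, word_size) {
  n <- nchar(seq)
  if (n < word_size) return(character(0))
  substring(seq, 1:(n - word_size + 1), word_size:n)
}

# seed diagonals of query q against precomputed contig words; returns unique
# diagonal offsets d such that q[i] aligns contig[d+i]
.seed_diagonals <- function(q, cwords, word_size) {
  qwords <- .words(q, word_size)
  if (!length(qwords) || !length(cwords)) return(integer(0))
  hits <- which(cwords %in% qwords)
  if (!length(hits)) return(integer(0))
  # map each contig word position to the query word positions sharing it
  idx <- split(seq_along(qwords), qwords)
  d <- unlist(lapply(hits, function(j) j - idx[[cwords[j]]]), use.names = FALSE)
  sort(unique(d))
}

# best ungapped segment of query q on diagonal d (q[i] vs contig[d+i]);
# returns NULL or list(score, q_start, q_end, matches)
.extend_diagonal <- function(qc, cc, d, reward, penalty) {
  nq <- length(qc)
  nc <- length(cc)
  i0 <- max(1L, 1L - d)           # first query pos with a partner
  i1 <- min(nq, nc - d)           # last query pos with a partner
  if (i0 > i1) return(NULL)
  is_match <- qc[i0:i1] == cc[(i0:i1) + d]
  sc <- ifelse(is_match, reward, penalty)
  # Kadane with segment tracking
  best <- 0; best_s <- 0L; best_e <- -1L
  cur <- 0; cur_s <- 1L
  for (k in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[k]; cur_s <- k } else cur <- cur + sc[k]
    if (cur > best) { best <- cur; best_s <- cur_s; best_e <- k }
  }
  if (best_e < best_s) return(NULL)
  seg <- best_s:best_e
  list(score = best,
       q_start = i0 + best_s - 1L, q_end = i0 + best_e - 1L,
       matches = sum(is_match[seg]))
}

#' Find protospacers: seed-and-extend search of spacers against contigs
#'
#' Both spacer strands are searched against the forward contig; word seeds
#' (`word_size`) trigger an ungapped extension maximising a
#' `reward`/`penalty` score, and the best segment per diagonal is kept.
#' Matches must cover at least `qcov` of the spacer and reach E-value
#' `<= max_evalue` (Karlin-Altschul, search space = spacer length x contig
#' length). Coordinates are 1-based inclusive on the forward contig strand;
#' flanking dinucleotides are reported in protospacer orientation via
#' [extract_pam()]. Matches inside the spacer's own source array region are
#' suppressed when the spacer table carries `array_contig` (and optionally
#' `array_start`/`array_end`) columns.
#'
#' @param spacers spacer data.frame (see [read_spacer_table()]).
#' @param contigs contig data.frame (id, sample, sequence).
#' @param word_size exact-word seed length.
#' @param qcov minimum aligned fraction of the spacer.
#' @param max_evalue E-value cutoff.
#' @param reward,penalty match/mismatch scores.
#' @return data.frame of matches: `spacer_id`, `contig_id`, `contig_sample`,
#'   `strand`, `contig_start`, `contig_end`, `spacer_start`, `spacer_end`,
#'   `aligned_len`, `mismatches`, `identity_fraction`,
#'   `aligned_query_fraction`, `score`, `evalue`, `flank_5p`, `flank_3p`.
#' @export
find_protospacers <- function(spacers, contigs, word_size = 8L, qcov = 0.95,
                              max_evalue = 10, reward = 2, penalty = -3) {
  lambda <- .ka_lambda(reward, penalty)
  has_arr_contig <- "array_contig" %in% names(spacers)
  contig_chars <- lapply(contigs$sequence, .chars)
  names(contig_chars) <- contigs$id
  contig_words <- lapply(contigs$sequence, .words, word_size = word_size)
  res <- vector("list", 0L)
  n_self <- 0L
  for (si in seq_len(nrow(spacers))) {
    sp <- spacers[si, ]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") sp$sequence else revcomp(sp$sequence)
      qc <- .chars(q)
      nq <- length(qc)
      for (ci in seq_len(nrow(contigs))) {
        diags <- .seed_diagonals(q, contig_words[[ci]], word_size)
        if (!length(diags)) next
        cc <- contig_chars[[ci]]
        for (d in diags) {
          ext <- .extend_diagonal(qc, cc, d, reward, penalty)
          if (is.null(ext)) next
          alen <- ext$q_end - ext$q_start + 1L
          if (alen / nq < qcov) next
          ev <- .KA_K * nq * length(cc) * exp(-lambda * ext$score)
          if (ev > max_evalue) next
          cstart <- ext$q_start + d
          cend <- ext$q_end + d
          # report spacer coordinates on the original (forward) spacer
          if (strand == "+") {
            ss <- ext$q_start; se <- ext$q_end
          } else {
            ss <- nq - ext$q_end + 1L; se <- nq - ext$q_start + 1L
          }
          if (has_arr_contig && !is.na(sp$array_contig) &&
              identical(sp$array_contig, contigs$id[ci])) {
            a_s <- if ("array_start" %in% names(sp)) sp$array_start else NA
            a_e <- if ("array_end" %in% names(sp)) sp$array_end else NA
            if (is.na(a_s) || (cstart <= a_e && cend >= a_s)) {
              n_self <- n_self + 1L
              next
            }
          }
          res[[length(res) + 1L]] <- data.frame(
            spacer_id = sp$spacer_id, contig_id = contigs$id[ci],
            contig_sample = contigs$sample[ci], strand = strand,
            contig_start = cstart, contig_end = cend,
            spacer_start = ss, spacer_end = se,
            aligned_len = alen, mismatches = alen - ext$matches,
            identity_fraction = ext$matches / alen,
            aligned_query_fraction = alen / nq,
            score = ext$score, evalue = ev, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (n_self > 0L) .log("%d self-match(es) to source array contigs suppressed", n_self)
  if (!length(res)) {
    out <- data.frame(spacer_id = character(0), contig_id = character(0),
                      contig_sample = character(0), strand = character(0),
                      contig_start = integer(0), contig_end = integer(0),
                      spacer_start = integer(0), spacer_end = integer(0),
                      aligned_len = integer(0), mismatches = integer(0),
                      identity_fraction = numeric(0),
                      aligned_query_fraction = numeric(0),
                      score = numeric(0), evalue = numeric(0),
                      flank_5p = character(0), flank_3p = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, res)
  # overlapping seeds on one diagonal yield one segment each; distinct
  # diagonals can still converge on the same site -> dedupe
  key <- paste(out$spacer_id, out$contig_id, out$strand,
               out$contig_start, out$contig_end, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$spacer_id, out$contig_id, out$contig_start), , drop = FALSE]
  rownames(out) <- NULL
  pam <- extract_pam(out, contigs)
  out$flank_5p <- pam$flank_5p
  out$flank_3p <- pam$flank_3p
  out
}

#' Extract flanking dinucleotides (PAM candidates) for protospacer matches
#'
#' Reports the two dinucleotides immediately flanking each protospacer, in
#' protospacer orientation: for minus-strand matches the flanks are taken
#' from the reverse complement of the contig. Positions beyond the contig
#' ends are padded with `N`. No claim is made about which side is the PAM;
#' for type I-F systems the classical CC motif sits 5' of the protospacer.
#'
#' @param matches match data.frame (needs `contig_id`, `strand`,
#'   `contig_start`, `contig_end`).
#' @param contigs contig data.frame.
#' @return data.frame with `flank_5p`, `flank_3p` per match.
#' @export
extract_pam <- function(matches, contigs) {
  n <- nrow(matches)
  f5 <- character(n); f3 <- character(n)
  seqs <- contigs$sequence[match(matches$contig_id, contigs$id)]
  if (anyNA(seqs) && n > 0L)
    .stopf("match on unknown contig: %s",
           paste(unique(matches$contig_id[is.na(seqs)]), collapse = ", "))
  pad_sub <- function(seq, from, to) {
    len <- nchar(seq)
    pos <- from:to
    ch <- rep("N", length(pos))
    ok <- pos >= 1L & pos <= len
    if (any(ok)) ch[ok] <- .chars(substr(seq, max(1L, from), min(len, to)))
    paste(ch, collapse = "")
  }
  for (i in seq_len(n)) {
    left <- pad_sub(seqs[i], matches$contig_start[i] - 2L, matches$contig_start[i] - 1L)
    right <- pad_sub(seqs[i], matches$contig_end[i] + 1L, matches$contig_end[i] + 2L)
    if (matches$strand[i] == "+") {
      f5[i] <- left; f3[i] <- right
    } else {
      f5[i] <- revcomp(right); f3[i] <- revcomp(left)
    }
  }
  data.frame(flank_5p = f5, flank_3p = f3, stringsAsFactors = FALSE)
}

#' Profile match positions within CRISPR arrays
#'
#' For each array, lists the in-array positions whose spacers have at least
#' one protospacer match, the contigs they match, and whether the matched
#' positions fall in two or more runs separated by at least one unmatched
#' spacer (a bimodal beginning-and-end pattern suggests distinct episodes of
#' acquisition against the same target).
#'
#' @param matches match data.frame from [find_protospacers()].
#' @param spacers spacer data.frame.
#' @return data.frame with one row per array that has any match:
#'   `array_id`, `n_spacers`, `matched_positions` (comma-joined),
#'   `matched_contigs` (comma-joined unique), `n_runs`, `multi_run`.
#' @export
array_position_profile <- function(matches, spacers) {
  empty <- data.frame(array_id = character(0), n_spacers = integer(0),
                      matched_positions = character(0),
                      matched_contigs = character(0),
                      n_runs = integer(0), multi_run = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(matches) == 0L) return(empty)
  sp <- spacers[match(matches$spacer_id, spacers$spacer_id), , drop = FALSE]
  if (anyNA(sp$spacer_id))
    .stopf("match for unknown spacer: %s",
           paste(unique(matches$spacer_id[is.na(sp$spacer_id)]), collapse = ", "))
  d <- data.frame(array_id = sp$array_id, pos = sp$position_in_array,
                  contig_id = matches$contig_id, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(d, d$array_id), function(x) {
    arr <- x$array_id[1L]
    n_sp <- sum(spacers$array_id == arr)
    pos <- sort(unique(x$pos))
    # runs of consecutive matched positions
    n_runs <- if (length(pos)) sum(c(TRUE, diff(pos) > 1L)) else 0L
    data.frame(array_id = arr, n_spacers = n_sp,
               matched_positions = paste(pos, collapse = ","),
               matched_contigs = paste(sort(unique(x$contig_id)), collapse = ","),
               n_runs = n_runs, multi_run = n_runs >= 2L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
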
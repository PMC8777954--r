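# Synthetic multi-community metagenomes with planted ground truth.
#
# The generator emulates the statistical structure the downstream stages
# assume: per community, assembled contigs in two size fractions, ORF
# coordinate tables, per-ORF profile hit tables with planted defense-system
# operons plus spurious noise hits, per-base depth tables, CRISPR spacer
# tables, pseudo-viral-caller verdicts, and protospacer sites planted into
# viral contigs with chosen flanking PAMs and mutation loads. Everything
# planted is recorded in a truth manifest; a fixed seed makes the whole
# fixture byte-identical across runs.

#' Scenario configuration for the synthetic-community generator
#'
#' Defaults describe a small four-community holobiont-style study: a handful
#' of multi-kb contigs per community, about one ORF per kb, 32-nt spacers in
#' a few arrays per community, and uniform-random background sequence
#' (low-complexity structure is irrelevant downstream because the matcher
#' runs without dust masking).
#'
#' @param communities character vector of community (sample) labels.
#' @param n_contigs bacterial contigs per community.
#' @param contig_length length range (uniform draw) for bacterial contigs.
#' @param orf_density ORFs per kb.
#' @param n_viral_contigs viral-fraction contigs per community.
#' @param viral_contig_length length range for viral contigs.
#' @param planted_systems data.frame with `community`, `system_name`,
#'   `n_genes` (one row per planted system), or `NULL`.
#' @param gene_gap_max maximum intervening ORFs drawn between consecutive
#'   planted system genes (kept below the calling gap of 5).
#' @param noise_hit_rate expected spurious profile hits per 100 ORFs.
#' @param n_arrays,spacers_per_array,spacer_length CRISPR array layout.
#' @param cas_type Cas subtype label attached to generated arrays.
#' @param planting data.frame with `spacer_source`, `contig_source`,
#'   `n_sites`, `mismatches`, `pam_5p`, `pam_3p`, `strand`, and optionally
#'   `target_contig` (id or shared-contig prefix) and `positions`
#'   (comma-joined in-array positions of the source spacers), or `NULL`.
#' @param shared_contigs list of `list(prefix =, samples =, length =,
#'   depths = named numeric)` entries: one sequence copied identically into
#'   the viral fraction of several communities (for dereplication/sharing
#'   and fold-change scenarios), or `NULL`.
#' @param depth_model `"constant"` (every position at the drawn mean) or
#'   `"poisson"` (per-position Poisson counts; zero rows omitted as
#'   `samtools depth` does).
#' @param depth_range integer range for per-contig mean depth draws.
#' @param n_reads mapped reads per community (the `N` of the normalization
#'   formula).
#' @param n_decoy_contigs non-viral decoy contigs in each viral fraction.
#' @param tool_sensitivity probability a pseudo-caller recognises a true
#'   viral contig.
#' @param tool_fpr probability a pseudo-caller calls a decoy viral.
#' @param preserve_seed keep an exact 8-mer and the terminal bases intact
#'   when mutating planted protospacers (see [mutate_protospacer()]).
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(communities = paste0("C", 1:4),
                            n_contigs = 4L,
                            contig_length = c(4000L, 8000L),
                            orf_density = 1.0,
                            n_viral_contigs = 3L,
                            viral_contig_length = c(3000L, 6000L),
                            planted_systems = NULL,
                            gene_gap_max = 3L,
                            noise_hit_rate = 0,
                            n_arrays = 2L,
                            spacers_per_array = 8L,
                            spacer_length = 32L,
                            cas_type = "I-F",
                            planting = NULL,
                            shared_contigs = NULL,
                            depth_model = c("constant", "poisson"),
                            depth_range = c(5L, 60L),
                            n_reads = 1e6,
                            n_decoy_contigs = 1L,
                            tool_sensitivity = 1.0,
                            tool_fpr = 0.1,
                            preserve_seed = TRUE,
                            seed = 1L) {
  depth_model <- match.arg(depth_model)
  stopifnot(n_contigs >= 0, n_viral_contigs >= 0, n_arrays >= 0,
            spacers_per_array >= 0, spacer_length >= 15, noise_hit_rate >= 0,
            n_reads > 0)
  structure(as.list(environment()), class = "scenario_config")
}

#' Mutate a protospacer to a chosen Hamming distance
#'
#' Introduces exactly `k_mismatches` substitutions at positions drawn
#' uniformly without replacement. With `preserve_seed = TRUE` (the default)
#' draws are rejected until (a) at least one exact window of `word_size`
#' consecutive bases survives, so a word-seeded matcher can find the site,
#' and (b) the full-length ungapped alignment of spacer and protospacer is
#' the unique maximum-scoring local segment under the default +2/-3 scores
#' (every proper prefix and suffix of the site scores positive). Without
#' (b), a mismatch near either end makes local alignment trim the site, so
#' the recoverable protospacer would be shorter than the planted one for
#' reasons unrelated to matcher sensitivity. Disable for negative controls.
#'
#' @param spacer nucleotide string.
#' @param k_mismatches Hamming distance to plant (< spacer length).
#' @param preserve_seed keep an intact word and full-site recoverability.
#' @param word_size seed word length to preserve.
#' @param reward,penalty scores used by the recoverability check.
#' @return mutated sequence (same length).
#' @export
mutate_protospacer <- function(spacer, k_mismatches, preserve_seed = TRUE,
                               word_size = 8L, reward = 2, penalty = -3) {
  n <- nchar(spacer)
  stopifnot(k_mismatches >= 0, k_mismatches < n)
  if (k_mismatches == 0L) return(spacer)
  ch <- .chars(spacer)
  repeat {
    pos <- sort(sample.int(n, k_mismatches))
    if (preserve_seed) {
      sc <- rep(reward, n); sc[pos] <- penalty
      cs <- cumsum(sc)
      # full segment uniquely optimal: all proper prefixes/suffixes positive
      if (any(cs[-n] <= 0) || any((cs[n] - cs[-n]) <= 0)) next
      if (k_mismatches <= n - word_size) {
        gaps <- diff(c(0L, pos, n + 1L)) - 1L   # intact run lengths
        if (max(gaps) < word_size) next
      }
    }
    break
  }
  out <- ch
  for (p in pos) out[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(out, collapse = "")
}

#' Disrupt every seed word of a protospacer
#'
#' Negative-control counterpart of [mutate_protospacer()]: places
#' substitutions so that no exact `word_size`-mer survives, defeating any
#' word-seeded matcher while a full local-alignment search still finds the
#' site.
#'
#' @param spacer nucleotide string.
#' @param word_size word length to disrupt.
#' @return mutated sequence.
#' @export
disrupt_protospacer_words <- function(spacer, word_size = 8L) {
  n <- nchar(spacer)
  ch <- .chars(spacer)
  pos <- seq.int(word_size, n, by = word_size)
  if (n - max(pos) >= word_size) pos <- c(pos, n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# evenly tiled non-overlapping ORFs, strand uniform
.place_orfs <- function(contig_id, len, density) {
  n <- max(0L, round(len / 1000 * density))
  if (n == 0L)
    return(data.frame(contig_id = character(0), orf_index = integer(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  seg <- len / n
  start <- floor((seq_len(n) - 1L) * seg) + 11L
  end <- floor(seq_len(n) * seg) - 10L
  data.frame(contig_id = contig_id, orf_index = seq_len(n) - 1L,
             start = as.integer(start), end = as.integer(end),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic scenario with planted ground truth
#'
#' Builds the full fixture set in memory and, when `out_dir` is given,
#' writes per community a contig FASTA per fraction, an ORF GFF3, a hit TSV,
#' a depth TSV, a spacer TSV and three pseudo-tool verdict CSVs, plus a
#' shared profile-mapping TSV and a JSON truth manifest. Planted defense
#' hits draw E-values log-uniform in [1e-50, 1e-15]; noise hits log-uniform
#' in [1e-12, 1e-2].
#'
#' @param config a [scenario_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list with `contigs`, `orfs`, `hits`, `mapping`, `spacers`,
#'   `depth`, `verdicts`, `manifest`, and `files` (paths, when written).
#' @export
generate_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  .with_seed(config$seed, .generate_scenario_impl(config, out_dir))
}

.generate_scenario_impl <- function(config, out_dir) {
  comms <- config$communities
  tools <- c("toolA", "toolB", "toolC")

  ## --- contigs -----------------------------------------------------------
  contig_rows <- list()
  for (cm in comms) {
    nb <- config$n_contigs
    if (nb > 0) {
      len <- sample(config$contig_length[1]:config$contig_length[2], nb, replace = TRUE)
      contig_rows[[length(contig_rows) + 1L]] <- data.frame(
        id = sprintf("%s_b%02d", cm, seq_len(nb)), sample = cm,
        fraction = "bacterial", sequence = random_dna(nb, len),
        stringsAsFactors = FALSE)
    }
    nv <- config$n_viral_contigs
    if (nv > 0) {
      len <- sample(config$viral_contig_length[1]:config$viral_contig_length[2],
                    nv, replace = TRUE)
      contig_rows[[length(contig_rows) + 1L]] <- data.frame(
        id = sprintf("%s_v%02d", cm, seq_len(nv)), sample = cm,
        fraction = "viral", sequence = random_dna(nv, len),
        stringsAsFactors = FALSE)
    }
    nd <- config$n_decoy_contigs
    if (nd > 0) {
      len <- sample(config$viral_contig_length[1]:config$viral_contig_length[2],
                    nd, replace = TRUE)
      contig_rows[[length(contig_rows) + 1L]] <- data.frame(
        id = sprintf("%s_d%02d", cm, seq_len(nd)), sample = cm,
        fraction = "viral", sequence = random_dna(nd, len),
        stringsAsFactors = FALSE)
    }
  }
  contigs <- do.call(rbind, contig_rows)

  # shared viral contigs: one master sequence copied into several samples
  shared_master <- list()
  shared_depth <- list()
  if (!is.null(config$shared_contigs)) {
    for (sc in config$shared_contigs) {
      shared_master[[sc$prefix]] <- random_dna(1L, sc$length)
      for (cm in sc$samples) {
        contigs <- rbind(contigs, data.frame(
          id = sprintf("%s_%s", sc$prefix, cm), sample = cm, fraction = "viral",
          sequence = "", stringsAsFactors = FALSE))
        shared_depth[[sprintf("%s_%s", sc$prefix, cm)]] <-
          unname(sc$depths[[cm]])
      }
    }
  }

  ## --- ORFs on bacterial contigs -----------------------------------------
  bact <- contigs[contigs$fraction == "bacterial", , drop = FALSE]
  orfs <- do.call(rbind, lapply(seq_len(nrow(bact)), function(i)
    .place_orfs(bact$id[i], nchar(bact$sequence[i]), config$orf_density)))
  if (is.null(orfs)) orfs <- .place_orfs("x", 0, 0)

  ## --- planted defense systems -------------------------------------------
  planted_sys <- list()
  hit_rows <- list()
  map_rows <- list()
  next_free <- stats::setNames(rep(0L, nrow(bact)), bact$id)
  if (!is.null(config$planted_systems) && nrow(config$planted_systems)) {
    ps <- config$planted_systems
    rr <- stats::setNames(rep(0L, length(comms)), comms)  # round-robin pointer
    for (k in seq_len(nrow(ps))) {
      cm <- ps$community[k]
      cand <- bact$id[bact$sample == cm]
      if (!length(cand)) .stopf("no bacterial contigs in community '%s'", cm)
      cid <- cand[(rr[cm] %% length(cand)) + 1L]
      rr[cm] <- rr[cm] + 1L
      n_orfs_here <- sum(orfs$contig_id == cid)
      ng <- ps$n_genes[k]
      gaps <- if (ng > 1L) sample(0:config$gene_gap_max, ng - 1L, replace = TRUE)
              else integer(0)
      span <- ng + sum(gaps)
      start_idx <- next_free[cid]
      if (start_idx + span > n_orfs_here)
        .stopf("contig '%s' has too few ORFs (%d) to plant system %d (span %d from %d); enlarge contigs or reduce systems",
               cid, n_orfs_here, k, span, start_idx)
      idx <- start_idx + cumsum(c(0L, gaps + 1L))
      next_free[cid] <- max(idx) + 7L   # > max_gap + 1: systems stay separate
      sysn <- ps$system_name[k]
      profs <- sprintf("%s_p%d", sysn, seq_len(ng))
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        profile = profs, system = sysn, gene = sprintf("%s_gene%d", sysn, seq_len(ng)),
        stringsAsFactors = FALSE)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        contig = cid, orf_index = idx, profile = profs,
        evalue = 10^stats::runif(ng, -50, -15), stringsAsFactors = FALSE)
      planted_sys[[length(planted_sys) + 1L]] <- data.frame(
        community = cm, contig_id = cid, system_name = sysn, n_genes = ng,
        orf_indices = paste(idx, collapse = ","),
        profiles = paste(profs, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  planted_sys <- if (length(planted_sys)) do.call(rbind, planted_sys) else
    data.frame(community = character(0), contig_id = character(0),
               system_name = character(0), n_genes = integer(0),
               orf_indices = character(0), profiles = character(0),
               stringsAsFactors = FALSE)

  # noise-profile pool (mapped, so noise survives parsing and exercises the
  # E-value filter and chaining rules downstream)
  noise_systems <- c("RM", "Abi", "TA", "Gabija", "Septu", "DISARM")
  noise_profiles <- as.vector(vapply(noise_systems, function(s)
    sprintf("%s_nz%d", s, 1:3), character(3)))
  map_rows[[length(map_rows) + 1L]] <- data.frame(
    profile = noise_profiles,
    system = rep(noise_systems, each = 3L),
    gene = sub("_nz", "_gene", noise_profiles), stringsAsFactors = FALSE)
  mapping_tsv <- unique(do.call(rbind, map_rows))

  if (config$noise_hit_rate > 0 && nrow(orfs)) {
    hit_p <- config$noise_hit_rate / 100
    pick <- which(stats::runif(nrow(orfs)) < hit_p)
    if (length(pick)) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        contig = orfs$contig_id[pick], orf_index = orfs$orf_index[pick],
        profile = sample(noise_profiles, length(pick), replace = TRUE),
        evalue = 10^stats::runif(length(pick), -12, -2), stringsAsFactors = FALSE)
    }
  }
  hits_tsv <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(contig = character(0), orf_index = integer(0),
               profile = character(0), evalue = numeric(0), stringsAsFactors = FALSE)
  hits_tsv <- hits_tsv[!duplicated(paste(hits_tsv$contig, hits_tsv$orf_index,
                                         hits_tsv$profile, sep = "\r")), , drop = FALSE]

  ## --- CRISPR arrays ------------------------------------------------------
  spacer_rows <- list()
  for (cm in comms) {
    for (a in seq_len(config$n_arrays)) {
      ns <- config$spacers_per_array
      if (ns == 0L) next
      spacer_rows[[length(spacer_rows) + 1L]] <- data.frame(
        spacer_id = sprintf("%s_arr%d_s%02d", cm, a, seq_len(ns) - 1L),
        sample = cm, fraction = "bacterial",
        array_id = sprintf("%s_arr%d", cm, a),
        position_in_array = seq_len(ns) - 1L,
        sequence = random_dna(ns, config$spacer_length),
        cas_type = config$cas_type, array_contig = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  spacers <- if (length(spacer_rows)) do.call(rbind, spacer_rows) else
    data.frame(spacer_id = character(0), sample = character(0),
               fraction = character(0), array_id = character(0),
               position_in_array = integer(0), sequence = character(0),
               cas_type = character(0), array_contig = character(0),
               stringsAsFactors = FALSE)

  ## --- protospacer planting ----------------------------------------------
  # sequences are edited in place; shared masters are edited once and copied
  # to every carrying sample afterwards
  seq_env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(contigs)))
    if (nzchar(contigs$sequence[i])) assign(contigs$id[i], contigs$sequence[i], seq_env)
  for (p in names(shared_master)) assign(paste0("shared:", p), shared_master[[p]], seq_env)
  occupied <- new.env(parent = emptyenv())   # per target: matrix of used spans

  plant_rows <- list()
  if (!is.null(config$planting) && nrow(config$planting)) {
    pl <- config$planting
    used_ptr <- stats::setNames(rep(0L, length(comms)), comms)
    for (k in seq_len(nrow(pl))) {
      src <- pl$spacer_source[k]; tgt <- pl$contig_source[k]
      ns <- pl$n_sites[k]
      src_sp <- spacers[spacers$sample == src, , drop = FALSE]
      if (!is.null(pl$positions) && !is.na(pl$positions[k])) {
        want <- as.integer(strsplit(pl$positions[k], ",")[[1]])
        arr <- sort(unique(src_sp$array_id))[1L]
        sel <- src_sp[src_sp$array_id == arr &
                        src_sp$position_in_array %in% want, , drop = FALSE]
      } else {
        if (used_ptr[src] + ns > nrow(src_sp))
          .stopf("community '%s' has only %d spacers (%d requested so far)",
                 src, nrow(src_sp), used_ptr[src] + ns)
        sel <- src_sp[used_ptr[src] + seq_len(ns), , drop = FALSE]
        used_ptr[src] <- used_ptr[src] + ns
      }
      if (nrow(sel) != ns)
        .stopf("planting row %d: requested %d sites but selected %d spacers", k, ns, nrow(sel))
      # resolve target sequence key
      tkey <- NULL
      if (!is.null(pl$target_contig) && !is.na(pl$target_contig[k])) {
        tc <- pl$target_contig[k]
        tkey <- if (tc %in% names(shared_master)) paste0("shared:", tc)
                else if (exists(tc, seq_env)) tc
                else .stopf("planting row %d: unknown target contig '%s'", k, tc)
      } else {
        cand <- contigs$id[contigs$sample == tgt & contigs$fraction == "viral" &
                             grepl("_v[0-9]+$", contigs$id)]
        if (!length(cand)) .stopf("no viral contigs in community '%s'", tgt)
        tkey <- cand[((k - 1L) %% length(cand)) + 1L]
      }
      for (j in seq_len(ns)) {
        sp <- sel[j, ]
        proto <- mutate_protospacer(sp$sequence, pl$mismatches[k],
                                    preserve_seed = config$preserve_seed)
        strand <- pl$strand[k]
        ins_fwd <- if (strand == "+")
          paste0(pl$pam_5p[k], proto, pl$pam_3p[k])
        else
          revcomp(paste0(pl$pam_5p[k], proto, pl$pam_3p[k]))
        tseq <- get(tkey, seq_env)
        tlen <- nchar(tseq)
        ilen <- nchar(ins_fwd)
        if (ilen + 40L > tlen)
          .stopf("planting row %d: spacer+PAM longer than target contig '%s'", k, tkey)
        occ <- if (exists(tkey, occupied)) get(tkey, occupied) else
          matrix(numeric(0), ncol = 2)
        for (try in 1:200) {
          pos <- sample.int(tlen - ilen - 20L, 1L) + 10L   # insertion start (PAM incl.)
          if (!nrow(occ) || all(pos + ilen + 19L < occ[, 1] | pos - 20L > occ[, 2])) break
          if (try == 200L) .stopf("planting row %d: no free site on '%s'", k, tkey)
        }
        substr(tseq, pos, pos + ilen - 1L) <- ins_fwd
        assign(tkey, tseq, seq_env)
        assign(tkey, rbind(occ, c(pos, pos + ilen - 1L)), occupied)
        # protospacer coordinates exclude the flanking PAM bases
        p5 <- nchar(pl$pam_5p[k]); p3 <- nchar(pl$pam_3p[k])
        if (strand == "+") {
          cstart <- pos + p5; cend <- pos + ilen - 1L - p3
        } else {
          cstart <- pos + p3; cend <- pos + ilen - 1L - p5
        }
        plant_rows[[length(plant_rows) + 1L]] <- data.frame(
          spacer_id = sp$spacer_id, spacer_source = src,
          target_key = tkey, contig_source = tgt,
          contig_start = cstart, contig_end = cend, strand = strand,
          pam_5p = pl$pam_5p[k], pam_3p = pl$pam_3p[k],
          mismatches = pl$mismatches[k], stringsAsFactors = FALSE)
      }
    }
  }
  planted_sites <- if (length(plant_rows)) do.call(rbind, plant_rows) else
    data.frame(spacer_id = character(0), spacer_source = character(0),
               target_key = character(0), contig_source = character(0),
               contig_start = integer(0), contig_end = integer(0),
               strand = character(0), pam_5p = character(0),
               pam_3p = character(0), mismatches = integer(0),
               stringsAsFactors = FALSE)

  # write edited sequences back; expand shared masters to their copies
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$id[i]
    if (exists(id, seq_env)) contigs$sequence[i] <- get(id, seq_env)
  }
  site_expanded <- list()
  for (r in seq_len(nrow(planted_sites))) {
    row <- planted_sites[r, ]
    if (startsWith(row$target_key, "shared:")) {
      pfx <- sub("^shared:", "", row$target_key)
      sc <- Filter(function(s) s$prefix == pfx, config$shared_contigs)[[1]]
      for (cm in sc$samples) {
        row2 <- row
        row2$contig_id <- sprintf("%s_%s", pfx, cm)
        row2$contig_source <- cm
        site_expanded[[length(site_expanded) + 1L]] <- row2
      }
    } else {
      row$contig_id <- row$target_key
      site_expanded[[length(site_expanded) + 1L]] <- row
    }
  }
  planted_sites <- if (length(site_expanded)) do.call(rbind, site_expanded) else
    cbind(planted_sites, data.frame(contig_id = character(0), stringsAsFactors = FALSE))
  planted_sites$target_key <- NULL
  rownames(planted_sites) <- NULL
  for (p in names(shared_master)) {
    final <- get(paste0("shared:", p), seq_env)
    sc <- Filter(function(s) s$prefix == p, config$shared_contigs)[[1]]
    for (cm in sc$samples)
      contigs$sequence[contigs$id == sprintf("%s_%s", p, cm)] <- final
  }
  contigs$length <- nchar(contigs$sequence)

  ## --- depth model --------------------------------------------------------
  mean_depth_target <- stats::setNames(
    sample(config$depth_range[1]:config$depth_range[2], nrow(contigs), replace = TRUE),
    contigs$id)
  for (id in names(shared_depth)) mean_depth_target[id] <- shared_depth[[id]]
  depth_rows <- lapply(seq_len(nrow(contigs)), function(i) {
    len <- contigs$length[i]
    d <- mean_depth_target[[contigs$id[i]]]
    if (config$depth_model == "constant") {
      data.frame(contig = contigs$id[i], pos = seq_len(len),
                 depth = rep(as.numeric(d), len), stringsAsFactors = FALSE)
    } else {
      dep <- stats::rpois(len, d)
      keep <- dep > 0L
      data.frame(contig = contigs$id[i], pos = which(keep),
                 depth = dep[keep], stringsAsFactors = FALSE)
    }
  })
  depth <- do.call(rbind, depth_rows)
  realized_depth <- stats::setNames(
    as.numeric(tapply(depth$depth, depth$contig, sum)[contigs$id]) / contigs$length,
    contigs$id)
  realized_depth[is.na(realized_depth)] <- 0
  contigs$mean_depth <- unname(realized_depth[contigs$id])

  ## --- pseudo viral-caller verdicts ---------------------------------------
  vir <- contigs[contigs$fraction == "viral", , drop = FALSE]
  is_decoy <- grepl("_d[0-9]+$", vir$id)
  verdicts <- do.call(rbind, lapply(tools, function(tl) {
    p <- ifelse(is_decoy, config$tool_fpr, config$tool_sensitivity)
    data.frame(contig_id = vir$id, tool = tl,
               is_viral = stats::runif(nrow(vir)) < p, stringsAsFactors = FALSE)
  }))

  ## --- truth manifest ------------------------------------------------------
  interaction <- matrix(0L, length(comms), length(comms),
                        dimnames = list(comms, comms))
  if (nrow(planted_sites)) {
    t0 <- table(factor(planted_sites$spacer_source, levels = comms),
                factor(planted_sites$contig_source, levels = comms))
    interaction[] <- as.integer(t0)
  }
  manifest <- list(
    seed = config$seed,
    communities = comms,
    planted_systems = planted_sys,
    planted_sites = planted_sites,
    interaction_matrix = interaction,
    contig_depths = contigs[, c("id", "sample", "fraction", "length", "mean_depth")],
    viral_truth = data.frame(contig_id = vir$id, is_viral = !is_decoy,
                             stringsAsFactors = FALSE),
    n_reads = stats::setNames(rep(config$n_reads, length(comms)), comms))

  out <- list(contigs = contigs, orfs = orfs, hits = hits_tsv,
              mapping = mapping_tsv, spacers = spacers, depth = depth,
              verdicts = verdicts, manifest = manifest)
  if (!is.null(out_dir)) out$files <- .write_scenario(out, comms, tools, out_dir)
  out
}

# write the fixture set to disk, one file group per community
.write_scenario <- function(sc, comms, tools, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  fp <- function(...) file.path(out_dir, sprintf(...))
  for (cm in comms) {
    cc <- sc$contigs[sc$contigs$sample == cm, , drop = FALSE]
    for (fr in c("bacterial", "viral")) {
      f <- fp("%s_%s.fasta", cm, fr)
      write_contig_fasta(cc[cc$fraction == fr, , drop = FALSE], f)
      files[[sprintf("%s_%s_fasta", cm, fr)]] <- f
    }
    oo <- sc$orfs[sc$orfs$contig_id %in% cc$id, , drop = FALSE]
    files[[paste0(cm, "_gff")]] <- write_orf_gff(oo, fp("%s_orfs.gff", cm))
    hh <- sc$hits[sc$hits$contig %in% cc$id, , drop = FALSE]
    utils::write.table(
      data.frame(contig = hh$contig, orf_index = hh$orf_index,
                 profile = hh$profile,
                 evalue = formatC(hh$evalue, format = "e", digits = 6)),
      fp("%s_hits.tsv", cm), sep = "\t", quote = FALSE, row.names = FALSE)
    files[[paste0(cm, "_hits")]] <- fp("%s_hits.tsv", cm)
    dd <- sc$depth[sc$depth$contig %in% cc$id, , drop = FALSE]
    files[[paste0(cm, "_depth")]] <- write_depth_table(dd, fp("%s_depth.tsv", cm))
    ssp <- sc$spacers[sc$spacers$sample == cm, , drop = FALSE]
    files[[paste0(cm, "_spacers")]] <- write_spacer_table(ssp, fp("%s_spacers.tsv", cm))
    for (tl in tools) {
      vv <- sc$verdicts[sc$verdicts$tool == tl &
                          sc$verdicts$contig_id %in% cc$id, , drop = FALSE]
      files[[sprintf("%s_verdict_%s", cm, tl)]] <-
        write_verdict_table(vv, fp("%s_verdict_%s.csv", cm, tl))
    }
  }
  utils::write.table(sc$mapping, file.path(out_dir, "profile_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files$mapping <- file.path(out_dir, "profile_map.tsv")
  mf <- sc$manifest
  mf$interaction_matrix <- as.data.frame(mf$interaction_matrix)
  jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$manifest <- file.path(out_dir, "manifest.json")
  files
}
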
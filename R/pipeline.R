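# End-to-end orchestration: read per-community inputs, run every stage with
# one set of thresholds, and write all tables, networks and the run report
# into an output directory. Outputs are pure functions of the declared
# inputs, so a rerun on identical inputs is byte-identical.

#' Default pipeline thresholds
#'
#' The defaults every stage runs with unless overridden: hit E-value cutoff
#' 1e-10, system chaining gap < 5 intervening ORFs, island gap <= 10,
#' spacer clustering at identity/coverage 0.95/0.95, viral dereplication at
#' 0.95/0.8, protospacer word size 8, query coverage 0.95, E-value 10, and
#' a 2-of-3 viral vote.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(evalue_max = 1e-10, max_gap = 5L, island_gap = 10L,
       spacer_identity = 0.95, spacer_coverage = 0.95,
       viral_identity = 0.95, viral_coverage = 0.8,
       word_size = 8L, qcov = 0.95, match_evalue_max = 10,
       min_votes = 2L, min_contig_length = 5000L)
}

#' Validate a pipeline run configuration
#'
#' A run config is a list (typically parsed from YAML) with `samples`, a
#' named list mapping each sample to its file paths (`bacterial_fasta`,
#' `viral_fasta`, `orf_gff`, `hit_tsv`, `depth_tsv`, `spacer_tsv`,
#' `verdict_csv` (vector), `n_reads`), a shared `profile_map`, and an
#' optional `thresholds` block overriding [default_thresholds()]. Every
#' referenced file must exist at validation time.
#'
#' @param config list or path to a YAML file.
#' @return the normalized config, invisibly on success; errors otherwise.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$samples) || !length(config$samples))
    .stopf("run config: no samples declared")
  if (is.null(config$profile_map)) .stopf("run config: profile_map missing")
  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  files <- c(config$profile_map,
             unlist(lapply(config$samples, function(s)
               unlist(s[c("bacterial_fasta", "viral_fasta", "orf_gff",
                          "hit_tsv", "depth_tsv", "spacer_tsv", "verdict_csv")]))))
  missing <- files[!file.exists(files)]
  if (length(missing))
    .stopf("run config: missing input file(s): %s", paste(missing, collapse = ", "))
  for (nm in names(config$samples))
    if (is.null(config$samples[[nm]]$n_reads))
      .stopf("run config: sample '%s' lacks n_reads", nm)
  config$thresholds <- th
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on a configuration
#'
#' Stages: input parsing, viral vote and dereplication, defense-hit
#' resolution, system calling, island detection, raw and normalized count
#' tables, spacer clustering and sharing, protospacer search with PAM
#' extraction, and the community-community network. Writes TSV/GraphML/JSON
#' outputs plus `run_report.json` with thresholds and per-stage record
#' counts (no timestamps, so reruns are byte-identical).
#'
#' @param config run config list or YAML path (see [validate_run_config()]).
#' @param out_dir output directory, created if missing.
#' @return invisible list of the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  th <- config$thresholds
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, sprintf(...))
  report <- list(package_version = as.character(utils::packageVersion("phagenet")),
                 thresholds = th, stages = list())
  stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
    .log("stage %s: %s", name,
         paste(sprintf("%s=%s", names(list(...)), unlist(list(...))), collapse = " "))
  }

  ## inputs ---------------------------------------------------------------
  mapping <- read_profile_map(config$profile_map)
  samples <- names(config$samples)
  contigs <- list(); orfs <- list(); hits <- list(); spacers <- list()
  verdicts <- list(); ctx <- list()
  for (nm in samples) {
    s <- config$samples[[nm]]
    cb <- read_contig_fasta(s$bacterial_fasta, sample = nm, fraction = "bacterial")
    cv <- read_contig_fasta(s$viral_fasta, sample = nm, fraction = "viral")
    cc <- rbind(cb, cv)
    cc <- read_depth_table(s$depth_tsv, cc)
    contigs[[nm]] <- cc
    orfs[[nm]] <- read_orf_gff(s$orf_gff)
    hits[[nm]] <- read_hit_table(s$hit_tsv, mapping)
    spacers[[nm]] <- read_spacer_table(s$spacer_tsv)
    verdicts[[nm]] <- read_verdict_table(s$verdict_csv)
    L <- sum(cc$length[cc$length >= th$min_contig_length])
    if (L <= 0) L <- sum(cc$length)
    ctx[[nm]] <- normalization_context(L = L, N = s$n_reads)
  }
  contigs_all <- do.call(rbind, contigs)
  spacers_all <- do.call(rbind, spacers)
  rownames(contigs_all) <- rownames(spacers_all) <- NULL
  stage("read_inputs", n_samples = length(samples), n_contigs = nrow(contigs_all),
        n_spacers = nrow(spacers_all))

  ## viruses --------------------------------------------------------------
  verd_all <- do.call(rbind, verdicts)
  viral_ids <- vote_viral(verd_all, min_votes = th$min_votes)
  viral_contigs <- contigs_all[contigs_all$id %in% viral_ids, , drop = FALSE]
  derep <- dereplicate_viral(viral_contigs, identity = th$viral_identity,
                             coverage = th$viral_coverage)
  vshare <- viral_shared_matrix(derep$clusters, contigs_all)
  utils::write.table(data.frame(contig_id = viral_ids), fp("viral_contigs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(derep$clusters, fp("viral_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(vshare$matrix, fp("viral_shared_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  stage("viruses", n_voted = length(viral_ids),
        n_representatives = nrow(derep$representatives),
        n_cross_fraction = vshare$n_cross_fraction_clusters)

  ## defense --------------------------------------------------------------
  hits_all <- do.call(rbind, hits)
  assignments <- filter_and_resolve_hits(hits_all, evalue_max = th$evalue_max)
  calls <- call_defense_systems(assignments, max_gap = th$max_gap)
  islands <- detect_islands(calls, island_gap = th$island_gap)
  contig_samples <- stats::setNames(contigs_all$sample, contigs_all$id)
  sys_counts <- count_defense(calls, assignments, contig_samples,
                              by = "system", samples = samples)
  gene_counts <- count_defense(calls, assignments, contig_samples,
                               by = "gene", samples = samples)
  norm_sys <- normalized_count_table(calls, contigs_all, ctx, samples = samples)
  norm_gene <- normalized_count_table(assignments, contigs_all, ctx,
                                      samples = samples)
  utils::write.table(calls, fp("defense_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(islands, fp("defense_islands.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sys_counts, fp("counts_systems.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(gene_counts, fp("counts_genes.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(norm_sys, fp("normalized_systems.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(norm_gene, fp("normalized_genes.tsv"), sep = "\t", quote = FALSE)
  stage("defense", n_hits = nrow(hits_all), n_assignments = nrow(assignments),
        n_calls = nrow(calls), n_islands = nrow(islands))

  ## spacerome ------------------------------------------------------------
  sp_seqs <- stats::setNames(spacers_all$sequence, spacers_all$spacer_id)
  sp_clusters <- cluster_sequences(sp_seqs, identity = th$spacer_identity,
                                   coverage = th$spacer_coverage)
  sp_samples <- stats::setNames(spacers_all$sample, spacers_all$spacer_id)
  sp_share <- shared_matrix(sp_clusters, sp_samples, samples = samples)
  matches <- find_protospacers(spacers_all, viral_contigs,
                               word_size = th$word_size, qcov = th$qcov,
                               max_evalue = th$match_evalue_max)
  profiles <- array_position_profile(matches, spacers_all)
  utils::write.table(sp_clusters, fp("spacer_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sp_share, fp("spacer_shared_matrix.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(matches, fp("protospacer_matches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(profiles, fp("array_position_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage("spacerome", n_spacer_clusters = length(unique(sp_clusters$cluster)),
        n_matches = nrow(matches))

  ## network --------------------------------------------------------------
  net <- build_network(matches, spacers_all, viral_contigs,
                       spacer_clusters = sp_clusters,
                       contig_clusters = derep$clusters)
  summ <- intra_vs_inter_summary(net$edges)
  write_network_graphml(net$edges, fp("network.graphml"),
                        node_sizes = net$node_sizes)
  utils::write.table(summ$table, fp("intra_vs_inter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage("network", n_edges = nrow(net$edges),
        fraction_intra_dominant = summ$fraction_intra_dominant)

  jsonlite::write_json(report, fp("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(contigs = contigs_all, spacers = spacers_all,
                 assignments = assignments, calls = calls, islands = islands,
                 system_counts = sys_counts, gene_counts = gene_counts,
                 normalized_systems = norm_sys, normalized_genes = norm_gene,
                 viral_ids = viral_ids, derep = derep,
                 viral_shared = vshare, spacer_clusters = sp_clusters,
                 spacer_shared = sp_share, matches = matches,
                 array_profiles = profiles, network = net,
                 intra_inter = summ, report = report))
}

#' Write a run config for a generated scenario
#'
#' Convenience bridge from [generate_scenario()] fixtures on disk to a
#' [run_pipeline()] YAML config.
#'
#' @param files the `files` element returned by [generate_scenario()].
#' @param communities community labels of the scenario.
#' @param n_reads mapped reads per community.
#' @param path output YAML path.
#' @param thresholds optional threshold overrides.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(files, communities, n_reads, path,
                             thresholds = NULL) {
  samples <- lapply(communities, function(cm) {
    list(bacterial_fasta = files[[paste0(cm, "_bacterial_fasta")]],
         viral_fasta = files[[paste0(cm, "_viral_fasta")]],
         orf_gff = files[[paste0(cm, "_gff")]],
         hit_tsv = files[[paste0(cm, "_hits")]],
         depth_tsv = files[[paste0(cm, "_depth")]],
         spacer_tsv = files[[paste0(cm, "_spacers")]],
         verdict_csv = unname(unlist(files[sprintf("%s_verdict_%s", cm,
                                                   c("toolA", "toolB", "toolC"))])),
         n_reads = n_reads)
  })
  names(samples) <- communities
  cfg <- list(profile_map = files$mapping, samples = samples)
  if (!is.null(thresholds)) cfg$thresholds <- thresholds
  yaml::write_yaml(cfg, path)
  invisible(path)
}
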
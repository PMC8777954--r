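# Depth- and library-size-normalized quantification of defense genes and
# systems. Each counted item contributes the weight of its contig,
#
#   weight = covdepth * 1e12 / (L * N)
#
# where covdepth is the contig's mean per-base coverage depth, L the total
# length of the (size-filtered) assembly, N the total number of reads mapped
# to it, and 1e12 a fixed scaling coefficient shared by all metagenomes so
# that normalized values land in the numeric range of the raw counts.

#' Normalization context for one metagenome
#'
#' @param L total assembly length in bases (contigs above the length cutoff).
#' @param N total number of reads mapped to the assembly.
#' @param scale scaling coefficient; fixed at `1e12`.
#' @return object of class `"norm_ctx"`.
#' @export
normalization_context <- function(L, N, scale = 1e12) {
  if (!isTRUE(L > 0)) .stopf("normalization context: L must be > 0")
  if (!isTRUE(N > 0)) .stopf("normalization context: N must be > 0")
  structure(list(L = as.numeric(L), N = as.numeric(N), scale = scale),
            class = "norm_ctx")
}

#' @export
print.norm_ctx <- function(x, ...) {
  cat(sprintf("normalization context: L = %g bp, N = %g reads, scale = %g\n",
              x$L, x$N, x$scale))
  invisible(x)
}

#' Normalized weight of a contig
#'
#' `mean_depth * scale / (L * N)`; linear in depth, nonnegative.
#'
#' @param mean_depth contig mean coverage depth (vectorised).
#' @param ctx a [normalization_context()].
#' @param contig_id optional ids used in the missing-depth error message.
#' @return numeric vector of weights.
#' @export
normalized_weight <- function(mean_depth, ctx, contig_id = NULL) {
  stopifnot(inherits(ctx, "norm_ctx"))
  if (anyNA(mean_depth)) {
    who <- if (is.null(contig_id)) "input" else
      paste(contig_id[is.na(mean_depth)], collapse = ", ")
    .stopf("missing mean depth for contig(s): %s", who)
  }
  mean_depth * ctx$scale / (ctx$L * ctx$N)
}

#' Normalized abundance table of defense genes or systems
#'
#' Each item (a system call or a gene assignment) contributes the normalized
#' weight of the contig it sits on; cells sum those weights per sample and
#' system type. With `raw = TRUE` every weight is forced to 1 and the raw
#' count table is recovered.
#'
#' @param items data.frame with at least `contig_id` and `system_name`
#'   (calls or assignments).
#' @param contigs contig data.frame with `mean_depth` set; supplies the
#'   sample of each contig.
#' @param ctx_per_sample named list of [normalization_context()], one per
#'   sample.
#' @param raw force unit weights (raw counting).
#' @param samples,systems optional row/column universes.
#' @return numeric matrix, samples x system types.
#' @export
normalized_count_table <- function(items, contigs, ctx_per_sample, raw = FALSE,
                                   samples = NULL, systems = NULL) {
  idx <- match(items$contig_id, contigs$id)
  if (anyNA(idx))
    .stopf("counted item on unknown contig: %s",
           paste(unique(items$contig_id[is.na(idx)]), collapse = ", "))
  samp <- contigs$sample[idx]
  samples <- sort(unique(c(samples, samp)))
  systems <- sort(unique(c(systems, items$system_name)))
  tab <- matrix(0, length(samples), length(systems),
                dimnames = list(samples, systems))
  if (nrow(items) == 0L) return(tab)
  w <- if (raw) rep(1, nrow(items)) else {
    vapply(seq_len(nrow(items)), function(i) {
      ctx <- ctx_per_sample[[samp[i]]]
      if (is.null(ctx)) .stopf("no normalization context for sample '%s'", samp[i])
      normalized_weight(contigs$mean_depth[idx[i]], ctx, items$contig_id[i])
    }, numeric(1))
  }
  for (i in seq_len(nrow(items)))
    tab[samp[i], items$system_name[i]] <- tab[samp[i], items$system_name[i]] + w[i]
  tab
}

#' Pairwise depth fold-changes of one contig (or cluster) across samples
#'
#' @param depths named numeric vector: mean depth of the contig (or of its
#'   cluster representative's members) per sample.
#' @return data.frame of all ordered sample pairs with `ratio`
#'   (`depth[num] / depth[den]`) and an `infinite` flag for zero
#'   denominators.
#' @export
depth_fold_change <- function(depths) {
  if (length(depths) < 2L)
    .stopf("depth fold-change needs the contig's depth in >= 2 samples")
  s <- names(depths)
  if (is.null(s) || any(!nzchar(s))) .stopf("depths must be named by sample")
  pairs <- expand.grid(num = s, den = s, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$num != pairs$den, , drop = FALSE]
  ratio <- unname(depths[pairs$num] / depths[pairs$den])
  data.frame(numerator = pairs$num, denominator = pairs$den,
             ratio = ratio, infinite = is.infinite(ratio),
             stringsAsFactors = FALSE, row.names = NULL)
}
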
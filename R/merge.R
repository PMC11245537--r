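# Cumulative merging of single-cell technical replicates and the
# depth-versus-overlap analysis.

#' Cumulatively merge single-cell technical replicates
#'
#' Pools the cells of `k` replicates (selected in random order when `seed`
#' is given, otherwise in list order), prefixing barcodes per member so
#' droplets never collide, and rebuilds clonotypes with sizes recomputed
#' from the pooled distinct barcodes. The merged unique-CDR3 set equals the
#' union of the members' sets, and the result is invariant to the order of
#' the same member set (canonical sorting).
#'
#' @param replicates list of `sc_repertoire`s sharing donor and method.
#' @param k number of replicates to merge (`1 <= k <= length(replicates)`).
#' @param seed optional seed controlling the random selection order.
#' @return an `sc_repertoire` with `replicate_id` recording the members.
#' @export
merge_cumulative <- function(replicates, k, seed = NULL) {
  if (k < 1 || k > length(replicates)) {
    stop(sprintf("k must be in [1, %d]", length(replicates)), call. = FALSE)
  }
  donors <- unique(vapply(replicates, `[[`, "", "donor"))
  if (length(donors) > 1) {
    stop("replicates must share a donor", call. = FALSE)
  }
  ord <- if (is.null(seed)) seq_along(replicates) else
    with_seed(seed, sample.int(length(replicates)))
  members <- replicates[ord[seq_len(k)]]
  cells <- bind_rows(lapply(seq_along(members), function(i) {
    ci <- members[[i]]$cells
    ci$cell_id <- paste0("m", i, "_", ci$cell_id)
    ci
  }))
  clono <- bind_rows(lapply(members, function(r) r$clonotypes))
  clono <- distinct(clono, clonotype_key, .keep_all = TRUE)
  ids <- vapply(members, function(r) r$replicate_id %||% r$sample_id, "")
  out <- new_sc_repertoire(
    clono, cells,
    sample_id = paste0(members[[1]]$donor, "_merged_k", k),
    donor = members[[1]]$donor,
    isotype_or_subset = members[[1]]$isotype_or_subset,
    replicate_id = paste(sort(ids), collapse = "+"))
  attr(out, "merge_order") <- ids
  out
}

#' CDR3 overlap with bulk as replicates are merged
#'
#' For each random ordering (one per seed) and each depth `k = 1..K`,
#' computes the Jaccard overlap between the bulk repertoire's unique CDRH3
#' amino-acid set and the union set of the first `k` merged single-cell
#' replicates — the sampling-depth analysis.
#'
#' @param bulk a bulk `repertoire` (same donor/isotype as the replicates).
#' @param replicates list of `sc_repertoire`s.
#' @param seeds integer vector; one random merge order is drawn per seed.
#' @param chain chain for the CDR3 sets (default heavy).
#' @return tidy tibble (`seed`, `k`, `jaccard`).
#' @export
depth_overlap_curve <- function(bulk, replicates, seeds = 1:10,
                                chain = "heavy") {
  bulk_set <- cdr3_set(bulk, chain = chain)
  rep_sets <- lapply(replicates, cdr3_set, chain = chain)
  K <- length(replicates)
  out <- lapply(seeds, function(s) {
    ord <- with_seed(s, sample.int(K))
    acc <- character(0)
    js <- numeric(K)
    for (k in seq_len(K)) {
      acc <- union(acc, rep_sets[[ord[k]]])
      js[k] <- jaccard_overlap(bulk_set, acc)
    }
    tibble(seed = s, k = seq_len(K), jaccard = js)
  })
  bind_rows(out)
}
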
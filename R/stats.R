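# Group-comparison statistics (Kruskal-Wallis global test, pairwise
# Wilcoxon rank-sum with Bonferroni adjustment) and the config-driven
# pipeline orchestrator.

#' Compare metric values between groups
#'
#' Global differences are tested with the Kruskal-Wallis test; post-hoc
#' pairwise comparisons use the two-sided Wilcoxon rank-sum test (exact
#' when both groups are small and tie-free, normal approximation with tie
#' correction otherwise — the standard defaults), with p values adjusted by
#' Bonferroni correction (`min(1, p * m)`, m = number of pairwise tests).
#' Pairwise values such as correlations or Jaccard indices are treated as
#' independent observations, as is conventional for this analysis despite
#' the known pseudo-replication.
#'
#' @param values numeric vector of observations.
#' @param groups vector of group labels, same length as `values` (>= 2
#'   groups).
#' @param alpha significance threshold reported alongside (default 0.05).
#' @return a `group_comparison`: per-group `n` and `median`, global
#'   Kruskal-Wallis p, matrices of raw and Bonferroni-adjusted pairwise p
#'   values.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop("need at least two groups", call. = FALSE)
  split_vals <- split(values, groups)
  summary_tbl <- tibble(
    group = lv,
    n = unname(vapply(split_vals[lv], length, integer(1))),
    median = unname(vapply(split_vals[lv], median, numeric(1))))
  kw <- suppressWarnings(kruskal.test(values, factor(groups)))
  pairs <- combn(lv, 2)
  m <- ncol(pairs)
  raw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (p in seq_len(m)) {
    a <- pairs[1, p]
    b <- pairs[2, p]
    pv <- suppressWarnings(
      wilcox.test(split_vals[[a]], split_vals[[b]],
                  alternative = "two.sided")$p.value)
    raw[a, b] <- raw[b, a] <- pv
  }
  adj <- raw * m
  adj[!is.na(adj) & adj > 1] <- 1
  structure(list(summary = summary_tbl, kruskal_p = unname(kw$p.value),
                 pairwise_p = raw, pairwise_p_adj = adj,
                 n_pairwise_tests = m, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d groups, Kruskal-Wallis p = %.4g\n",
              nrow(x$summary), x$kruskal_p))
  print(x$summary)
  cat(sprintf("pairwise Wilcoxon (Bonferroni-adjusted, m = %d):\n",
              x$n_pairwise_tests))
  print(round(x$pairwise_p_adj, 4))
  invisible(x)
}

# ---- Pipeline orchestration -------------------------------------------------

default_pipeline_config <- function() {
  list(
    seed = 42,
    n_bulk = 2000,
    n_sc_cells = 600,
    n_replicates = 4,
    replicate_depth = 150,
    n_serum = 30,
    n_decoys = 200,
    contaminant_rate = 0.02,
    decoy_rate = 0.02,
    pool_fraction = 0.5,
    min_cdr3_overlap = 3,
    depth_curve_orderings = 5
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  modifyList(default_pipeline_config(), config)
}

run_stage <- function(name, expr) {
  message(sprintf("[%s] starting", name))
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done", name))
  out
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> repertoire features -> replicate merging ->
#' peptide mapping -> statistics from a configuration (an R list or a JSON
#' file), writing tidy TSV outputs plus a JSON run manifest when `out_dir`
#' is given. Rerunning with the same configuration gives byte-identical
#' outputs (no timestamps are written).
#'
#' @param config list or path to a JSON file; unset fields take the
#'   defaults (seed 42, 2000 bulk clonotypes, 600 cells, 4 replicates of
#'   150 cells, 30 serum clonotypes, 2% contaminant/decoy peptide rates).
#' @param out_dir optional output directory (created if needed).
#' @return invisibly, a list with the simulated objects, feature tables,
#'   depth curve, filter ladder, identifications and statistics.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg_in <- read_pipeline_config(config)
  seed <- cfg_in$seed

  sim <- run_stage("synthetic_data", {
    gh <- germline_model(chain = "heavy", seed = seed + 1)
    gl <- germline_model(n_v = 20, n_j = 4, chain = "kappa",
                         seed = seed + 2)
    bulk_cfg <- simulation_config(n_clonotypes = cfg_in$n_bulk, seed = seed)
    bulk <- simulate_repertoire(bulk_cfg, gh, donor = "D1",
                                sample_id = "D1_bulk", seed = seed + 10)
    sc_cfg <- simulation_config(n_clonotypes = cfg_in$n_sc_cells,
                                seed = seed)
    sc <- simulate_paired_repertoire(sc_cfg, gh, gl, donor = "D1",
                                     sample_id = "D1_sc", seed = seed + 11,
                                     pool = bulk,
                                     pool_fraction = cfg_in$pool_fraction)
    list(germline_heavy = gh, germline_light = gl, bulk = bulk, sc = sc,
         bulk_cfg = bulk_cfg, sc_cfg = sc_cfg)
  })

  feats <- run_stage("repertoire_features", {
    gu_bulk <- gene_usage(sim$bulk)
    gu_sc <- gene_usage(sim$sc)
    corr <- usage_correlation(list(gu_bulk, gu_sc))
    ev <- evenness_profile(sim$bulk)
    lcc <- light_chain_coherence_within(sim$sc)
    j <- jaccard_overlap(cdr3_set(sim$bulk), cdr3_set(sim$sc))
    list(usage = list(bulk = gu_bulk, sc = gu_sc), correlation = corr,
         evenness = ev, lcc = lcc, jaccard_bulk_sc = j)
  })

  merged <- run_stage("replicate_merge", {
    if (cfg_in$replicate_depth > nrow(sim$sc$cells)) {
      stop(sprintf("replicate depth %d exceeds %d cells",
                   cfg_in$replicate_depth, nrow(sim$sc$cells)))
    }
    reps <- subsample_replicates(sim$sc, k = cfg_in$n_replicates,
                                 depth = cfg_in$replicate_depth,
                                 seed = seed + 20)
    curve <- depth_overlap_curve(sim$bulk, reps,
                                 seeds = seed + seq_len(
                                   cfg_in$depth_curve_orderings))
    list(replicates = reps, curve = curve)
  })

  abseq <- run_stage("abseq_map", {
    decoys <- generate_decoy_reference(cfg_in$n_decoys, sim$germline_heavy,
                                       seed = seed + 30,
                                       reference = c(
                                         sim$bulk$clonotypes$vdj_aa,
                                         sim$sc$clonotypes$vdj_aa))
    ptab <- simulate_abseq_run(list(sim$bulk, sim$sc), sim$bulk_cfg,
                               n_serum = cfg_in$n_serum,
                               contaminant_rate = cfg_in$contaminant_rate,
                               decoy_rate = cfg_in$decoy_rate,
                               decoys = decoys, seed = seed + 31)
    index <- build_reference_index(bulk_reps = sim$bulk, sc_reps = sim$sc,
                                   decoys = decoys,
                                   contaminants = synthetic_contaminants())
    matches <- match_peptides(ptab, index)
    classified <- classify_matches(matches,
                                   min_cdr3_overlap = cfg_in$min_cdr3_overlap)
    ident <- reconstruct_vdj(classified, index)
    cst <- class_switch_table(ident, ptab)
    message(sprintf("[abseq_map] ladder: all=%d specific=%d cdr3=%d unique=%d",
                    classified$ladder$all,
                    classified$ladder$antibody_specific,
                    classified$ladder$cdr3_overlapping,
                    classified$ladder$uniquely_mapped))
    list(peptides = ptab, index = index, classified = classified,
         identified = ident, class_switch = cst)
  })

  stats_out <- run_stage("stats_report", {
    curve <- merged$curve
    if (length(unique(curve$k)) > 1) {
      compare_groups(curve$jaccard, paste0("k", curve$k))
    } else NULL
  })

  result <- list(config = cfg_in, sim = sim, features = feats,
                 merge = merged, abseq = abseq, stats = stats_out)

  if (!is.null(out_dir)) {
    run_stage("report", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_airr(sim$bulk, file.path(out_dir, "bulk_reference.airr.tsv"))
      write_airr(sim$sc, file.path(out_dir, "sc_reference.airr.tsv"))
      write_tsv(merged$curve, file.path(out_dir, "depth_overlap_curve.tsv"),
                progress = FALSE)
      write_peptides(abseq$peptides, file.path(out_dir, "peptides.tsv"))
      write_tsv(as_tibble(abseq$identified),
                file.path(out_dir, "identifications.tsv"), progress = FALSE)
      ladder_df <- tibble(stage = names(unclass(abseq$classified$ladder)),
                          count = unlist(unclass(abseq$classified$ladder)))
      write_tsv(ladder_df, file.path(out_dir, "filter_ladder.tsv"),
                progress = FALSE)
      cst <- as_tibble(as.data.frame.matrix(abseq$class_switch),
                       rownames = "ref_isotype")
      write_tsv(cst, file.path(out_dir, "class_switch.tsv"),
                progress = FALSE)
      export_reference_fasta(list(sim$bulk, sim$sc),
                             file.path(out_dir, "reference.fasta"))
      manifest <- list(
        package_version = as.character(packageVersion("repab")),
        config = cfg_in,
        counts = list(
          bulk_clonotypes = n_clonotypes(sim$bulk),
          sc_cells = nrow(sim$sc$cells),
          peptides = nrow(abseq$peptides),
          ladder = unclass(abseq$classified$ladder),
          identifications = nrow(abseq$identified)))
      write_json(manifest, file.path(out_dir, "manifest.json"),
                 auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  }
  invisible(result)
}
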
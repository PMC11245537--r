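# Repertoire feature quantification: unweighted V-gene usage with pairwise
# Pearson correlation, CDR3 amino-acid Jaccard overlap, Hill-number evenness
# profiles, and light-chain coherence.

#' Unweighted V-gene usage profile
#'
#' Every clonotype contributes equally regardless of its size: the frequency
#' of gene g is the number of clonotypes calling g divided by the number of
#' clonotypes. Size-independence makes bulk (UMI-counted) and single-cell
#' (barcode-counted) samples comparable.
#'
#' @param rep a `repertoire`.
#' @param chain which chain to profile (default `"heavy"`; `"all"` uses
#'   every clonotype).
#' @return a `gene_usage_profile`: list with `sample_id`, named frequency
#'   vector `freq` (sums to 1), and `unique_gene_count`.
#' @export
gene_usage <- function(rep, chain = "heavy") {
  df <- rep$clonotypes
  if (chain == "light") df <- df[df$chain %in% c("kappa", "lambda"), ]
  else if (chain != "all") df <- df[df$chain == chain, ]
  if (nrow(df) == 0) {
    stop("empty repertoire (no ", chain, " clonotypes)", call. = FALSE)
  }
  tab <- table(df$v_gene)
  structure(list(sample_id = rep$sample_id,
                 freq = setNames(as.numeric(tab) / nrow(df), names(tab)),
                 unique_gene_count = length(tab)),
            class = "gene_usage_profile")
}

#' @export
print.gene_usage_profile <- function(x, ...) {
  cat(sprintf("<gene_usage_profile> %s: %d genes\n", x$sample_id,
              x$unique_gene_count))
  invisible(x)
}

#' Pairwise Pearson correlation of gene-usage profiles
#'
#' For each pair, frequencies are aligned on the union of genes observed in
#' either profile, absent genes imputed as 0 (set `support =
#' "intersection"` to restrict to shared genes). A pair whose aligned
#' vectors have zero variance yields `NA` with a warning rather than a
#' silent 0.
#'
#' @param profiles list of [gene_usage()] results (>= 2).
#' @param support gene support per pair: `"union"` (default) or
#'   `"intersection"`.
#' @return a `pairwise_matrix` (metric `"pearson_usage"`).
#' @export
usage_correlation <- function(profiles, support = c("union", "intersection")) {
  support <- match.arg(support)
  if (length(profiles) < 2) stop("need at least two profiles", call. = FALSE)
  labels <- vapply(profiles, `[[`, "", "sample_id")
  m <- length(profiles)
  mat <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  diag(mat) <- 1
  undefined <- FALSE
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      fa <- profiles[[i]]$freq
      fb <- profiles[[j]]$freq
      genes <- if (support == "union") union(names(fa), names(fb)) else
        intersect(names(fa), names(fb))
      a <- ifelse(is.na(fa[genes]), 0, fa[genes])
      b <- ifelse(is.na(fb[genes]), 0, fb[genes])
      if (length(genes) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
        undefined <- TRUE
        r <- NA_real_
      } else {
        r <- cor(a, b)
      }
      mat[i, j] <- mat[j, i] <- r
    }
  }
  if (undefined) {
    warning("zero-variance gene support for some pair(s); entries set to NA",
            call. = FALSE)
  }
  structure(list(metric = "pearson_usage", labels = labels, matrix = mat),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> metric %s, %d samples\n", x$metric,
              length(x$labels)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Jaccard overlap of two CDR3 sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`, on unique amino-acid CDR3
#' strings.
#'
#' @param A,B character vectors (treated as sets).
#' @return a number in `[0, 1]`; `NA` with a warning when both sets are
#'   empty.
#' @export
jaccard_overlap <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) {
    warning("Jaccard undefined for two empty sets", call. = FALSE)
    return(NA_real_)
  }
  length(intersect(A, B)) / u
}

#' Pairwise CDR3 Jaccard overlap matrix
#'
#' @param reps list of repertoires.
#' @param chain chain passed to [cdr3_set()].
#' @return a `pairwise_matrix` (metric `"jaccard_cdr3"`).
#' @export
jaccard_matrix <- function(reps, chain = "heavy") {
  labels <- vapply(reps, `[[`, "", "sample_id")
  sets <- lapply(reps, cdr3_set, chain = chain)
  m <- length(reps)
  mat <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m)) {
    for (j in i:m) {
      mat[i, j] <- mat[j, i] <- jaccard_overlap(sets[[i]], sets[[j]])
    }
  }
  structure(list(metric = "jaccard_cdr3", labels = labels, matrix = mat),
            class = "pairwise_matrix")
}

hill_diversity <- function(f, alpha) {
  f <- f[f > 0]
  vapply(alpha, function(a) {
    if (abs(a - 1) < 1e-9) exp(-sum(f * log(f)))
    else sum(f^a)^(1 / (1 - a))
  }, numeric(1))
}

#' Hill-diversity evenness profile
#'
#' Hill diversities `D(alpha) = (sum_i f_i^alpha)^(1/(1-alpha))` over an
#' alpha grid, with the `alpha = 1` singularity evaluated as the Shannon
#' limit `exp(-sum f_i log f_i)`. Evenness is `E = D / n`, 1 for a
#' perfectly uniform clonal frequency distribution. Zero-frequency entries
#' are removed before evaluation, so `D(0)` counts observed clonotypes.
#'
#' @param rep a `repertoire` or a numeric clonal frequency vector.
#' @param alpha_grid alpha values in `[0, 10]` (default 0 to 10 step 0.1).
#' @return tibble (`alpha`, `D`, `E`) of class `evenness_profile`.
#' @export
evenness_profile <- function(rep, alpha_grid = seq(0, 10, by = 0.1)) {
  f <- if (inherits(rep, "repertoire")) clonal_freqs(rep) else rep
  stopifnot(is.numeric(f), all(f >= 0))
  if (any(alpha_grid < 0 | alpha_grid > 10)) {
    stop("alpha_grid must lie in [0, 10]", call. = FALSE)
  }
  f <- f[f > 0]
  f <- f / sum(f)
  n <- length(f)
  D <- hill_diversity(f, alpha_grid)
  out <- tibble(alpha = alpha_grid, D = D, E = D / n)
  if (inherits(rep, "repertoire")) attr(out, "sample_id") <- rep$sample_id
  class(out) <- c("evenness_profile", class(out))
  out
}

# ---- Light chain coherence --------------------------------------------------

lcc_result <- function(scope, n_cells_evaluated, n_eligible_pairs,
                       n_coherent_pairs) {
  structure(list(
    scope = scope,
    n_cells_evaluated = as.integer(n_cells_evaluated),
    n_eligible_pairs = as.numeric(n_eligible_pairs),
    n_coherent_pairs = as.numeric(n_coherent_pairs),
    coherence_pct = if (n_eligible_pairs > 0)
      100 * n_coherent_pairs / n_eligible_pairs else NA_real_
  ), class = "lcc_result")
}

#' @export
print.lcc_result <- function(x, ...) {
  cat(sprintf(
    "<lcc_result> %s: %s coherent / %s eligible pairs (%s), %d cells\n",
    x$scope, format(x$n_coherent_pairs), format(x$n_eligible_pairs),
    if (is.na(x$coherence_pct)) "NA" else
      sprintf("%.2f%%", x$coherence_pct),
    x$n_cells_evaluated))
  invisible(x)
}

# Cell-level view used by the coherence computations: one row per cell with
# heavy V gene, heavy CDR3 aa, heavy clonotype key and light V gene.
cell_chain_table <- function(screp) {
  cl <- screp$clonotypes
  h <- match(screp$cells$heavy_key, cl$clonotype_key)
  l <- match(screp$cells$light_key, cl$clonotype_key)
  tibble(cell_id = screp$cells$cell_id,
         hv = cl$v_gene[h], hc = cl$cdr3_aa[h],
         hkey = cl$clonotype_key[h], lv = cl$v_gene[l])
}

choose2 <- function(n) n * (n - 1) / 2

#' Light-chain coherence within a donor
#'
#' Eligible pairs are unordered pairs of cells with the same heavy V gene
#' and identical CDRH3 amino-acid sequence (100% identity) but different
#' heavy clonotype keys (clonally related cells are excluded). A pair is
#' coherent when both cells carry the same light-chain V gene. When no pair
#' meets the criteria, the percentage is `NA`.
#'
#' @param screp an `sc_repertoire`.
#' @return an `lcc_result`.
#' @export
light_chain_coherence_within <- function(screp) {
  ct <- cell_chain_table(screp)
  grp <- ct |>
    group_by(hv, hc) |>
    summarise(
      m = n(),
      same_key = sum(choose2(table(hkey))),
      same_light = sum(choose2(table(lv))),
      same_light_same_key = sum(choose2(table(paste(hkey, lv)))),
      n_keys = n_distinct(hkey),
      .groups = "drop")
  eligible <- sum(choose2(grp$m) - grp$same_key)
  coherent <- sum(grp$same_light - grp$same_light_same_key)
  cells_eval <- {
    elig_groups <- grp[grp$n_keys >= 2, c("hv", "hc")]
    nrow(inner_join(ct, elig_groups, by = c("hv", "hc")))
  }
  lcc_result("within_donor", cells_eval, eligible, coherent)
}

#' Light-chain coherence across two donors
#'
#' Cross-donor cell pairs with the same heavy V gene and identical CDRH3
#' amino-acid sequence; no different-clonotype requirement since cells of
#' different donors are unrelated by construction. Coherent = same
#' light-chain V gene.
#'
#' @param repA,repB `sc_repertoire`s from two donors.
#' @return an `lcc_result`.
#' @export
light_chain_coherence_across <- function(repA, repB) {
  ca <- cell_chain_table(repA)
  cb <- cell_chain_table(repB)
  ga <- ca |> group_by(hv, hc) |> summarise(ma = n(), .groups = "drop")
  gb <- cb |> group_by(hv, hc) |> summarise(mb = n(), .groups = "drop")
  shared <- inner_join(ga, gb, by = c("hv", "hc"))
  eligible <- sum(shared$ma * shared$mb)
  la <- ca |> group_by(hv, hc, lv) |> summarise(ma = n(), .groups = "drop")
  lb <- cb |> group_by(hv, hc, lv) |> summarise(mb = n(), .groups = "drop")
  lshared <- inner_join(la, lb, by = c("hv", "hc", "lv"))
  coherent <- sum(lshared$ma * lshared$mb)
  cells_eval <- nrow(inner_join(ca, shared[, c("hv", "hc")],
                                by = c("hv", "hc"))) +
    nrow(inner_join(cb, shared[, c("hv", "hc")], by = c("hv", "hc")))
  lcc_result("across_donors", cells_eval, eligible, coherent)
}
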
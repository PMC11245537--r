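# Synthetic world: germline scaffolds, per-donor gene-usage distributions,
# Zipf clonal expansion, paired-chain cells with tunable light-chain
# coherence, serum sampling, in-silico protease digestion, contaminants and
# decoys. Everything is seeded and byte-reproducible.

#' Germline scaffold model
#'
#' A lightweight stand-in for a germline reference: each V gene carries a
#' framework1-3 amino-acid scaffold ending where the CDR3 begins, each J gene
#' a framework4 suffix. Simulated variable regions are
#' `v_scaffold + CDR3 + j_scaffold`.
#'
#' @param n_v,n_j number of V and J genes.
#' @param chain `"heavy"`, `"kappa"` or `"lambda"` (sets gene-name prefixes).
#' @param v_scaffold_length,j_scaffold_length scaffold lengths in residues
#'   (V framework ~80 aa, J ~12 aa, matching typical variable-region sizes).
#' @param seed RNG seed; the model is fully reproducible.
#' @return a `germline_model` with tibbles `v_genes` and `j_genes`.
#' @export
germline_model <- function(n_v = 50, n_j = 6,
                           chain = c("heavy", "kappa", "lambda"),
                           v_scaffold_length = 80, j_scaffold_length = 12,
                           seed = 101) {
  chain <- match.arg(chain)
  prefix <- c(heavy = "IGH", kappa = "IGK", lambda = "IGL")[chain]
  with_seed(seed, {
    vnames <- sprintf("%sV%d-%d", prefix, ((seq_len(n_v) - 1L) %% 7L) + 1L,
                      ((seq_len(n_v) - 1L) %/% 7L) + 1L)
    jnames <- sprintf("%sJ%d", prefix, seq_len(n_j))
    v_sc <- rand_aa_string(n_v, rep(v_scaffold_length, n_v))
    j_sc <- rand_aa_string(n_j, rep(j_scaffold_length, n_j))
    structure(list(
      chain = chain,
      v_genes = tibble(name = vnames, scaffold = v_sc),
      j_genes = tibble(name = jnames, scaffold = j_sc)
    ), class = "germline_model")
  })
}

#' Per-donor germline gene usage distribution
#'
#' Draws a Dirichlet-distributed categorical usage over the model's V and J
#' genes from an RNG stream seeded by a hash of the donor label, so the same
#' donor always has the same usage profile regardless of sample, method or
#' simulation seed — the property that makes same-donor samples correlate.
#'
#' @param germline a [germline_model()].
#' @param donor donor label.
#' @param concentration Dirichlet concentration for V genes (smaller =
#'   spikier donor-specific profiles).
#' @return list with named probability vectors `v` and `j`.
#' @export
donor_usage_probs <- function(germline, donor, concentration = 2) {
  with_seed(hash_string(paste0(donor, "::", germline$chain)), {
    v <- rgamma(nrow(germline$v_genes), shape = concentration)
    j <- rgamma(nrow(germline$j_genes), shape = 5)
    list(v = setNames(v / sum(v), germline$v_genes$name),
         j = setNames(j / sum(j), germline$j_genes$name))
  })
}

#' Simulation configuration
#'
#' Collects the generative knobs of the synthetic world. Defaults encode the
#' conditions the analyses assume: CDR3 lengths 8-25 with mode 15, Zipf-like
#' clonal expansion, negligible inter-donor CDR3 sharing (`donor_overlap`
#' 0), high within-donor light-chain coherence (0.9, within the observed
#' 88-93% range), and serum sampling independent of clonal size
#' (`serum_rank_bias` 0).
#'
#' @param n_clonotypes number of clonotypes (or cells, for the paired-chain
#'   generator).
#' @param clone_size_zipf_exponent Zipf exponent for clone sizes
#'   (`size ~ rank^-s`); may be a named vector per isotype.
#' @param size_scale scale of the largest clone relative to `n`.
#' @param cdr3_lengths,cdr3_length_probs discrete CDR3 aa length
#'   distribution.
#' @param isotype_proportions categorical over IgA/IgD/IgG/IgM.
#' @param donor_overlap fraction of clonotypes drawn from a shared pool when
#'   a pool is supplied.
#' @param light_chain_coherence probability that the second cell of a
#'   coherence pair reuses the group's canonical light V gene.
#' @param serum_rank_bias exponent beta in serum sampling weights
#'   `size^beta`; 0 = size-independent.
#' @param seed integer seed for all randomness.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_clonotypes = 1000,
                              clone_size_zipf_exponent = 1.1,
                              size_scale = 20,
                              cdr3_lengths = 8:25,
                              cdr3_length_probs = NULL,
                              isotype_proportions = c(IgA = 0.2, IgD = 0.1,
                                                      IgG = 0.3, IgM = 0.4),
                              donor_overlap = 0,
                              light_chain_coherence = 0.9,
                              serum_rank_bias = 0,
                              seed = 42) {
  if (is.null(cdr3_length_probs)) {
    # binomial shape over the length range, mode at 15 aa
    k <- length(cdr3_lengths) - 1L
    mode_target <- 15
    p <- (mode_target - min(cdr3_lengths)) / k
    cdr3_length_probs <- stats::dbinom(0:k, k, p)
  }
  stopifnot(length(cdr3_length_probs) == length(cdr3_lengths),
            all(cdr3_length_probs >= 0),
            donor_overlap >= 0, donor_overlap <= 1,
            light_chain_coherence >= 0, light_chain_coherence <= 1,
            all(isotype_proportions >= 0))
  structure(list(
    n_clonotypes = as.integer(n_clonotypes),
    clone_size_zipf_exponent = clone_size_zipf_exponent,
    size_scale = size_scale,
    cdr3_lengths = as.integer(cdr3_lengths),
    cdr3_length_probs = cdr3_length_probs / sum(cdr3_length_probs),
    isotype_proportions = isotype_proportions / sum(isotype_proportions),
    donor_overlap = donor_overlap,
    light_chain_coherence = light_chain_coherence,
    serum_rank_bias = serum_rank_bias,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

zipf_exponent_for <- function(cfg, isotype) {
  s <- cfg$clone_size_zipf_exponent
  if (!is.null(names(s)) && isotype %in% names(s)) unname(s[isotype])
  else unname(s[1])
}

sample_cdr3_aa <- function(n, cfg) {
  lens <- sample(cfg$cdr3_lengths, n, replace = TRUE,
                 prob = cfg$cdr3_length_probs)
  inner <- rand_aa_string(n, pmax(lens - 2L, 1L))
  paste0("C", inner, "W")
}

# Zipf-like sizes: size(rank) = max(1, round(scale * n * rank^-s)), assigned
# to clonotypes in a random order.
zipf_sizes <- function(n, s, scale) {
  sz <- pmax(1L, as.integer(round(scale * n * seq_len(n)^(-s))))
  sz[sample.int(n)]
}

#' Simulate a bulk-style repertoire
#'
#' Draws `n_clonotypes` clonotypes with donor-specific V/J usage, random
#' CDR3s anchored by C...W, Zipf-distributed sizes, and deterministic
#' back-translated CDR3 nucleotide sequences. When `pool` is given, a
#' fraction `cfg$donor_overlap` of clonotypes is copied from it (shared
#' clones between samples).
#'
#' @param cfg a [simulation_config()].
#' @param germline a [germline_model()].
#' @param donor,sample_id,isotype_or_subset metadata.
#' @param method `"bulk"` or `"single_cell"` (container label only).
#' @param seed overrides `cfg$seed` (use to draw several samples from one
#'   configuration).
#' @param pool optional `repertoire` acting as shared clonotype pool.
#' @return a `repertoire`.
#' @export
simulate_repertoire <- function(cfg, germline, donor = "D1",
                                sample_id = paste0(donor, "_bulk"),
                                method = "bulk", isotype_or_subset = "all",
                                seed = cfg$seed, pool = NULL) {
  n <- cfg$n_clonotypes
  if (n < 1) stop("n_clonotypes must be >= 1", call. = FALSE)
  usage <- donor_usage_probs(germline, donor)
  with_seed(seed, {
    n_shared <- if (is.null(pool)) 0L else
      min(round(cfg$donor_overlap * n), nrow(pool$clonotypes))
    shared <- NULL
    if (n_shared > 0) {
      idx <- sample.int(nrow(pool$clonotypes), n_shared)
      shared <- pool$clonotypes[idx, c("chain", "v_gene", "j_gene",
                                       "isotype", "cdr3_nt", "cdr3_aa",
                                       "vdj_aa", "cdr3_start", "cdr3_end")]
    }
    n_new <- n - n_shared
    vs <- sample(names(usage$v), n_new, replace = TRUE, prob = usage$v)
    js <- sample(names(usage$j), n_new, replace = TRUE, prob = usage$j)
    iso <- if (germline$chain == "heavy") {
      sample(names(cfg$isotype_proportions), n_new, replace = TRUE,
             prob = cfg$isotype_proportions)
    } else rep("none", n_new)
    cdr3 <- sample_cdr3_aa(n_new, cfg)
    vsc <- germline$v_genes$scaffold[match(vs, germline$v_genes$name)]
    jsc <- germline$j_genes$scaffold[match(js, germline$j_genes$name)]
    df <- tibble(
      chain = germline$chain, v_gene = vs, j_gene = js, isotype = iso,
      cdr3_nt = back_translate(cdr3), cdr3_aa = cdr3,
      vdj_aa = paste0(vsc, cdr3, jsc),
      cdr3_start = nchar(vsc), cdr3_end = nchar(vsc) + nchar(cdr3)
    )
    df <- bind_rows(df, shared)
    df$clonotype_key <- clonotype_key(df$cdr3_nt, df$cdr3_aa, df$v_gene,
                                      df$j_gene, df$isotype)
    # regenerate any key collisions among the novel draws
    while (anyDuplicated(df$clonotype_key)) {
      dup <- which(duplicated(df$clonotype_key))
      redo <- sample_cdr3_aa(length(dup), cfg)
      vsc2 <- germline$v_genes$scaffold[
        match(df$v_gene[dup], germline$v_genes$name)]
      jsc2 <- germline$j_genes$scaffold[
        match(df$j_gene[dup], germline$j_genes$name)]
      df$cdr3_aa[dup] <- redo
      df$cdr3_nt[dup] <- back_translate(redo)
      df$vdj_aa[dup] <- paste0(vsc2, redo, jsc2)
      df$cdr3_end[dup] <- df$cdr3_start[dup] + nchar(redo)
      df$clonotype_key[dup] <- clonotype_key(df$cdr3_nt[dup],
                                             df$cdr3_aa[dup], df$v_gene[dup],
                                             df$j_gene[dup], df$isotype[dup])
    }
    s_exp <- zipf_exponent_for(cfg, isotype_or_subset)
    df$size <- zipf_sizes(n, s_exp, cfg$size_scale)
    df$productive <- TRUE
    df <- arrange(df, desc(size), clonotype_key)
    new_repertoire(df, sample_id, donor, method, isotype_or_subset)
  })
}

canonical_light_v <- function(cdr3_aa, light_germline) {
  nv <- nrow(light_germline$v_genes)
  light_germline$v_genes$name[(hash_string(cdr3_aa) %% nv) + 1L]
}

make_light_clonotype <- function(v, germline_light, cfg) {
  j <- sample(germline_light$j_genes$name, length(v), replace = TRUE)
  cdr3 <- sample_cdr3_aa(length(v), cfg)
  vsc <- germline_light$v_genes$scaffold[
    match(v, germline_light$v_genes$name)]
  jsc <- germline_light$j_genes$scaffold[
    match(j, germline_light$j_genes$name)]
  tibble(chain = germline_light$chain, v_gene = v, j_gene = j,
         isotype = "none", cdr3_nt = back_translate(cdr3), cdr3_aa = cdr3,
         vdj_aa = paste0(vsc, cdr3, jsc), cdr3_start = nchar(vsc),
         cdr3_end = nchar(vsc) + nchar(cdr3), productive = TRUE)
}

#' Simulate a paired-chain single-cell repertoire
#'
#' Generates one droplet per cell with exactly one heavy and one light
#' clonotype. A subset of cells forms light-chain-coherence pairs: two cells
#' with the same heavy V gene and identical CDRH3 amino-acid sequence but
#' different CDR3 nucleotide sequences (synonymous variants, hence different
#' clonotype keys). The first cell of a pair carries the group's canonical
#' light V gene (a deterministic function of the CDRH3, so it agrees across
#' donors sharing a pool); the second reuses it with probability
#' `cfg$light_chain_coherence`, otherwise its light V is resampled from the
#' full light-gene distribution (chance-level collisions possible). The
#' remaining cells are singletons, optionally drawn (clonally, size-weighted,
#' with their fixed partner light chain) from a bulk `pool` with probability
#' `pool_fraction`.
#'
#' @param cfg a [simulation_config()]; `n_clonotypes` is the cell count.
#' @param germline_heavy,germline_light heavy- and light-chain
#'   [germline_model()]s.
#' @param donor,sample_id metadata.
#' @param seed overrides `cfg$seed`.
#' @param n_coherence_pairs number of coherence pairs (default 10% of
#'   cells).
#' @param heavy_pool optional tibble (`v_gene`, `j_gene`, `cdr3_aa`) of
#'   shared heavy groups for cross-donor coherence; pairs draw from it with
#'   probability `cfg$donor_overlap`.
#' @param pool optional bulk `repertoire`; singleton cells express a pool
#'   clonotype with probability `pool_fraction` (clonal expansion: cells of
#'   one clone share heavy and light chains).
#' @param pool_fraction probability a singleton cell comes from `pool`.
#' @return an `sc_repertoire`; the generative coherence is stored in
#'   `attr(, "true_rho")` and the heavy-to-light ground truth pairing in the
#'   cell table itself.
#' @export
simulate_paired_repertoire <- function(cfg, germline_heavy, germline_light,
                                       donor = "D1",
                                       sample_id = paste0(donor, "_sc"),
                                       seed = cfg$seed,
                                       n_coherence_pairs = NULL,
                                       heavy_pool = NULL, pool = NULL,
                                       pool_fraction = 0) {
  n_cells <- cfg$n_clonotypes
  if (n_cells < 1) stop("n_clonotypes must be >= 1", call. = FALSE)
  rho <- cfg$light_chain_coherence
  if (is.null(n_coherence_pairs)) {
    n_coherence_pairs <- max(0L, floor(0.1 * n_cells / 2))
  }
  n_coherence_pairs <- min(n_coherence_pairs, n_cells %/% 2L)
  usage_h <- donor_usage_probs(germline_heavy, donor)
  usage_l <- donor_usage_probs(germline_light, donor)
  with_seed(seed, {
    heavy_rows <- list()
    light_rows <- list()
    cell_heavy <- character(0)
    cell_light <- character(0)

    add_heavy <- function(v, j, cdr3, iso, variant) {
      vsc <- germline_heavy$v_genes$scaffold[
        match(v, germline_heavy$v_genes$name)]
      jsc <- germline_heavy$j_genes$scaffold[
        match(j, germline_heavy$j_genes$name)]
      tibble(chain = "heavy", v_gene = v, j_gene = j, isotype = iso,
             cdr3_nt = back_translate(cdr3, variant), cdr3_aa = cdr3,
             vdj_aa = paste0(vsc, cdr3, jsc), cdr3_start = nchar(vsc),
             cdr3_end = nchar(vsc) + nchar(cdr3), productive = TRUE)
    }

    # --- coherence pairs (batch-built; cells of pair g are rows g and
    # G + g of the heavy/light tables) -----------------------------------
    if (n_coherence_pairs > 0) {
      G <- n_coherence_pairs
      use_pool <- if (is.null(heavy_pool)) rep(FALSE, G) else
        runif(G) < cfg$donor_overlap
      gv <- sample(names(usage_h$v), G, replace = TRUE, prob = usage_h$v)
      gj <- sample(names(usage_h$j), G, replace = TRUE, prob = usage_h$j)
      gc3 <- sample_cdr3_aa(G, cfg)
      if (any(use_pool)) {
        pick <- sample.int(nrow(heavy_pool), sum(use_pool), replace = TRUE)
        gv[use_pool] <- heavy_pool$v_gene[pick]
        gj[use_pool] <- heavy_pool$j_gene[pick]
        gc3[use_pool] <- heavy_pool$cdr3_aa[pick]
      }
      iso <- sample(names(cfg$isotype_proportions), G, replace = TRUE,
                    prob = cfg$isotype_proportions)
      canon <- canonical_light_v(gc3, germline_light)
      lv2 <- ifelse(runif(G) < rho, canon,
                    sample(names(usage_l$v), G, replace = TRUE,
                           prob = usage_l$v))
      heavy_rows$pairs1 <- add_heavy(gv, gj, gc3, iso, 0L)
      heavy_rows$pairs2 <- add_heavy(gv, gj, gc3, iso, 1L)
      light_rows$pairs1 <- make_light_clonotype(canon, germline_light, cfg)
      light_rows$pairs2 <- make_light_clonotype(lv2, germline_light, cfg)
    }

    # --- singleton / pool-expanded cells -------------------------------
    n_single <- n_cells - 2L * n_coherence_pairs
    pool_assign <- integer(0)
    if (n_single > 0) {
      from_pool <- if (!is.null(pool) && pool_fraction > 0)
        runif(n_single) < pool_fraction else rep(FALSE, n_single)
      n_pool <- sum(from_pool)
      n_novel <- n_single - n_pool
      if (n_novel > 0) {
        vs <- sample(names(usage_h$v), n_novel, replace = TRUE,
                     prob = usage_h$v)
        js <- sample(names(usage_h$j), n_novel, replace = TRUE,
                     prob = usage_h$j)
        isoN <- sample(names(cfg$isotype_proportions), n_novel,
                       replace = TRUE, prob = cfg$isotype_proportions)
        cd <- sample_cdr3_aa(n_novel, cfg)
        heavy_rows$novel <- add_heavy(vs, js, cd, isoN, 0L)
        light_rows$novel <- make_light_clonotype(
          sample(names(usage_l$v), n_novel, replace = TRUE,
                 prob = usage_l$v), germline_light, cfg)
      }
      if (n_pool > 0) {
        f <- pool$clonotypes$size / sum(pool$clonotypes$size)
        pool_assign <- sample.int(nrow(pool$clonotypes), n_pool,
                                  replace = TRUE, prob = f)
      }
    }

    heavy <- bind_rows(heavy_rows)
    light <- bind_rows(light_rows)
    if (nrow(heavy)) {
      heavy$clonotype_key <- clonotype_key(heavy$cdr3_nt, heavy$cdr3_aa,
                                           heavy$v_gene, heavy$j_gene,
                                           heavy$isotype)
      light$clonotype_key <- clonotype_key(light$cdr3_nt, light$cdr3_aa,
                                           light$v_gene, light$j_gene,
                                           light$isotype)
      cell_heavy <- heavy$clonotype_key
      cell_light <- light$clonotype_key
    }

    # pool-expanded cells: one fixed light partner per pool clonotype
    pool_clono <- NULL
    if (length(pool_assign)) {
      uniq <- sort(unique(pool_assign))
      pc <- pool$clonotypes[uniq, intersect(
        c("chain", "v_gene", "j_gene", "isotype", "cdr3_nt", "cdr3_aa",
          "vdj_aa", "cdr3_start", "cdr3_end", "productive",
          "clonotype_key"), names(pool$clonotypes))]
      partner <- make_light_clonotype(
        sample(names(usage_l$v), length(uniq), replace = TRUE,
               prob = usage_l$v), germline_light, cfg)
      partner$clonotype_key <- clonotype_key(partner$cdr3_nt,
                                             partner$cdr3_aa,
                                             partner$v_gene,
                                             partner$j_gene,
                                             partner$isotype)
      m <- match(pool_assign, uniq)
      cell_heavy <- c(cell_heavy, pc$clonotype_key[m])
      cell_light <- c(cell_light, partner$clonotype_key[m])
      pool_clono <- bind_rows(pc, partner)
    }

    clono <- bind_rows(heavy, light, pool_clono)
    clono <- distinct(clono, clonotype_key, .keep_all = TRUE)
    cells <- tibble(
      cell_id = sprintf("BC%06d", seq_along(cell_heavy)),
      heavy_key = cell_heavy, light_key = cell_light)
    out <- new_sc_repertoire(clono, cells, sample_id, donor)
    attr(out, "true_rho") <- rho
    out
  })
}

#' Subsample technical replicates from a single-cell repertoire
#'
#' Each replicate draws `depth` cells without replacement, independently of
#' the other replicates (the same parent cell can appear in several
#' replicates, as in repeated droplet encapsulation of one cell suspension).
#' Barcodes are prefixed per replicate so merged replicates never collide.
#'
#' @param screp parent `sc_repertoire`.
#' @param k number of replicates.
#' @param depth cells per replicate; must not exceed the parent cell count.
#' @param seed RNG seed.
#' @return list of `k` `sc_repertoire`s with `replicate_id` set.
#' @export
subsample_replicates <- function(screp, k, depth, seed = 1) {
  n <- nrow(screp$cells)
  if (depth > n) {
    stop(sprintf("depth (%d) exceeds number of cells (%d)", depth, n),
         call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(k), function(r) {
      idx <- sample.int(n, depth)
      cells <- screp$cells[idx, , drop = FALSE]
      cells$cell_id <- paste0("R", r, "_", cells$cell_id)
      keys <- unique(c(cells$heavy_key, cells$light_key))
      clono <- screp$clonotypes[screp$clonotypes$clonotype_key %in% keys, ]
      rep <- new_sc_repertoire(clono, cells,
                               sample_id = paste0(screp$sample_id, "_rep", r),
                               donor = screp$donor,
                               isotype_or_subset = screp$isotype_or_subset,
                               replicate_id = paste0("rep", r))
      rep
    })
  })
}

# ---- In-silico digestion ----------------------------------------------------

#' Protease digestion configuration
#'
#' @param protease one of `"trypsin"`, `"chymotrypsin"`,
#'   `"chymotrypsin_then_trypsin"`, `"aspn"`.
#' @param max_missed_cleavages maximum missed cleavages (default 2, the
#'   MaxQuant default).
#' @param min_length,max_length retained peptide length window (defaults 7
#'   and 40 aa).
#' @return a `digest_config`.
#' @export
digest_config <- function(protease = c("trypsin", "chymotrypsin",
                                       "chymotrypsin_then_trypsin", "aspn"),
                          max_missed_cleavages = 2, min_length = 7,
                          max_length = 40) {
  protease <- match.arg(protease)
  stopifnot(max_missed_cleavages >= 0, min_length <= max_length)
  structure(list(protease = protease,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_config")
}

# 0-based boundaries strictly inside the protein where the protease cuts.
cleavage_sites <- function(seq, protease) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2) return(integer(0))
  i <- seq_len(n - 1L)
  tryp <- i[ch[i] %in% c("K", "R") & ch[i + 1L] != "P"]
  chym <- i[ch[i] %in% c("F", "W", "Y") & ch[i + 1L] != "P"]
  aspn <- i[ch[i + 1L] == "D"]
  switch(protease,
         trypsin = tryp,
         chymotrypsin = chym,
         chymotrypsin_then_trypsin = sort(union(chym, tryp)),
         aspn = aspn)
}

#' In-silico protease digestion
#'
#' Cleavage rules: trypsin cuts after K or R unless the next residue is P;
#' chymotrypsin (high specificity) after F, W or Y unless before P; AspN
#' before D; the sequential chymotrypsin+trypsin digest uses the union of
#' both site sets. Peptides with 0 to `max_missed_cleavages` missed
#' cleavages are enumerated (a peptide with m missed cleavages is the
#' concatenation of m+1 adjacent fully-cleaved fragments), then filtered to
#' the configured length window.
#'
#' @param protein amino-acid string (standard 20-letter alphabet).
#' @param cfg a [digest_config()].
#' @return tibble with `peptide`, 0-based half-open `start`/`end` in the
#'   protein, and `missed` (missed-cleavage count).
#' @export
digest <- function(protein, cfg) {
  stopifnot(inherits(cfg, "digest_config"))
  if (!nzchar(protein)) stop("empty protein", call. = FALSE)
  assert_aa(protein, "protein")
  bounds <- c(0L, cleavage_sites(protein, cfg$protease), nchar(protein))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  nf <- length(starts)
  out <- vector("list", cfg$max_missed_cleavages + 1L)
  for (m in 0:cfg$max_missed_cleavages) {
    if (nf - m < 1L) break
    i <- seq_len(nf - m)
    out[[m + 1L]] <- tibble(start = starts[i], end = ends[i + m],
                            missed = m)
  }
  res <- bind_rows(out)
  res$peptide <- substr(rep(protein, nrow(res)), res$start + 1L, res$end)
  res <- res[nchar(res$peptide) >= cfg$min_length &
               nchar(res$peptide) <= cfg$max_length, ]
  res[, c("peptide", "start", "end", "missed")]
}

# ---- Serum / Ab-seq simulation ---------------------------------------------

default_class_switch <- function() {
  iso <- c("IgA", "IgD", "IgG", "IgM")
  m <- matrix(0, 4, 4, dimnames = list(from = iso, to = iso))
  m["IgA", ] <- c(0.25, 0.00, 0.70, 0.05)
  m["IgD", ] <- c(0.10, 0.00, 0.80, 0.10)
  m["IgG", ] <- c(0.05, 0.00, 0.95, 0.00)
  m["IgM", ] <- c(0.10, 0.00, 0.70, 0.20)
  m
}

#' Synthetic contaminant proteins
#'
#' Three fixed synthetic protein sequences standing in for the usual sample
#' contaminants (keratins, serum albumin) in proteomics searches. Purely
#' synthetic: generated once from a seeded RNG, not real protein sequences.
#'
#' @return named character vector of amino-acid sequences.
#' @export
synthetic_contaminants <- function() {
  if (is.null(.repab_env$contaminants)) {
    .repab_env$contaminants <- with_seed(7002, setNames(
      rand_aa_string(3, c(180, 150, 120)),
      c("CON_SYN_KRT1", "CON_SYN_ALB", "CON_SYN_TRYP")))
  }
  .repab_env$contaminants
}

#' Simulate a serum antibody digestion run
#'
#' Samples serum clonotypes from the reference repertoires with weight
#' `size^beta` (`beta = cfg$serum_rank_bias`; 0 gives size-independent
#' sampling), assigns each heavy-chain clonotype a serum isotype through a
#' class-switch transition matrix (light chains fall in the kappa serum
#' fraction), digests every sampled variable region under each digestion
#' configuration, and appends contaminant- and decoy-derived peptides at the
#' requested rates. Every peptide row keeps its ground-truth source label.
#'
#' @param refs a `repertoire` or list of repertoires (the personalized
#'   reference).
#' @param cfg a [simulation_config()].
#' @param digests list of [digest_config()]s (default: all four proteases).
#' @param n_serum number of serum clonotypes to sample.
#' @param class_switch 4x4 row-stochastic matrix over IgA/IgD/IgG/IgM;
#'   default biased toward IgG.
#' @param contaminants named character vector of contaminant proteins
#'   (default [synthetic_contaminants()]).
#' @param contaminant_rate,decoy_rate fraction of contaminant/decoy-derived
#'   peptides retained (0 disables).
#' @param decoys decoy set from [generate_decoy_reference()] (required if
#'   `decoy_rate > 0`).
#' @param seed overrides `cfg$seed`.
#' @return a `peptide_table` tibble (`sequence`, `protease`,
#'   `serum_fraction`, `true_source`, `true_key`, `true_identity`,
#'   `ref_isotype`, `serum_isotype`); the sampled serum table and the
#'   transition matrix are attached as attributes.
#' @export
simulate_abseq_run <- function(refs, cfg, digests = NULL, n_serum = 50,
                               class_switch = NULL,
                               contaminants = synthetic_contaminants(),
                               contaminant_rate = 0, decoy_rate = 0,
                               decoys = NULL, seed = cfg$seed) {
  if (inherits(refs, "repertoire")) refs <- list(refs)
  pool <- bind_rows(lapply(refs, function(r) {
    d <- r$clonotypes
    d$source <- r$method
    d
  }))
  pool <- distinct(pool, clonotype_key, .keep_all = TRUE)
  if (nrow(pool) == 0) stop("empty reference", call. = FALSE)
  if (is.null(digests)) {
    digests <- lapply(c("trypsin", "chymotrypsin",
                        "chymotrypsin_then_trypsin", "aspn"), digest_config)
  }
  if (is.null(class_switch)) class_switch <- default_class_switch()
  beta <- cfg$serum_rank_bias
  with_seed(seed, {
    w <- pool$size^beta
    n_serum <- min(n_serum, nrow(pool))
    idx <- sample.int(nrow(pool), n_serum, prob = w)
    serum <- pool[idx, ]
    serum$serum_isotype <- vapply(seq_len(nrow(serum)), function(i) {
      if (serum$chain[i] != "heavy") return("IgK")
      from <- serum$isotype[i]
      if (!from %in% rownames(class_switch)) from <- "IgM"
      sample(colnames(class_switch), 1, prob = class_switch[from, ])
    }, character(1))
    pep <- lapply(seq_len(nrow(serum)), function(i) {
      bind_rows(lapply(digests, function(dc) {
        d <- digest(serum$vdj_aa[i], dc)
        if (nrow(d) == 0) return(NULL)
        tibble(sequence = d$peptide, protease = dc$protease,
               serum_fraction = serum$serum_isotype[i],
               true_source = "clonotype",
               true_key = serum$clonotype_key[i],
               true_identity = aa_identity_of(serum$chain[i],
                                              serum$v_gene[i],
                                              serum$j_gene[i],
                                              serum$cdr3_aa[i]),
               ref_isotype = serum$isotype[i],
               serum_isotype = serum$serum_isotype[i])
      }))
    })
    pep <- bind_rows(pep)
    fractions <- unique(pep$serum_fraction)
    extra_pep <- function(seqs, label, rate) {
      if (rate <= 0 || length(seqs) == 0) return(NULL)
      all <- bind_rows(lapply(seq_along(seqs), function(i) {
        bind_rows(lapply(digests, function(dc) {
          d <- digest(seqs[i], dc)
          if (nrow(d) == 0) return(NULL)
          tibble(sequence = d$peptide, protease = dc$protease)
        }))
      }))
      if (nrow(all) == 0) return(NULL)
      keep <- sample.int(nrow(all), max(1L, round(rate * nrow(all))))
      all <- all[keep, ]
      all$serum_fraction <- sample(fractions, nrow(all), replace = TRUE)
      all$true_source <- label
      all$true_key <- NA_character_
      all$true_identity <- NA_character_
      all$ref_isotype <- NA_character_
      all$serum_isotype <- NA_character_
      all
    }
    pep <- bind_rows(
      pep,
      extra_pep(unname(contaminants), "contaminant", contaminant_rate),
      extra_pep(if (is.null(decoys)) character(0) else decoys$vdj_aa,
                "decoy", decoy_rate))
    pep <- distinct(pep)
    attr(pep, "serum") <- serum
    attr(pep, "class_switch") <- class_switch
    class(pep) <- c("peptide_table", class(pep))
    pep
  })
}

#' Generate a decoy reference set
#'
#' Produces `n` variable-region-like amino-acid sequences built from the
#' germline scaffolds with shuffled CDR3s, guaranteed disjoint (as full
#' strings) from the supplied true reference sequences.
#'
#' @param n number of decoys.
#' @param germline a [germline_model()].
#' @param seed RNG seed.
#' @param reference optional character vector of true reference `vdj_aa`
#'   strings to exclude.
#' @param cfg a [simulation_config()] controlling CDR3 lengths.
#' @return tibble (`decoy_id`, `vdj_aa`) of class `decoy_set`.
#' @export
generate_decoy_reference <- function(n, germline, seed = 99,
                                     reference = character(0),
                                     cfg = simulation_config()) {
  n <- as.integer(n)
  if (n == 0) {
    out <- tibble(decoy_id = character(0), vdj_aa = character(0))
    class(out) <- c("decoy_set", class(out))
    return(out)
  }
  with_seed(seed, {
    vs <- sample(germline$v_genes$scaffold, n, replace = TRUE)
    js <- sample(germline$j_genes$scaffold, n, replace = TRUE)
    cdr3 <- sample_cdr3_aa(n, cfg)
    # shuffle the CDR3 interior so decoys are CDR3-novel
    cdr3 <- vapply(cdr3, function(s) {
      mid <- strsplit(substr(s, 2, nchar(s) - 1L), "")[[1]]
      paste0("C", paste(sample(mid), collapse = ""), "W")
    }, character(1), USE.NAMES = FALSE)
    seqs <- paste0(vs, cdr3, js)
    bad <- seqs %in% reference | duplicated(seqs)
    guard <- 0L
    while (any(bad) && guard < 100L) {
      redo <- sample_cdr3_aa(sum(bad), cfg)
      seqs[bad] <- paste0(vs[bad], redo, js[bad])
      bad <- seqs %in% reference | duplicated(seqs)
      guard <- guard + 1L
    }
    out <- tibble(decoy_id = sprintf("DEC%05d", seq_len(n)), vdj_aa = seqs)
    class(out) <- c("decoy_set", class(out))
    out
  })
}
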
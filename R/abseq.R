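# Ab-seq integration: exact substring matching of serum-digest peptides
# against personalized BCR references, the four-stage filter ladder,
# clonotype identification, clonal rank, class switching, and single- and
# paired-chain V(D)J reconstruction.

#' Build a peptide-search reference index
#'
#' Collects bulk and single-cell reference clonotypes (deduplicated at the
#' (`vdj_aa`, `clonotype_key`) level within each source; identical
#' variable regions occurring in both sources are retained once per source,
#' linked through their shared amino-acid identity for "both" attribution),
#' plus decoy sequences and contaminant proteins. Decoy entries identical to
#' a true reference sequence are rejected at build time.
#'
#' @param bulk_reps,sc_reps a `repertoire` or list of repertoires per
#'   source (either may be `NULL`, not both).
#' @param decoys a `decoy_set` from [generate_decoy_reference()] or `NULL`.
#' @param contaminants named character vector of contaminant proteins or
#'   `NULL`.
#' @return a `reference_index` with the entry table and search material.
#' @export
build_reference_index <- function(bulk_reps = NULL, sc_reps = NULL,
                                  decoys = NULL, contaminants = NULL) {
  gather <- function(reps, source) {
    if (is.null(reps)) return(NULL)
    if (inherits(reps, "repertoire")) reps <- list(reps)
    bind_rows(lapply(reps, function(r) {
      d <- r$clonotypes
      d$sample_id <- r$sample_id
      d$source <- source
      d
    }))
  }
  entries <- bind_rows(gather(bulk_reps, "bulk"), gather(sc_reps, "sc"))
  if (is.null(entries) || nrow(entries) == 0) {
    stop("empty reference set", call. = FALSE)
  }
  entries <- distinct(entries, vdj_aa, clonotype_key, source,
                      .keep_all = TRUE)
  entries$aa_identity <- aa_identity_of(entries$chain, entries$v_gene,
                                        entries$j_gene, entries$cdr3_aa)
  entries$entry_id <- seq_len(nrow(entries))
  bad_span <- entries$cdr3_start < 0 | entries$cdr3_end > nchar(entries$vdj_aa)
  if (any(bad_span)) stop("invalid cdr3_span in reference", call. = FALSE)
  decoy_tbl <- if (is.null(decoys)) {
    tibble(decoy_id = character(0), vdj_aa = character(0))
  } else {
    as_tibble(decoys[, c("decoy_id", "vdj_aa")])
  }
  clash <- decoy_tbl$vdj_aa %in% entries$vdj_aa
  if (any(clash)) {
    warning(sum(clash), " decoy entr(ies) identical to a true reference ",
            "rejected", call. = FALSE)
    decoy_tbl <- decoy_tbl[!clash, , drop = FALSE]
  }
  contam_tbl <- if (is.null(contaminants)) {
    tibble(name = character(0), seq = character(0))
  } else {
    tibble(name = names(contaminants) %||%
             paste0("CON", seq_along(contaminants)),
           seq = unname(contaminants))
  }
  structure(list(entries = as_tibble(entries), decoys = decoy_tbl,
                 contaminants = contam_tbl),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf(
    "<reference_index> %d entries (%d bulk, %d sc), %d decoys, %d contaminants\n",
    nrow(x$entries), sum(x$entries$source == "bulk"),
    sum(x$entries$source == "sc"), nrow(x$decoys), nrow(x$contaminants)))
  invisible(x)
}

# Exact many-vs-many substring search: k-mer seed on the peptide prefix,
# verified by direct substring comparison. Returns every occurrence of every
# peptide in every subject (0-based half-open spans). Peptides shorter than
# the seed width are handled by brute-force scan.
find_substring_hits <- function(peptides, subjects, k = 7L) {
  if (length(peptides) == 0 || length(subjects) == 0) {
    return(tibble(pep = integer(0), subj = integer(0),
                  start = integer(0), end = integer(0)))
  }
  ns <- nchar(subjects)
  k <- min(k, max(nchar(peptides)))
  long <- which(nchar(peptides) >= k)
  short <- setdiff(seq_along(peptides), long)
  res <- list()
  if (length(long)) {
    offs <- 0:(max(ns) - k)
    seed <- rbindlist(lapply(offs, function(o) {
      ok <- which(ns >= o + k)
      if (!length(ok)) return(NULL)
      data.table(subj = ok, pos = o,
                 kmer = substr(subjects[ok], o + 1L, o + k))
    }))
    setkeyv(seed, "kmer")
    qry <- data.table(pep = long, kmer = substr(peptides[long], 1L, k),
                      len = nchar(peptides[long]))
    cand <- seed[qry, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(cand)) {
      keep <- cand$pos + cand$len <= ns[cand$subj] &
        substr(subjects[cand$subj], cand$pos + 1L, cand$pos + cand$len) ==
        peptides[cand$pep]
      cand <- cand[keep]
      res$long <- tibble(pep = cand$pep, subj = cand$subj,
                         start = cand$pos, end = cand$pos + cand$len)
    }
  }
  if (length(short)) {
    res$short <- bind_rows(lapply(short, function(i) {
      hits <- gregexpr(peptides[i], subjects, fixed = TRUE)
      bind_rows(lapply(seq_along(hits), function(s) {
        p <- hits[[s]]
        if (p[1] == -1L) return(NULL)
        tibble(pep = i, subj = s, start = as.integer(p) - 1L,
               end = as.integer(p) - 1L + nchar(peptides[i]))
      }))
    }))
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(pep = integer(0), subj = integer(0),
                  start = integer(0), end = integer(0)))
  }
  arrange(out, pep, subj, start)
}

#' Contiguous overlap between a peptide match and the CDR3
#'
#' Length of the intersection of two 0-based half-open intervals on the same
#' variable-region sequence; contiguous by construction since both are
#' intervals.
#'
#' @param match_start,match_end peptide match span.
#' @param cdr3_start,cdr3_end CDR3 span.
#' @return integer overlap length (0 when disjoint).
#' @export
cdr3_overlap_length <- function(match_start, match_end, cdr3_start,
                                cdr3_end) {
  pmax(0L, pmin(match_end, cdr3_end) - pmax(match_start, cdr3_start))
}

#' Match peptides against a reference index
#'
#' A hit is an exact contiguous occurrence of the peptide within a reference
#' variable region (optionally under I/L equivalence, since isoleucine and
#' leucine are isobaric in mass spectra). All occurrences per reference are
#' recorded with their CDR3 overlap lengths; contaminant and decoy hits are
#' flagged per peptide.
#'
#' @param peptides a `peptide_table` tibble (needs a `sequence` column) or a
#'   character vector.
#' @param index a [build_reference_index()] result.
#' @param il_equivalence treat I and L as the same letter class (default
#'   off, mirroring search engines that report a concrete residue choice).
#' @return a `peptide_matches` object: `$peptides` (one row per distinct
#'   sequence with `contaminant_hit`, `decoy_hit`, `n_ref_hits`,
#'   `max_cdr3_overlap`, `n_identities`), `$hits` (one row per occurrence),
#'   and the original table in `$table`.
#' @export
match_peptides <- function(peptides, index, il_equivalence = FALSE) {
  stopifnot(inherits(index, "reference_index"))
  tbl <- if (is.character(peptides)) tibble(sequence = peptides) else
    as_tibble(peptides)
  stopifnot("sequence" %in% names(tbl))
  seqs <- unique(tbl$sequence)
  tr <- function(x) if (il_equivalence) chartr("I", "L", x) else x
  q <- tr(seqs)
  ref <- tr(index$entries$vdj_aa)
  hits <- find_substring_hits(q, ref)
  ent <- index$entries[hits$subj, ]
  hit_tbl <- tibble(
    sequence = seqs[hits$pep],
    entry_id = ent$entry_id,
    clonotype_key = ent$clonotype_key,
    aa_identity = ent$aa_identity,
    chain = ent$chain,
    source = ent$source,
    start = hits$start,
    end = hits$end,
    cdr3_overlap_len = cdr3_overlap_length(hits$start, hits$end,
                                           ent$cdr3_start, ent$cdr3_end))
  con_hit <- rep(FALSE, length(seqs))
  if (nrow(index$contaminants)) {
    ch <- find_substring_hits(q, tr(index$contaminants$seq))
    con_hit[unique(ch$pep)] <- TRUE
  }
  dec_hit <- rep(FALSE, length(seqs))
  if (nrow(index$decoys)) {
    dh <- find_substring_hits(q, tr(index$decoys$vdj_aa))
    dec_hit[unique(dh$pep)] <- TRUE
  }
  per_pep <- if (nrow(hit_tbl)) {
    hit_tbl |>
      group_by(sequence) |>
      summarise(n_ref_hits = n_distinct(entry_id),
                max_cdr3_overlap = max(cdr3_overlap_len),
                n_identities = n_distinct(aa_identity),
                .groups = "drop")
  } else {
    tibble(sequence = character(0), n_ref_hits = integer(0),
           max_cdr3_overlap = integer(0), n_identities = integer(0))
  }
  pep_tbl <- tibble(sequence = seqs, contaminant_hit = con_hit,
                    decoy_hit = dec_hit) |>
    left_join(per_pep, by = "sequence")
  pep_tbl$n_ref_hits[is.na(pep_tbl$n_ref_hits)] <- 0L
  pep_tbl$max_cdr3_overlap[is.na(pep_tbl$max_cdr3_overlap)] <- 0L
  pep_tbl$n_identities[is.na(pep_tbl$n_identities)] <- 0L
  structure(list(peptides = pep_tbl, hits = hit_tbl, table = tbl,
                 il_equivalence = il_equivalence),
            class = "peptide_matches")
}

#' @export
print.peptide_matches <- function(x, ...) {
  cat(sprintf("<peptide_matches> %d peptides, %d reference hits\n",
              nrow(x$peptides), nrow(x$hits)))
  invisible(x)
}

#' Per-peptide reference-source attribution
#'
#' `"both"` when a peptide's reference hits include at least one bulk and
#' one single-cell entry; `"none"` (flagged undefined) when it has no BCR
#' hit.
#'
#' @param matches a [match_peptides()] result.
#' @return tibble (`sequence`, `source_attribution`).
#' @export
source_attribution <- function(matches) {
  stopifnot(inherits(matches, "peptide_matches"))
  src <- matches$hits |>
    group_by(sequence) |>
    summarise(has_bulk = any(source == "bulk"), has_sc = any(source == "sc"),
              .groups = "drop")
  out <- tibble(sequence = matches$peptides$sequence) |>
    left_join(src, by = "sequence")
  out$source_attribution <- dplyr::case_when(
    is.na(out$has_bulk) ~ "none",
    out$has_bulk & out$has_sc ~ "both",
    out$has_bulk ~ "bulk",
    TRUE ~ "sc")
  out[, c("sequence", "source_attribution")]
}

#' Apply the four-stage peptide filter ladder
#'
#' Stages: peptides not matching a contaminant protein (*all*); of those,
#' peptides hitting a reference BCR sequence and no decoy
#' (*antibody-specific*); of those, peptides whose best hit overlaps the
#' CDR3 by at least `min_cdr3_overlap` contiguous residues
#' (*CDR3-overlapping*); of those, peptides whose reference hits all share
#' one clonotype identity (*uniquely mapped*) versus several
#' (*multi-mapped*). Identity is evaluated at the amino-acid level
#' (chain, V gene, J gene, CDR3 aa) by default because peptide evidence
#' cannot distinguish nucleotide variants; cross-source hits on the same
#' identity do not make a peptide multi-mapped.
#'
#' @param matches a [match_peptides()] result.
#' @param min_cdr3_overlap minimum contiguous CDR3 overlap (default 3 aa,
#'   boundary inclusive).
#' @param unique_scope `"aa_identity"` (default) or `"clonotype_key"` for
#'   nucleotide-level uniqueness.
#' @return a `classified_matches` object: `$peptides` with logical stage
#'   columns and a `category` factor, `$ladder` (a `filter_ladder` count
#'   list), plus the hit table.
#' @export
classify_matches <- function(matches, min_cdr3_overlap = 3,
                             unique_scope = c("aa_identity",
                                              "clonotype_key")) {
  stopifnot(inherits(matches, "peptide_matches"))
  unique_scope <- match.arg(unique_scope)
  pep <- matches$peptides
  if (unique_scope == "clonotype_key") {
    nid <- matches$hits |>
      group_by(sequence) |>
      summarise(n_identities = n_distinct(clonotype_key), .groups = "drop")
    pep <- select(pep, -n_identities) |>
      left_join(nid, by = "sequence")
    pep$n_identities[is.na(pep$n_identities)] <- 0L
  }
  pep$all <- !pep$contaminant_hit
  pep$antibody_specific <- pep$all & !pep$decoy_hit & pep$n_ref_hits > 0
  pep$cdr3_overlapping <- pep$antibody_specific &
    pep$max_cdr3_overlap >= min_cdr3_overlap
  pep$uniquely_mapped <- pep$cdr3_overlapping & pep$n_identities == 1L
  pep$multi_mapped <- pep$cdr3_overlapping & !pep$uniquely_mapped
  pep$category <- dplyr::case_when(
    !pep$all ~ "contaminant",
    pep$uniquely_mapped ~ "uniquely_mapped",
    pep$multi_mapped ~ "multi_mapped",
    pep$cdr3_overlapping ~ "cdr3_overlapping",
    pep$antibody_specific ~ "antibody_specific",
    TRUE ~ "all")
  att <- source_attribution(matches)
  pep <- left_join(pep, att, by = "sequence")
  ladder <- structure(list(
    all = sum(pep$all),
    antibody_specific = sum(pep$antibody_specific),
    cdr3_overlapping = sum(pep$cdr3_overlapping),
    uniquely_mapped = sum(pep$uniquely_mapped),
    multi_mapped = sum(pep$multi_mapped)
  ), class = "filter_ladder")
  structure(list(peptides = pep, ladder = ladder, hits = matches$hits,
                 table = matches$table,
                 min_cdr3_overlap = min_cdr3_overlap,
                 unique_scope = unique_scope),
            class = "classified_matches")
}

#' @export
print.filter_ladder <- function(x, ...) {
  cat(sprintf(
    "<filter_ladder> all %d >= antibody-specific %d >= CDR3-overlapping %d = unique %d + multi %d\n",
    x$all, x$antibody_specific, x$cdr3_overlapping, x$uniquely_mapped,
    x$multi_mapped))
  invisible(x)
}

#' @export
print.classified_matches <- function(x, ...) {
  print(x$ladder)
  invisible(x)
}

#' Clonal rank of clonotypes within a reference repertoire
#'
#' Competition ("min") ranking by descending clonal size: rank 1 is the
#' most expanded clonotype; tied sizes share the smallest rank of the tie
#' group.
#'
#' @param clonotype_keys keys to rank (must exist in `rep`).
#' @param rep the reference `repertoire`.
#' @return integer ranks.
#' @export
clonal_rank <- function(clonotype_keys, rep) {
  sizes <- rep$clonotypes$size
  i <- match(clonotype_keys, rep$clonotypes$clonotype_key)
  if (anyNA(i)) {
    stop("clonotype key(s) absent from reference: ",
         paste(head(clonotype_keys[is.na(i)], 3), collapse = ", "),
         call. = FALSE)
  }
  vapply(i, function(ii) 1L + sum(sizes > sizes[ii]), integer(1))
}

# competition rank within an arbitrary entry table
rank_within <- function(sizes) {
  srt <- sort(sizes, decreasing = TRUE)
  function(s) 1L + sum(srt > s)
}

#' Reconstruct V(D)J sequences from uniquely mapped peptides
#'
#' For every uniquely mapped CDR3-overlapping peptide (or the subset named
#' in `peptides`), reports the matched clonotype's V gene, J gene, CDR3 and
#' full variable-region amino-acid sequence, with the supporting peptide's
#' match span annotated for display. The representative reference entry is
#' the largest-sized hit (ties: bulk before sc, then key order); clonal rank
#' is computed by competition ranking among same-source, same-chain index
#' entries.
#'
#' @param classified a [classify_matches()] result.
#' @param index the [build_reference_index()] used for matching.
#' @param peptides optional character vector restricting (and checking) the
#'   peptides to reconstruct; requesting a non-uniquely-mapped peptide is an
#'   error.
#' @return an `identified_clonotypes` tibble, one row per uniquely mapped
#'   peptide.
#' @export
reconstruct_vdj <- function(classified, index, peptides = NULL) {
  stopifnot(inherits(classified, "classified_matches"))
  pep <- classified$peptides
  if (!is.null(peptides)) {
    miss <- setdiff(peptides, pep$sequence)
    if (length(miss)) {
      stop("unknown peptide(s): ", paste(head(miss, 3), collapse = ", "),
           call. = FALSE)
    }
    sel <- pep[pep$sequence %in% peptides, ]
    if (any(!sel$uniquely_mapped)) {
      stop("peptide(s) not uniquely mapped: ",
           paste(head(sel$sequence[!sel$uniquely_mapped], 3),
                 collapse = ", "), call. = FALSE)
    }
    pep <- sel
  } else {
    pep <- pep[pep$uniquely_mapped, ]
  }
  if (nrow(pep) == 0) {
    return(structure(tibble(), class = c("identified_clonotypes",
                                         class(tibble()))))
  }
  hits <- classified$hits[classified$hits$sequence %in% pep$sequence, ]
  ent <- index$entries
  hits <- left_join(hits,
                    ent[, c("entry_id", "v_gene", "j_gene", "isotype",
                            "size", "vdj_aa", "cdr3_aa", "cdr3_start",
                            "cdr3_end", "sample_id")],
                    by = "entry_id")
  rankers <- list()
  rank_of <- function(source, chain, size) {
    keyid <- paste(source, chain)
    if (is.null(rankers[[keyid]])) {
      sub <- ent[ent$source == source & ent$chain == chain, ]
      rankers[[keyid]] <<- list(fn = rank_within(sub$size),
                                n = nrow(sub))
    }
    c(rankers[[keyid]]$fn(size), rankers[[keyid]]$n)
  }
  rows <- hits |>
    group_by(sequence) |>
    arrange(desc(size), source, clonotype_key, start) |>
    slice(1) |>
    ungroup()
  rk <- t(vapply(seq_len(nrow(rows)), function(i) {
    rank_of(rows$source[i], rows$chain[i], rows$size[i])
  }, integer(2)))
  out <- tibble(
    sequence = rows$sequence,
    clonotype_key = rows$clonotype_key,
    aa_identity = rows$aa_identity,
    chain = rows$chain,
    v_gene = rows$v_gene,
    j_gene = rows$j_gene,
    cdr3_aa = rows$cdr3_aa,
    vdj_aa = rows$vdj_aa,
    cdr3_start = rows$cdr3_start,
    cdr3_end = rows$cdr3_end,
    match_start = rows$start,
    match_end = rows$end,
    cdr3_overlap_len = rows$cdr3_overlap_len,
    ref_isotype = rows$isotype,
    ref_size = rows$size,
    ref_source = rows$source,
    ref_sample_id = rows$sample_id,
    clonal_rank = rk[, 1],
    rank_n = rk[, 2])
  out <- left_join(out,
                   pep[, c("sequence", "source_attribution")],
                   by = "sequence")
  structure(out, class = c("identified_clonotypes", class(tibble())))
}

#' Recover the paired chain of single-cell identifications
#'
#' For identifications whose reference hits include a single-cell source,
#' the cell barcodes carrying the identified clonotype are collected from
#' the single-cell repertoire and the partner-chain clonotypes of those
#' cells are tallied. The majority partner is reported together with an
#' ambiguity fraction (1 - majority/total); exact ties are flagged
#' ambiguous.
#'
#' @param identified an `identified_clonotypes` tibble from
#'   [reconstruct_vdj()].
#' @param screp the single-cell reference `sc_repertoire`.
#' @return `identified` restricted to sc-supported rows, with partner-chain
#'   columns (`partner_*`, `pair_ambiguity`, `pair_ambiguous`,
#'   `n_barcodes`).
#' @export
recover_paired_chain <- function(identified, screp) {
  sc_rows <- identified[identified$source_attribution %in% c("sc", "both"), ]
  if (nrow(sc_rows) == 0) {
    stop("no single-cell-supported identifications", call. = FALSE)
  }
  cl <- screp$clonotypes
  cl$aa_identity <- aa_identity_of(cl$chain, cl$v_gene, cl$j_gene,
                                   cl$cdr3_aa)
  out <- vector("list", nrow(sc_rows))
  for (i in seq_len(nrow(sc_rows))) {
    keys <- cl$clonotype_key[cl$aa_identity == sc_rows$aa_identity[i]]
    # prefer the identified clonotype's own barcodes; fall back to all
    # synonymous nucleotide variants when the representative entry is not
    # itself in the single-cell reference (source "both")
    if (sc_rows$clonotype_key[i] %in% keys) {
      keys <- sc_rows$clonotype_key[i]
    }
    is_heavy <- sc_rows$chain[i] == "heavy"
    cells <- if (is_heavy) {
      screp$cells[screp$cells$heavy_key %in% keys, ]
    } else {
      screp$cells[screp$cells$light_key %in% keys, ]
    }
    if (nrow(cells) == 0) {
      stop("no cell barcodes found for identification ",
           sc_rows$aa_identity[i], call. = FALSE)
    }
    partners <- if (is_heavy) cells$light_key else cells$heavy_key
    tab <- sort(table(partners), decreasing = TRUE)
    top <- names(tab)[1]
    tied <- sum(tab == tab[1]) > 1
    if (tied) top <- sort(names(tab)[tab == tab[1]])[1]
    p <- cl[match(top, cl$clonotype_key), ]
    out[[i]] <- tibble(
      partner_key = top,
      partner_chain = p$chain,
      partner_v_gene = p$v_gene,
      partner_j_gene = p$j_gene,
      partner_cdr3_aa = p$cdr3_aa,
      partner_vdj_aa = p$vdj_aa,
      pair_ambiguity = 1 - as.numeric(tab[1]) / length(partners),
      pair_ambiguous = tied,
      n_barcodes = length(partners))
  }
  res <- dplyr::bind_cols(sc_rows, bind_rows(out))
  structure(res, class = c("identified_clonotypes", class(tibble())))
}

#' Class-switch cross-tabulation
#'
#' Counts uniquely mapped identifications by the isotype of the BCR-seq
#' reference clonotype (rows) against the serum fraction of the supporting
#' peptide's sample (columns). Comparing rows with columns reveals class
#' switching between the B-cell compartment and the secreted serum
#' antibodies.
#'
#' @param identified an `identified_clonotypes` tibble.
#' @param peptide_table the peptide table carrying `sequence` and
#'   `serum_fraction`.
#' @param isotypes row order (default IgA, IgD, IgG, IgM).
#' @param fractions column order (default IgA, IgG, IgK, IgM).
#' @return integer matrix reference-isotype x serum-fraction.
#' @export
class_switch_table <- function(identified, peptide_table,
                               isotypes = c("IgA", "IgD", "IgG", "IgM"),
                               fractions = c("IgA", "IgG", "IgK", "IgM")) {
  m <- matrix(0L, length(isotypes), length(fractions),
              dimnames = list(ref_isotype = isotypes,
                              serum_fraction = fractions))
  if (nrow(identified) == 0) return(m)
  pt <- as_tibble(peptide_table)[, c("sequence", "serum_fraction")]
  pt <- distinct(pt)
  joined <- inner_join(identified[, c("sequence", "ref_isotype")], pt,
                       by = "sequence")
  joined <- joined[joined$ref_isotype %in% isotypes &
                     joined$serum_fraction %in% fractions, ]
  if (nrow(joined) == 0) return(m)
  tab <- table(factor(joined$ref_isotype, levels = isotypes),
               factor(joined$serum_fraction, levels = fractions))
  m[] <- as.integer(tab)
  m
}

#' Pairwise CDR3 edit distances of identified clonotypes
#'
#' Standard unit-cost Levenshtein distances between the CDR3 amino-acid
#' sequences of all unordered pairs of identified clonotypes, computed per
#' chain (heavy and light CDR3s are not compared with each other).
#'
#' @param identified an `identified_clonotypes` tibble.
#' @return tibble (`chain`, `id_a`, `id_b`, `distance`); empty with fewer
#'   than two identifications.
#' @export
cdr3_edit_distance_distribution <- function(identified) {
  empty <- tibble(chain = character(0), id_a = character(0),
                  id_b = character(0), distance = integer(0))
  if (nrow(identified) < 2) return(empty)
  ids <- distinct(as_tibble(identified)[, c("aa_identity", "chain",
                                            "cdr3_aa")])
  out <- lapply(split(ids, ids$chain), function(d) {
    if (nrow(d) < 2) return(NULL)
    dm <- adist(d$cdr3_aa)
    pr <- which(upper.tri(dm), arr.ind = TRUE)
    tibble(chain = d$chain[1],
           id_a = d$aa_identity[pr[, 1]],
           id_b = d$aa_identity[pr[, 2]],
           distance = as.integer(dm[pr]))
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) empty else res
}

# ---- MaxQuant-style peptide table I/O --------------------------------------

#' Read a MaxQuant-style peptide table
#'
#' Reads a `peptides.txt`-like TSV: requires a `Sequence` column; tolerates
#' extra columns. `Proteins` entries with `CON__`/`REV__` prefixes set the
#' contaminant/decoy prior flags; `Protease` and `Serum fraction` (or an
#' `Experiment` column formatted `<fraction>_<protease>`) populate the
#' corresponding fields.
#'
#' @param path TSV file.
#' @return a `peptide_table` tibble.
#' @export
read_peptides <- function(path) {
  df <- suppressWarnings(
    read_tsv(path, col_types = cols(.default = col_character()),
             progress = FALSE))
  if (!"Sequence" %in% names(df)) {
    stop("missing required column: Sequence", call. = FALSE)
  }
  out <- tibble(sequence = df$Sequence)
  prot <- df[["Proteins"]] %||% rep("", nrow(df))
  out$proteins <- prot
  out$maxquant_contaminant <- grepl("CON__", prot, fixed = TRUE)
  out$maxquant_decoy <- grepl("REV__", prot, fixed = TRUE)
  if (!is.null(df[["Protease"]])) {
    out$protease <- df$Protease
  } else if (!is.null(df[["Experiment"]])) {
    out$protease <- sub("^[^_]*_", "", df$Experiment)
  } else {
    out$protease <- NA_character_
  }
  if (!is.null(df[["Serum fraction"]])) {
    out$serum_fraction <- df[["Serum fraction"]]
  } else if (!is.null(df[["Experiment"]])) {
    out$serum_fraction <- sub("_.*$", "", df$Experiment)
  } else {
    out$serum_fraction <- NA_character_
  }
  class(out) <- c("peptide_table", class(out))
  out
}

#' Write a peptide table in the MaxQuant-style dialect
#'
#' @param tbl a `peptide_table` tibble (from [simulate_abseq_run()] or
#'   [read_peptides()]).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(tbl, path) {
  out <- tibble(
    Sequence = tbl$sequence,
    Proteins = tbl[["proteins"]] %||% ifelse(
      (tbl[["true_source"]] %||% rep("clonotype", nrow(tbl))) ==
        "contaminant", "CON__synthetic",
      ifelse((tbl[["true_source"]] %||% rep("", nrow(tbl))) == "decoy",
             "REV__synthetic", tbl[["true_key"]] %||% "")),
    Experiment = paste0(tbl[["serum_fraction"]] %||% "NA", "_",
                        tbl[["protease"]] %||% "NA"),
    Protease = tbl[["protease"]] %||% NA_character_,
    `Serum fraction` = tbl[["serum_fraction"]] %||% NA_character_)
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}
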
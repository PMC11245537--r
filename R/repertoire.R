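# Domain containers: a repertoire is a tibble of clonotypes plus sample
# metadata; a single-cell repertoire additionally carries the cell table
# (droplet barcode -> one heavy + one light clonotype).

CLONOTYPE_COLS <- c("clonotype_key", "chain", "v_gene", "j_gene", "isotype",
                    "cdr3_nt", "cdr3_aa", "vdj_aa", "cdr3_start", "cdr3_end",
                    "size", "productive")

#' Build a clonotype identifier
#'
#' The key concatenates the CDR3 (nucleotide sequence when available,
#' otherwise amino acid), the V gene, the J gene and the isotype, so that
#' clonotypes are separated by constant-region class and nucleotide-level
#' CDR3 variants remain distinct.
#'
#' @param cdr3_nt CDR3 nucleotide sequences (may be `NA`).
#' @param cdr3_aa CDR3 amino-acid sequences.
#' @param v_gene,j_gene gene-level calls (no allele suffix).
#' @param isotype isotype labels (`"none"` for light chains).
#' @return character vector of keys.
#' @export
clonotype_key <- function(cdr3_nt, cdr3_aa, v_gene, j_gene, isotype) {
  cdr3_nt <- rep_len(cdr3_nt, length(cdr3_aa))
  cdr3 <- ifelse(is.na(cdr3_nt) | !nzchar(cdr3_nt), cdr3_aa, cdr3_nt)
  paste(cdr3, v_gene, j_gene, isotype, sep = "|")
}

# Identity at the amino-acid level: what peptide evidence can distinguish.
aa_identity_of <- function(chain, v_gene, j_gene, cdr3_aa) {
  paste(chain, v_gene, j_gene, cdr3_aa, sep = "|")
}

fill_clonotype_defaults <- function(df) {
  df <- as_tibble(df)
  if (!"cdr3_nt" %in% names(df)) df$cdr3_nt <- NA_character_
  if (!"isotype" %in% names(df)) df$isotype <- "none"
  if (!"size" %in% names(df)) df$size <- 1L
  if (!"productive" %in% names(df)) df$productive <- TRUE
  if (!"vdj_aa" %in% names(df) || all(is.na(df$vdj_aa))) {
    df$vdj_aa <- df$cdr3_aa
  }
  if (!"cdr3_start" %in% names(df) || all(is.na(df$cdr3_start))) {
    # locate the CDR3 inside the variable region (0-based half-open)
    pos <- vapply(seq_len(nrow(df)), function(i) {
      v <- df$vdj_aa[i]
      c3 <- df$cdr3_aa[i]
      if (is.na(v) || is.na(c3)) return(NA_integer_)
      as.integer(regexpr(c3, v, fixed = TRUE)[1]) - 1L
    }, integer(1))
    df$cdr3_start <- pos
    df$cdr3_end <- pos + nchar(df$cdr3_aa)
  }
  df$cdr3_start <- as.integer(df$cdr3_start)
  df$cdr3_end <- as.integer(df$cdr3_end)
  if (!"clonotype_key" %in% names(df)) {
    df$clonotype_key <- clonotype_key(df$cdr3_nt, df$cdr3_aa,
                                      df$v_gene, df$j_gene, df$isotype)
  }
  df$size <- as.integer(df$size)
  df[, union(CLONOTYPE_COLS, names(df))]
}

validate_clonotypes <- function(df) {
  if (any(df$size < 1L)) stop("clonotype sizes must be >= 1", call. = FALSE)
  if (anyDuplicated(df$clonotype_key)) {
    stop("duplicate clonotype_key within a repertoire", call. = FALSE)
  }
  sl <- substr(df$vdj_aa, df$cdr3_start + 1L, df$cdr3_end)
  bad <- which(!is.na(df$cdr3_aa) & sl != df$cdr3_aa)
  if (length(bad)) {
    stop(sprintf("cdr3_span does not slice cdr3_aa for %d clonotype(s), e.g. %s",
                 length(bad), df$clonotype_key[bad[1]]), call. = FALSE)
  }
  invisible(df)
}

#' Construct a repertoire
#'
#' @param clonotypes a data frame with at least `chain`, `v_gene`, `j_gene`,
#'   `cdr3_aa`; optional `cdr3_nt`, `vdj_aa`, `cdr3_start`/`cdr3_end`
#'   (0-based half-open), `size`, `isotype`, `productive`. Missing pieces are
#'   derived (the key falls back to the amino-acid CDR3 when no nucleotide
#'   sequence is present; the fallback is recorded in `key_basis`).
#' @param sample_id,donor,method,isotype_or_subset,replicate_id sample
#'   metadata; `method` is `"bulk"` or `"single_cell"`.
#' @param validate check invariants (unique keys, sizes, CDR3 slice).
#' @return an object of class `repertoire`.
#' @export
new_repertoire <- function(clonotypes, sample_id, donor = sample_id,
                           method = c("bulk", "single_cell"),
                           isotype_or_subset = "all", replicate_id = NULL,
                           validate = TRUE) {
  method <- match.arg(method)
  df <- fill_clonotype_defaults(clonotypes)
  if (validate && nrow(df)) validate_clonotypes(df)
  structure(list(
    clonotypes = df,
    sample_id = sample_id,
    donor = donor,
    method = method,
    isotype_or_subset = isotype_or_subset,
    replicate_id = replicate_id,
    key_basis = if (all(is.na(df$cdr3_nt))) "cdr3_aa" else "cdr3_nt"
  ), class = "repertoire")
}

#' Construct a single-cell (paired-chain) repertoire
#'
#' @inheritParams new_repertoire
#' @param cells tibble with columns `cell_id`, `heavy_key`, `light_key`
#'   referencing `clonotype_key`s in `clonotypes`.
#' @param recompute_sizes set every clonotype's `size` to its number of
#'   distinct cell barcodes (the single-cell clonal-count definition).
#' @return an object of class `sc_repertoire` (inherits `repertoire`).
#' @export
new_sc_repertoire <- function(clonotypes, cells, sample_id,
                              donor = sample_id, isotype_or_subset = "all",
                              replicate_id = NULL, validate = TRUE,
                              recompute_sizes = TRUE) {
  cells <- as_tibble(cells)
  stopifnot(all(c("cell_id", "heavy_key", "light_key") %in% names(cells)))
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell barcodes", call. = FALSE)
  }
  df <- fill_clonotype_defaults(clonotypes)
  if (recompute_sizes) {
    cnt <- table(c(cells$heavy_key, cells$light_key))
    df$size <- as.integer(cnt[df$clonotype_key])
    if (anyNA(df$size)) {
      df <- df[!is.na(df$size), , drop = FALSE]
    }
  }
  df <- arrange(df, desc(size), clonotype_key)
  if (validate && nrow(df)) validate_clonotypes(df)
  miss <- setdiff(c(cells$heavy_key, cells$light_key), df$clonotype_key)
  if (length(miss)) {
    stop("cells reference unknown clonotypes: ", paste(head(miss, 3),
         collapse = ", "), call. = FALSE)
  }
  rep <- new_repertoire(df, sample_id, donor, "single_cell",
                        isotype_or_subset, replicate_id, validate = FALSE)
  rep$cells <- cells
  class(rep) <- c("sc_repertoire", "repertoire")
  rep
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<%s> sample '%s' (donor %s, %s%s)\n",
              paste(class(x), collapse = "/"), x$sample_id, x$donor,
              x$method,
              if (is.null(x$replicate_id)) "" else
                paste0(", replicate ", x$replicate_id)))
  cat(sprintf("  %d clonotypes, total size %d", nrow(x$clonotypes),
              sum(x$clonotypes$size)))
  if (!is.null(x$cells)) cat(sprintf(", %d cells", nrow(x$cells)))
  cat("\n")
  invisible(x)
}

#' Number of clonotypes in a repertoire
#' @param rep a `repertoire`.
#' @return integer count.
#' @export
n_clonotypes <- function(rep) nrow(rep$clonotypes)

#' Clonal frequency distribution
#'
#' Relative clonotype abundances `f_i = size_i / sum(size)`, the distribution
#' entering the Hill-diversity formula.
#'
#' @param rep a `repertoire`.
#' @return named numeric vector summing to 1.
#' @export
clonal_freqs <- function(rep) {
  s <- rep$clonotypes$size
  setNames(s / sum(s), rep$clonotypes$clonotype_key)
}

#' Unique CDR3 amino-acid sequences of a repertoire
#'
#' @param rep a `repertoire`.
#' @param chain `"heavy"`, `"kappa"`, `"lambda"`, `"light"` or `"all"`.
#' @return character vector of unique CDR3 aa strings.
#' @export
cdr3_set <- function(rep, chain = "heavy") {
  df <- rep$clonotypes
  if (chain == "light") df <- df[df$chain %in% c("kappa", "lambda"), ]
  else if (chain != "all") df <- df[df$chain == chain, ]
  unique(df$cdr3_aa)
}

# ---- AIRR I/O ---------------------------------------------------------------

strip_allele <- function(x) sub("\\*.*$", "", x)

chain_from_locus <- function(locus) {
  out <- c(IGH = "heavy", IGK = "kappa", IGL = "lambda")[toupper(locus)]
  unname(out)
}

locus_from_chain <- function(chain) {
  unname(c(heavy = "IGH", kappa = "IGK", lambda = "IGL")[chain])
}

isotype_from_c_call <- function(c_call, chain) {
  iso <- rep("none", length(chain))
  heavy <- chain == "heavy" & !is.na(c_call) & nzchar(c_call)
  cc <- toupper(c_call)
  map <- c(A = "IgA", D = "IgD", E = "IgE", G = "IgG", M = "IgM")
  sub4 <- substr(cc, 4, 4)
  # accepts IGHA1/IGHG2-style calls and already-mapped IgA-style labels
  iso[heavy & substr(cc, 1, 3) == "IGH" & sub4 %in% names(map)] <-
    map[sub4[heavy & substr(cc, 1, 3) == "IGH" & sub4 %in% names(map)]]
  pretty <- c_call %in% c("IgA", "IgD", "IgE", "IgG", "IgM")
  iso[heavy & pretty] <- c_call[heavy & pretty]
  iso
}

airr_rows_to_clonotype_fields <- function(df) {
  tibble(
    chain = chain_from_locus(df$locus),
    v_gene = strip_allele(df$v_call),
    j_gene = strip_allele(df$j_call),
    isotype = isotype_from_c_call(df[["c_call"]] %||%
                                    rep(NA_character_, nrow(df)),
                                  chain_from_locus(df$locus)),
    cdr3_nt = df[["junction"]] %||% rep(NA_character_, nrow(df)),
    cdr3_aa = df$junction_aa,
    vdj_aa = df[["sequence_alignment_aa"]] %||%
      rep(NA_character_, nrow(df)),
    productive = if (is.null(df[["productive"]])) TRUE else
      toupper(df$productive) %in% c("T", "TRUE", "1"),
    cell_id = df[["cell_id"]] %||% rep(NA_character_, nrow(df)),
    duplicate_count = suppressWarnings(
      as.integer(df[["duplicate_count"]] %||% rep(1L, nrow(df))))
  )
}

#' Read repertoires from an AIRR Rearrangement TSV
#'
#' Reads MiXCR-style clonotype tables in the AIRR standard dialect. Allele
#' suffixes (`*01`) are stripped from V/J calls, `junction_aa` becomes the
#' CDR3, and `sequence_alignment_aa` (when present) the full variable region.
#' For `method = "single_cell"`, rows are grouped by `cell_id` and droplets
#' with anything other than exactly one heavy and one light chain are
#' discarded.
#'
#' @param path TSV file with header; required columns `v_call`, `j_call`,
#'   `junction_aa`, `locus`. Optional: `junction`, `c_call`,
#'   `sequence_alignment_aa`, `duplicate_count`, `cell_id`, `productive`,
#'   `sample_id`.
#' @param method `"bulk"` or `"single_cell"`.
#' @param sample_id,donor,isotype_or_subset metadata for the returned
#'   repertoire(s); ignored when the file carries a `sample_id` column, in
#'   which case a named list of repertoires is returned.
#' @return a `repertoire` (or `sc_repertoire`), or a named list of them.
#' @export
read_airr <- function(path, method = c("bulk", "single_cell"),
                      sample_id = "sample", donor = sample_id,
                      isotype_or_subset = "all") {
  method <- match.arg(method)
  df <- suppressWarnings(
    read_tsv(path, col_types = cols(.default = col_character()),
             progress = FALSE))
  if (nrow(df) == 0) stop("empty AIRR file: ", path, call. = FALSE)
  req <- c("v_call", "j_call", "junction_aa", "locus")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required AIRR column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  build_one <- function(d, sid) {
    rows <- airr_rows_to_clonotype_fields(d)
    if (method == "bulk") {
      build_clonotypes(rows, method = "bulk", sample_id = sid, donor = donor,
                       isotype_or_subset = isotype_or_subset)
    } else {
      filter_cells_one_heavy_one_light(rows, sample_id = sid, donor = donor,
                                       isotype_or_subset = isotype_or_subset)
    }
  }
  if ("sample_id" %in% names(df)) {
    parts <- split(df, df$sample_id)
    out <- lapply(names(parts), function(s) build_one(parts[[s]], s))
    names(out) <- names(parts)
    if (length(out) == 1L) out[[1L]] else out
  } else {
    build_one(df, sample_id)
  }
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Inverse of [read_airr()] on the supported column subset: single-cell
#' repertoires are expanded to one row per (cell, chain); bulk repertoires
#' write one row per clonotype with `duplicate_count` carrying the size.
#'
#' @param rep a `repertoire` or `sc_repertoire`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  df <- rep$clonotypes
  base <- tibble(
    sequence_id = paste0("seq", seq_len(nrow(df))),
    v_call = df$v_gene,
    j_call = df$j_gene,
    c_call = ifelse(df$isotype == "none", "", df$isotype),
    locus = locus_from_chain(df$chain),
    junction = ifelse(is.na(df$cdr3_nt), "", df$cdr3_nt),
    junction_aa = df$cdr3_aa,
    sequence_alignment_aa = df$vdj_aa,
    productive = ifelse(df$productive, "T", "F"),
    duplicate_count = df$size,
    sample_id = rep$sample_id,
    clonotype_key = df$clonotype_key
  )
  if (inherits(rep, "sc_repertoire")) {
    long <- bind_rows(
      tibble(cell_id = rep$cells$cell_id, clonotype_key = rep$cells$heavy_key),
      tibble(cell_id = rep$cells$cell_id, clonotype_key = rep$cells$light_key)
    )
    out <- left_join(long, base, by = "clonotype_key")
    out$sequence_id <- paste0("seq", seq_len(nrow(out)))
    out$duplicate_count <- 1L
    out <- select(out, sequence_id, v_call, j_call, c_call, locus, junction,
                  junction_aa, sequence_alignment_aa, productive,
                  duplicate_count, cell_id, sample_id)
  } else {
    out <- select(base, -clonotype_key)
  }
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# ---- Filters ----------------------------------------------------------------

is_productive_clonotype <- function(df) {
  frame_ok <- is.na(df$cdr3_nt) | !nzchar(df$cdr3_nt) |
    nchar(df$cdr3_nt) %% 3 == 0
  no_stop <- !grepl("*", df$vdj_aa, fixed = TRUE)
  df$productive & frame_ok & no_stop
}

#' Remove out-of-frame and stop-codon clonotypes
#'
#' Keeps clonotypes that are flagged productive, contain no internal stop
#' (`*`) in the variable region, and whose CDR3 nucleotide length (when
#' present) is divisible by three. Idempotent. For single-cell repertoires,
#' cells losing a chain are dropped and sizes recomputed.
#'
#' @param rep a `repertoire` or `sc_repertoire`.
#' @return filtered object of the same class.
#' @export
filter_productive <- function(rep) {
  UseMethod("filter_productive")
}

#' @export
filter_productive.repertoire <- function(rep) {
  keep <- is_productive_clonotype(rep$clonotypes)
  rep$clonotypes <- rep$clonotypes[keep, , drop = FALSE]
  rep
}

#' @export
filter_productive.sc_repertoire <- function(rep) {
  keep <- is_productive_clonotype(rep$clonotypes)
  kept_keys <- rep$clonotypes$clonotype_key[keep]
  cells <- rep$cells[rep$cells$heavy_key %in% kept_keys &
                       rep$cells$light_key %in% kept_keys, , drop = FALSE]
  new_sc_repertoire(rep$clonotypes[keep, , drop = FALSE], cells,
                    rep$sample_id, rep$donor, rep$isotype_or_subset,
                    rep$replicate_id)
}

#' Keep droplets with exactly one heavy and one light chain
#'
#' Applies the single-cell quality rule: a droplet is retained only when it
#' contains exactly one heavy-chain and one light-chain contig. Clonotype
#' sizes are then recomputed as distinct-barcode counts.
#'
#' @param rows per-chain tibble with clonotype fields (`chain`, `v_gene`,
#'   `j_gene`, `cdr3_aa`, ...) and a `cell_id` column.
#' @param sample_id,donor,isotype_or_subset metadata.
#' @return an `sc_repertoire`.
#' @export
filter_cells_one_heavy_one_light <- function(rows, sample_id = "sample",
                                             donor = sample_id,
                                             isotype_or_subset = "all") {
  rows <- as_tibble(rows)
  stopifnot(all(c("cell_id", "chain") %in% names(rows)))
  tab <- rows |>
    group_by(cell_id) |>
    summarise(nh = sum(chain == "heavy"),
              nl = sum(chain %in% c("kappa", "lambda")), .groups = "drop")
  good <- tab$cell_id[tab$nh == 1L & tab$nl == 1L]
  rows <- rows[rows$cell_id %in% good, , drop = FALSE]
  rows <- fill_clonotype_defaults(rows)
  clono <- aggregate_clonotypes(rows, count_col = "cell_id")
  heavy <- rows[rows$chain == "heavy", c("cell_id", "clonotype_key")]
  light <- rows[rows$chain != "heavy", c("cell_id", "clonotype_key")]
  cells <- tibble(cell_id = heavy$cell_id,
                  heavy_key = heavy$clonotype_key,
                  light_key = light$clonotype_key[
                    match(heavy$cell_id, light$cell_id)])
  new_sc_repertoire(clono, cells, sample_id, donor, isotype_or_subset)
}

# Shared aggregation: group rows by clonotype key, size = distinct count of
# the given column (UMIs for bulk, barcodes for single-cell); deterministic
# order (descending size, then key).
aggregate_clonotypes <- function(rows, count_col) {
  rows |>
    group_by(clonotype_key) |>
    summarise(
      chain = first(chain), v_gene = first(v_gene), j_gene = first(j_gene),
      isotype = first(isotype), cdr3_nt = first(cdr3_nt),
      cdr3_aa = first(cdr3_aa), vdj_aa = first(vdj_aa),
      cdr3_start = first(cdr3_start), cdr3_end = first(cdr3_end),
      productive = all(productive),
      size = n_distinct(.data[[count_col]]),
      .groups = "drop") |>
    arrange(desc(size), clonotype_key)
}

#' Assemble clonotypes from annotated rows
#'
#' Rows sharing a clonotype key (CDR3 + V gene + J gene, separated by
#' isotype) are collapsed; the clonal count is the number of distinct UMIs
#' (bulk) or cell barcodes (single cell).
#'
#' @param rows tibble of per-read/per-contig annotations with clonotype
#'   fields plus `umi` (or `duplicate_count`) for bulk, `cell_id` for
#'   single cell.
#' @param method `"bulk"` or `"single_cell"`.
#' @param sample_id,donor,isotype_or_subset metadata.
#' @return a `repertoire` ordered by descending size then key.
#' @export
build_clonotypes <- function(rows, method = c("bulk", "single_cell"),
                             sample_id = "sample", donor = sample_id,
                             isotype_or_subset = "all") {
  method <- match.arg(method)
  rows <- fill_clonotype_defaults(as_tibble(rows))
  if (method == "bulk") {
    if ("umi" %in% names(rows)) {
      clono <- aggregate_clonotypes(rows, count_col = "umi")
    } else if ("duplicate_count" %in% names(rows)) {
      clono <- rows |>
        group_by(clonotype_key) |>
        summarise(
          chain = first(chain), v_gene = first(v_gene),
          j_gene = first(j_gene), isotype = first(isotype),
          cdr3_nt = first(cdr3_nt), cdr3_aa = first(cdr3_aa),
          vdj_aa = first(vdj_aa), cdr3_start = first(cdr3_start),
          cdr3_end = first(cdr3_end), productive = all(productive),
          size = sum(as.integer(duplicate_count)), .groups = "drop") |>
        arrange(desc(size), clonotype_key)
    } else {
      stop("bulk rows need a 'umi' or 'duplicate_count' column",
           call. = FALSE)
    }
    new_repertoire(clono, sample_id, donor, "bulk", isotype_or_subset)
  } else {
    if (!"cell_id" %in% names(rows)) {
      stop("single-cell rows need a 'cell_id' column", call. = FALSE)
    }
    filter_cells_one_heavy_one_light(rows, sample_id, donor,
                                     isotype_or_subset)
  }
}

# ---- Reference FASTA export -------------------------------------------------

#' Export clonotype variable regions as a reference FASTA
#'
#' One record per clonotype; the header encodes
#' `clonotype_key;sample_id;chain;method;cdr3_start-cdr3_end` so a matching
#' reader recovers the metadata losslessly. Sequences are the full
#' variable-region amino-acid strings, wrapped at 80 columns.
#'
#' @param reps a `repertoire` or list of repertoires.
#' @param path optional output file; when `NULL` only the
#'   [Biostrings::AAStringSet] is returned.
#' @return an `AAStringSet`, invisibly when `path` is given.
#' @export
export_reference_fasta <- function(reps, path = NULL) {
  if (inherits(reps, "repertoire")) reps <- list(reps)
  dfs <- lapply(reps, function(r) {
    d <- r$clonotypes
    d$sample_id <- r$sample_id
    d$method <- r$method
    d
  })
  df <- bind_rows(dfs)
  if (nrow(df)) {
    bad <- is.na(df$vdj_aa) | !nzchar(df$vdj_aa)
    if (any(bad)) {
      stop("clonotypes lacking vdj_aa: ",
           paste(head(df$clonotype_key[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  seqs <- Biostrings::AAStringSet(df$vdj_aa %||% character(0))
  names(seqs) <- sprintf("%s;%s;%s;%s;%d-%d", df$clonotype_key,
                         df$sample_id, df$chain, df$method,
                         df$cdr3_start, df$cdr3_end)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(seqs, path, width = 80L)
    return(invisible(seqs))
  }
  seqs
}

#' Read a reference FASTA written by [export_reference_fasta()]
#'
#' @param path FASTA file.
#' @return tibble with clonotype fields, `sample_id`, `method` and the
#'   variable-region sequence.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    return(tibble(clonotype_key = character(), sample_id = character(),
                  chain = character(), method = character(),
                  cdr3_start = integer(), cdr3_end = integer(),
                  vdj_aa = character()))
  }
  parts <- strsplit(names(seqs), ";", fixed = TRUE)
  span <- strsplit(vapply(parts, `[`, "", 5), "-", fixed = TRUE)
  tibble(
    clonotype_key = vapply(parts, `[`, "", 1),
    sample_id = vapply(parts, `[`, "", 2),
    chain = vapply(parts, `[`, "", 3),
    method = vapply(parts, `[`, "", 4),
    cdr3_start = as.integer(vapply(span, `[`, "", 1)),
    cdr3_end = as.integer(vapply(span, `[`, "", 2)),
    vdj_aa = unname(as.character(seqs))
  )
}
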
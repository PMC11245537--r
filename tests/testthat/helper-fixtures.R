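# Shared fixture builders: tiny hand-written clonotypes and cells, plus
# small seeded germline models reused across tests.

tiny_germlines <- function() {
  list(heavy = germline_model(n_v = 10, n_j = 3, chain = "heavy",
                              v_scaffold_length = 30,
                              j_scaffold_length = 8, seed = 11),
       light = germline_model(n_v = 20, n_j = 3, chain = "kappa",
                              v_scaffold_length = 25,
                              j_scaffold_length = 6, seed = 12))
}

# A heavy clonotype with explicit fields; vdj_aa is built around the CDR3.
mk_clono <- function(v = "IGHV1-1", j = "IGHJ1", cdr3 = "CARDW",
                     iso = "IgM", nt = NA_character_, size = 1,
                     chain = "heavy", prefix = "EVQLV", suffix = "WGQGT") {
  data.frame(chain = chain, v_gene = v, j_gene = j, isotype = iso,
             cdr3_nt = nt, cdr3_aa = cdr3,
             vdj_aa = paste0(prefix, cdr3, suffix),
             cdr3_start = nchar(prefix),
             cdr3_end = nchar(prefix) + nchar(cdr3),
             size = size, productive = TRUE,
             stringsAsFactors = FALSE)
}

# Build an sc_repertoire from per-cell heavy/light specs. Each spec row:
# hv, hcdr3, hnt (distinct nucleotide CDR3s -> distinct clonotypes), lv.
mk_sc_rep <- function(spec, sample_id = "S1", donor = "D1") {
  heavy <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    mk_clono(v = spec$hv[i], cdr3 = spec$hcdr3[i], nt = spec$hnt[i])
  }))
  light <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    mk_clono(v = spec$lv[i], j = "IGKJ1",
             cdr3 = sprintf("CQQ%02dF", i), iso = "none",
             chain = "kappa", prefix = "DIQMT", suffix = "FGQGT")
  }))
  clono <- rbind(heavy, light)
  clono$clonotype_key <- clonotype_key(clono$cdr3_nt, clono$cdr3_aa,
                                       clono$v_gene, clono$j_gene,
                                       clono$isotype)
  clono <- clono[!duplicated(clono$clonotype_key), ]
  hkeys <- clonotype_key(spec$hnt, spec$hcdr3, spec$hv, "IGHJ1", "IgM")
  lkeys <- clonotype_key(NA, sprintf("CQQ%02dF", seq_len(nrow(spec))),
                         spec$lv, "IGKJ1", "none")
  cells <- data.frame(cell_id = sprintf("BC%03d", seq_len(nrow(spec))),
                      heavy_key = hkeys, light_key = lkeys,
                      stringsAsFactors = FALSE)
  new_sc_repertoire(clono, cells, sample_id = sample_id, donor = donor)
}

cell_view <- function(screp) {
  cl <- screp$clonotypes
  h <- match(screp$cells$heavy_key, cl$clonotype_key)
  l <- match(screp$cells$light_key, cl$clonotype_key)
  data.frame(hv = cl$v_gene[h], hc = cl$cdr3_aa[h],
             hkey = cl$clonotype_key[h], lv = cl$v_gene[l],
             stringsAsFactors = FALSE)
}

random_cdr3_sets <- function(n_pairs, max_size = 50, seed = 1) {
  withr::with_seed(seed, {
    universe <- paste0("C", replicate(200, paste(
      sample(c("A", "R", "S", "T", "W", "G"), 6, replace = TRUE),
      collapse = "")), "W")
    lapply(seq_len(n_pairs), function(i) {
      list(A = sample(universe, sample.int(max_size, 1)),
           B = sample(universe, sample.int(max_size, 1)))
    })
  })
}
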
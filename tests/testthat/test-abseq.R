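# Peptide-to-clonotype mapping: index construction, substring matching,
# the filter ladder, attribution, ranking, reconstruction, pairing,
# class switching and CDR3 distances.

abseq_fixture <- function(seed = 43, n_bulk = 120, n_cells = 80,
                          n_serum = 15, rho = 1, contaminant_rate = 0,
                          decoy_rate = 0, n_decoys = 50) {
  g <- tiny_germlines()
  cfg <- simulation_config(n_clonotypes = n_bulk,
                           light_chain_coherence = rho, seed = seed)
  bulk <- simulate_repertoire(cfg, g$heavy, donor = "D1", seed = seed)
  sc_cfg <- simulation_config(n_clonotypes = n_cells,
                              light_chain_coherence = rho, seed = seed)
  sc <- simulate_paired_repertoire(sc_cfg, g$heavy, g$light, donor = "D1",
                                   seed = seed + 1,
                                   n_coherence_pairs = n_cells %/% 10)
  decoys <- generate_decoy_reference(n_decoys, g$heavy, seed = seed + 2,
                                     reference = c(bulk$clonotypes$vdj_aa,
                                                   sc$clonotypes$vdj_aa))
  ptab <- simulate_abseq_run(list(bulk, sc), cfg, n_serum = n_serum,
                             contaminant_rate = contaminant_rate,
                             decoy_rate = decoy_rate, decoys = decoys,
                             seed = seed + 3)
  index <- build_reference_index(bulk_reps = bulk, sc_reps = sc,
                                 decoys = decoys,
                                 contaminants = synthetic_contaminants())
  list(g = g, cfg = cfg, bulk = bulk, sc = sc, decoys = decoys,
       ptab = ptab, index = index)
}

test_that("reference index deduplicates, links sources, rejects bad decoys", {
  bulk_rows <- rbind(mk_clono(cdr3 = "CARAAW"), mk_clono(cdr3 = "CARBBW"),
                     mk_clono(cdr3 = "CARCCW"))
  sc_rows <- rbind(mk_clono(cdr3 = "CARAAW"), mk_clono(cdr3 = "CARDDW"))
  bulk <- new_repertoire(bulk_rows, "b")
  sc_cells <- data.frame(cell_id = c("c1", "c2"),
                         heavy_key = clonotype_key(NA, c("CARAAW", "CARDDW"),
                                                   "IGHV1-1", "IGHJ1",
                                                   "IgM"),
                         light_key = clonotype_key(NA, c("CQQ1F", "CQQ2F"),
                                                   "IGKV1", "IGKJ1", "none"))
  sc_clono <- rbind(sc_rows,
                    mk_clono(v = "IGKV1", j = "IGKJ1", cdr3 = "CQQ1F",
                             iso = "none", chain = "kappa"),
                    mk_clono(v = "IGKV1", j = "IGKJ1", cdr3 = "CQQ2F",
                             iso = "none", chain = "kappa"))
  screp <- new_sc_repertoire(sc_clono, sc_cells, "s")
  idx <- build_reference_index(bulk_reps = bulk, sc_reps = screp)
  # 3 bulk + 4 sc entries; the shared vdj_aa is kept once per source
  expect_equal(nrow(idx$entries), 7L)
  shared <- idx$entries[idx$entries$cdr3_aa == "CARAAW", ]
  expect_setequal(shared$source, c("bulk", "sc"))
  expect_equal(dplyr::n_distinct(shared$aa_identity), 1L)
  # decoy equal to a true reference is rejected with a warning
  dec <- tibble::tibble(decoy_id = "DEC1",
                        vdj_aa = bulk$clonotypes$vdj_aa[1])
  class(dec) <- c("decoy_set", class(dec))
  expect_warning(idx2 <- build_reference_index(bulk_reps = bulk,
                                               decoys = dec), "rejected")
  expect_equal(nrow(idx2$decoys), 0L)
  expect_error(build_reference_index(), "empty")
})

test_that("peptide matching agrees with a brute-force substring scan", {
  fx <- abseq_fixture(n_bulk = 25, n_cells = 20, n_serum = 6)
  peps <- unique(fx$ptab$sequence)
  peps <- peps[seq_len(min(60, length(peps)))]
  m <- match_peptides(peps, fx$index)
  want <- oracle_substring_scan(peps, fx$index$entries$vdj_aa)
  got <- m$hits[order(match(m$hits$sequence, peps), m$hits$entry_id,
                      m$hits$start), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$entry_id, fx$index$entries$entry_id[want$subj])
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("matching records full-length, absent, and repeated occurrences", {
  ref <- new_repertoire(rbind(
    mk_clono(cdr3 = "CARAAW", prefix = "MSTAB", suffix = "GGQGT"),
    mk_clono(cdr3 = "CDEFGW", prefix = "ABABA", suffix = "BABAB")),
    "r", validate = TRUE)
  idx <- build_reference_index(bulk_reps = ref)
  full <- ref$clonotypes$vdj_aa[1]
  m <- match_peptides(c(full, "QQQQQQQ", "ABAB"), idx)
  h1 <- m$hits[m$hits$sequence == full, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(c(h1$start, h1$end), c(0L, nchar(full)))
  expect_equal(m$peptides$n_ref_hits[m$peptides$sequence == "QQQQQQQ"], 0L)
  # "ABAB" occurs twice within the one ABABA...BABAB reference
  h3 <- m$hits[m$hits$sequence == "ABAB", ]
  expect_equal(nrow(h3), 2L)
  expect_equal(dplyr::n_distinct(h3$entry_id), 1L)
  expect_equal(h3$start, c(0L, 12L))
})

test_that("I/L equivalence folds the letter classes when enabled", {
  ref <- new_repertoire(mk_clono(cdr3 = "CARILW", prefix = "MSTAB",
                                 suffix = "GGQGT"), "r")
  idx <- build_reference_index(bulk_reps = ref)
  off <- match_peptides("ARLLW", idx)
  expect_equal(nrow(off$hits), 0L)
  on <- match_peptides("ARLLW", idx, il_equivalence = TRUE)
  expect_equal(nrow(on$hits), 1L)
})

test_that("cdr3 overlap length is exact interval arithmetic", {
  expect_equal(cdr3_overlap_length(10L, 25L, 20L, 35L), 5L)
  expect_equal(cdr3_overlap_length(0L, 5L, 10L, 20L), 0L)
  # match strictly inside a 12-residue CDR3: overlap = peptide length
  expect_equal(cdr3_overlap_length(22L, 30L, 20L, 32L), 8L)
  expect_equal(cdr3_overlap_length(c(0L, 5L), c(4L, 9L), 2L, 7L),
               c(2L, 2L))
})

test_that("the filter ladder applies the four stages with a 3-aa boundary", {
  ref <- new_repertoire(rbind(
    mk_clono(cdr3 = "CARDEFGHW", prefix = "MSTABCDKL",
             suffix = "GGQGTLVTV"),
    mk_clono(cdr3 = "CWWDEFGHW", prefix = "MSTABCDKL",
             suffix = "GGQGTLVTV")), "r")
  idx <- build_reference_index(bulk_reps = ref,
                               contaminants = c(CON1 = "QQQQQQQQQQ"))
  v <- ref$clonotypes$vdj_aa[ref$clonotypes$cdr3_aa == "CARDEFGHW"]
  s <- ref$clonotypes$cdr3_start[1]
  pep_over3 <- substr(v, s + 3 - 4, s + 3)   # overlaps CDR3 by exactly 3
  pep_over2 <- substr(v, s + 2 - 4, s + 2)   # overlaps by 2
  pep_shared <- "DEFGHWGGQ"                  # crosses both CDR3s
  pep_con <- "QQQQQQQ"
  m <- match_peptides(c(pep_over3, pep_over2, pep_shared, pep_con), idx)
  cl <- classify_matches(m, min_cdr3_overlap = 3)
  p <- cl$peptides
  cat3 <- p$category[p$sequence == pep_over3]
  expect_equal(cat3, "uniquely_mapped")
  expect_equal(p$category[p$sequence == pep_over2], "antibody_specific")
  expect_equal(p$category[p$sequence == pep_shared], "multi_mapped")
  expect_equal(p$category[p$sequence == pep_con], "contaminant")
  lad <- cl$ladder
  expect_equal(lad$all, 3L)
  expect_equal(lad$antibody_specific, 3L)
  expect_equal(lad$cdr3_overlapping, 2L)
  expect_equal(lad$uniquely_mapped, 1L)
  expect_equal(lad$multi_mapped, 1L)
})

test_that("ladder identities hold and decoy-only peptides never pass", {
  fx <- abseq_fixture(contaminant_rate = 0.1, decoy_rate = 0.1)
  m <- match_peptides(fx$ptab, fx$index)
  cl <- classify_matches(m)
  lad <- cl$ladder
  expect_gte(lad$all, lad$antibody_specific)
  expect_gte(lad$antibody_specific, lad$cdr3_overlapping)
  expect_equal(lad$cdr3_overlapping, lad$uniquely_mapped + lad$multi_mapped)
  p <- cl$peptides
  decoy_only <- p$decoy_hit & p$n_ref_hits == 0
  expect_gt(sum(p$decoy_hit), 0)  # decoy peptides were planted
  expect_false(any(p$antibody_specific & decoy_only))
  expect_false(any(p$antibody_specific & p$decoy_hit))
})

test_that("source attribution distinguishes bulk, sc and both", {
  shared <- mk_clono(cdr3 = "CARSHAREDW", prefix = "MSTABCDKL",
                     suffix = "GGQGTLVTV")
  bulk_only <- mk_clono(cdr3 = "CARBULKW", prefix = "QWERTYQWE",
                        suffix = "TYQWERTYQ")
  bulk <- new_repertoire(rbind(shared, bulk_only), "b")
  sc_h <- rbind(shared, mk_clono(cdr3 = "CARSCW", prefix = "LKJHGFDSA",
                                 suffix = "ASDFGHJKL"))
  sc_l <- do.call(rbind, lapply(1:2, function(i) {
    mk_clono(v = "IGKV1", j = "IGKJ1", cdr3 = sprintf("CQQX%dF", i),
             iso = "none", chain = "kappa")
  }))
  keys_h <- clonotype_key(NA, c("CARSHAREDW", "CARSCW"), "IGHV1-1",
                          "IGHJ1", "IgM")
  keys_l <- clonotype_key(NA, sprintf("CQQX%dF", 1:2), "IGKV1", "IGKJ1",
                          "none")
  screp <- new_sc_repertoire(rbind(sc_h, sc_l),
                             data.frame(cell_id = c("c1", "c2"),
                                        heavy_key = keys_h,
                                        light_key = keys_l), "s")
  idx <- build_reference_index(bulk_reps = bulk, sc_reps = screp)
  m <- match_peptides(c("ARSHAREDWGG", "ARBULKWTY", "ARSCWAS", "ZZZZZZZ"),
                      idx)
  att <- source_attribution(m)
  expect_equal(att$source_attribution,
               c("both", "bulk", "sc", "none"))
})

test_that("clonal rank uses competition ranking", {
  rows <- do.call(rbind, lapply(1:4, function(i) {
    mk_clono(cdr3 = sprintf("CAR%dW", i), size = c(10, 5, 5, 1)[i])
  }))
  rep1 <- new_repertoire(rows, "r")
  ordered_keys <- rep1$clonotypes$clonotype_key[
    order(-rep1$clonotypes$size)]
  expect_equal(clonal_rank(ordered_keys, rep1), c(1L, 2L, 2L, 4L))
  single <- new_repertoire(mk_clono(), "one")
  expect_equal(clonal_rank(single$clonotypes$clonotype_key, single), 1L)
  expect_error(clonal_rank("missing|key", rep1), "absent")
})

test_that("reconstruction returns the reference sequence and match span", {
  fx <- abseq_fixture()
  cl <- classify_matches(match_peptides(fx$ptab, fx$index))
  ident <- reconstruct_vdj(cl, fx$index)
  expect_gt(nrow(ident), 0)
  ent <- fx$index$entries
  for (i in seq_len(min(nrow(ident), 25))) {
    e <- ent[ent$clonotype_key == ident$clonotype_key[i] &
               ent$source == ident$ref_source[i], ]
    expect_equal(ident$vdj_aa[i], e$vdj_aa[1])
    expect_equal(substr(ident$vdj_aa[i], ident$match_start[i] + 1,
                        ident$match_end[i]), ident$sequence[i])
  }
  # requesting a non-unique peptide is an error
  multi <- cl$peptides$sequence[cl$peptides$multi_mapped]
  if (length(multi)) {
    expect_error(reconstruct_vdj(cl, fx$index, peptides = multi[1]),
                 "not uniquely mapped")
  }
  expect_error(reconstruct_vdj(cl, fx$index, peptides = "NOPE"),
               "unknown")
})

test_that("identification is sound: every unique peptide finds its source", {
  fx <- abseq_fixture(seed = 47, n_bulk = 150, n_cells = 100, n_serum = 25)
  cl <- classify_matches(match_peptides(fx$ptab, fx$index))
  ident <- reconstruct_vdj(cl, fx$index)
  truth <- fx$ptab[match(ident$sequence, fx$ptab$sequence), ]
  expect_true(all(ident$aa_identity == truth$true_identity))
})

test_that("paired-chain recovery reports the majority with ambiguity", {
  # one heavy clonotype carried by 3 cells: lights {L1, L1, L2}
  heavy <- mk_clono(cdr3 = "CARPAIRW", prefix = "MSTABCDKL",
                    suffix = "GGQGTLVTV")
  lights <- do.call(rbind, lapply(1:2, function(i) {
    mk_clono(v = paste0("IGKV", i), j = "IGKJ1", cdr3 = sprintf("CQQ%dF", i),
             iso = "none", chain = "kappa")
  }))
  hkey <- clonotype_key(NA, "CARPAIRW", "IGHV1-1", "IGHJ1", "IgM")
  lkeys <- clonotype_key(NA, sprintf("CQQ%dF", 1:2), paste0("IGKV", 1:2),
                         "IGKJ1", "none")
  cells <- data.frame(cell_id = c("c1", "c2", "c3"),
                      heavy_key = hkey,
                      light_key = lkeys[c(1, 1, 2)])
  screp <- new_sc_repertoire(rbind(heavy, lights), cells, "s")
  idx <- build_reference_index(sc_reps = screp)
  cl <- classify_matches(match_peptides("ARPAIRWGG", idx))
  ident <- reconstruct_vdj(cl, idx)
  pc <- recover_paired_chain(ident, screp)
  expect_equal(pc$partner_key, lkeys[1])
  expect_equal(pc$pair_ambiguity, 1 / 3)
  expect_false(pc$pair_ambiguous)
  expect_equal(pc$n_barcodes, 3L)
  # unanimity: ambiguity 0
  cells0 <- cells[1:2, ]
  screp0 <- new_sc_repertoire(rbind(heavy, lights[1, ]), cells0, "s0")
  idx0 <- build_reference_index(sc_reps = screp0)
  cl0 <- classify_matches(match_peptides("ARPAIRWGG", idx0))
  pc0 <- recover_paired_chain(reconstruct_vdj(cl0, idx0), screp0)
  expect_equal(pc0$pair_ambiguity, 0)
  # bulk-only identifications cannot be paired
  fxb <- abseq_fixture(n_cells = 20, n_serum = 5)
  idx_b <- build_reference_index(bulk_reps = fxb$bulk)
  clb <- classify_matches(match_peptides(fxb$ptab, idx_b))
  identb <- reconstruct_vdj(clb, idx_b)
  if (nrow(identb)) {
    expect_error(recover_paired_chain(identb, fxb$sc),
                 "no single-cell-supported")
  }
})

test_that("class switching is recovered; identity matrix gives a diagonal", {
  g <- tiny_germlines()
  cfg <- simulation_config(n_clonotypes = 120, seed = 53)
  bulk <- simulate_repertoire(cfg, g$heavy)
  ident_m <- diag(4)
  dimnames(ident_m) <- list(from = c("IgA", "IgD", "IgG", "IgM"),
                            to = c("IgA", "IgD", "IgG", "IgM"))
  ptab <- simulate_abseq_run(bulk, cfg, n_serum = 40,
                             class_switch = ident_m, seed = 54)
  idx <- build_reference_index(bulk_reps = bulk)
  cl <- classify_matches(match_peptides(ptab, idx))
  ident <- reconstruct_vdj(cl, idx)
  tab <- class_switch_table(ident, ptab,
                            fractions = c("IgA", "IgD", "IgG", "IgM"))
  expect_gt(sum(tab), 0)
  expect_equal(sum(diag(tab)), sum(tab))
  # all-to-IgG switching concentrates mass in the IgG column
  allg <- ident_m * 0
  allg[, "IgG"] <- 1
  ptab_g <- simulate_abseq_run(bulk, cfg, n_serum = 40,
                               class_switch = allg, seed = 55)
  cl_g <- classify_matches(match_peptides(ptab_g, idx))
  tab_g <- class_switch_table(reconstruct_vdj(cl_g, idx), ptab_g)
  expect_equal(sum(tab_g[, "IgG"]), sum(tab_g))
  # empty identification set -> all-zero matrix
  empty <- class_switch_table(reconstruct_vdj(cl, idx,
                                              peptides = character(0)),
                              ptab)
  expect_true(all(empty == 0))
})

test_that("CDR3 edit distances follow the Levenshtein oracle", {
  ids <- tibble::tibble(
    aa_identity = c("h|a", "h|b", "h|c", "k|a"),
    chain = c("heavy", "heavy", "heavy", "kappa"),
    cdr3_aa = c("CARW", "CASW", "kitten", "CQQF"))
  d <- cdr3_edit_distance_distribution(ids)
  expect_equal(nrow(d), 3L)  # heavy pairs only; single kappa dropped
  get <- function(a, b) d$distance[(d$id_a == a & d$id_b == b) |
                                     (d$id_a == b & d$id_b == a)]
  expect_equal(get("h|a", "h|b"), 1L)
  ids2 <- tibble::tibble(aa_identity = c("x", "y"),
                         chain = "heavy",
                         cdr3_aa = c("kitten", "sitting"))
  expect_equal(cdr3_edit_distance_distribution(ids2)$distance, 3L)
  ids3 <- tibble::tibble(aa_identity = c("x", "y"), chain = "heavy",
                         cdr3_aa = c("CARW", "CARW"))
  expect_equal(cdr3_edit_distance_distribution(ids3)$distance, 0L)
  expect_equal(nrow(cdr3_edit_distance_distribution(ids3[1, ])), 0L)
})

test_that("peptide tables round-trip through the MaxQuant dialect", {
  fx <- abseq_fixture(n_bulk = 40, n_cells = 20, n_serum = 5,
                      contaminant_rate = 0.05)
  path <- tempfile(fileext = ".tsv")
  write_peptides(fx$ptab, path)
  back <- read_peptides(path)
  expect_equal(back$sequence, fx$ptab$sequence)
  expect_equal(back$protease, fx$ptab$protease)
  expect_equal(back$serum_fraction, fx$ptab$serum_fraction)
  expect_equal(back$maxquant_contaminant,
               fx$ptab$true_source == "contaminant")
  expect_error(read_peptides(tempfile(fileext = ".tsv")))
  bad <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(NotSequence = "A"), bad)
  expect_error(read_peptides(bad), "Sequence")
})
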
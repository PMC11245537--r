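# Internal helpers: amino-acid alphabet, deterministic hashing, seeded RNG,
# and the fixed codon table used for deterministic back-translation.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-donor RNG streams and canonical light-gene assignments that must agree
# across independently simulated samples.
hash_string <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (ci in utf8ToInt(s)) h <- (h * 131 + ci) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

assert_aa <- function(x, what = "sequence") {
  bad <- regexpr(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 substr(x[i], bad[i], bad[i]), bad[i], what), call. = FALSE)
  }
  invisible(x)
}

rand_aa_string <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_STANDARD, len[min(i, length(len))], replace = TRUE),
          collapse = "")
  }, character(1))
}

# Codon lists per amino acid, lexicographically sorted so that codon index 1
# ("variant 0") is a fixed, reproducible choice.
codons_by_aa <- function() {
  if (is.null(.repab_env$codons)) {
    gc <- Biostrings::GENETIC_CODE
    byaa <- split(names(gc), unname(gc))
    .repab_env$codons <- lapply(byaa, sort)
  }
  .repab_env$codons
}

# Deterministic back-translation. variant = 0 picks the lexicographically
# first codon at every position; variant k > 0 is decoded as a mixed-radix
# number over per-position codon counts, yielding distinct nucleotide
# sequences for the same amino-acid string (synonymous variants).
back_translate <- function(aa, variant = 0L) {
  tab <- codons_by_aa()
  if (all(variant == 0L)) {
    first <- vapply(tab, `[`, character(1), 1L)
    return(vapply(strsplit(aa, "", fixed = TRUE), function(ch) {
      paste(first[ch], collapse = "")
    }, character(1), USE.NAMES = FALSE))
  }
  mapply(function(s, v) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(length(ch))
    for (i in seq_along(ch)) {
      cods <- tab[[ch[i]]]
      k <- length(cods)
      d <- v %% k
      v <- v %/% k
      out[i] <- cods[d + 1L]
    }
    paste(out, collapse = "")
  }, aa, rep_len(as.integer(variant), length(aa)), USE.NAMES = FALSE)
}

# Standard-code translation of an in-frame nucleotide string.
translate_nt <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    stopifnot(nchar(s) %% 3 == 0)
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(gc[cods], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
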
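# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package
# internals: plain loops and set scans.

oracle_jaccard <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  if (length(A) == 0 && length(B) == 0) return(NA_real_)
  inter <- 0
  for (a in A) if (any(b_eq <- (B == a))) inter <- inter + 1
  inter / (length(A) + length(B) - inter)
}

# All-pairs light-chain-coherence enumeration on the cell level.
# cells: data.frame with hv, hc, hkey, lv (one row per cell).
oracle_lcc_within <- function(cells) {
  n <- nrow(cells)
  eligible <- 0
  coherent <- 0
  in_pair <- rep(FALSE, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (cells$hv[i] == cells$hv[j] && cells$hc[i] == cells$hc[j] &&
            cells$hkey[i] != cells$hkey[j]) {
          eligible <- eligible + 1
          in_pair[i] <- in_pair[j] <- TRUE
          if (cells$lv[i] == cells$lv[j]) coherent <- coherent + 1
        }
      }
    }
  }
  list(eligible = eligible, coherent = coherent,
       pct = if (eligible > 0) 100 * coherent / eligible else NA_real_,
       n_cells = sum(in_pair))
}

oracle_lcc_across <- function(cells_a, cells_b) {
  eligible <- 0
  coherent <- 0
  for (i in seq_len(nrow(cells_a))) {
    for (j in seq_len(nrow(cells_b))) {
      if (cells_a$hv[i] == cells_b$hv[j] &&
          cells_a$hc[i] == cells_b$hc[j]) {
        eligible <- eligible + 1
        if (cells_a$lv[i] == cells_b$lv[j]) coherent <- coherent + 1
      }
    }
  }
  list(eligible = eligible, coherent = coherent,
       pct = if (eligible > 0) 100 * coherent / eligible else NA_real_)
}

# Brute-force exact substring scan: every occurrence of every peptide in
# every subject, 0-based half-open spans.
oracle_substring_scan <- function(peptides, subjects) {
  out <- list()
  for (p in seq_along(peptides)) {
    lp <- nchar(peptides[p])
    for (s in seq_along(subjects)) {
      ls <- nchar(subjects[s])
      if (lp > ls) next
      for (st in 0:(ls - lp)) {
        if (substr(subjects[s], st + 1, st + lp) == peptides[p]) {
          out[[length(out) + 1]] <- data.frame(pep = p, subj = s,
                                               start = st, end = st + lp)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(pep = integer(0), subj = integer(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, out)
}

# Exact two-sided rank-sum p value by full enumeration of rank assignments.
oracle_exact_wilcoxon <- function(x, y) {
  nx <- length(x)
  all_vals <- c(x, y)
  ranks <- rank(all_vals)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(all_vals), nx)
  ws <- apply(combs, 2, function(idx) {
    sum(ranks[idx]) - nx * (nx + 1) / 2
  })
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Hill diversity evaluated directly from the formula.
oracle_hill <- function(f, a) {
  f <- f[f > 0]
  if (abs(a - 1) < 1e-12) exp(-sum(f * log(f))) else
    sum(f^a)^(1 / (1 - a))
}
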
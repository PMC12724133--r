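# Brute-force alignment oracle, independent of the package's DP kernel.
#
# score_moves() prices a complete move string (D = pair, U = query-only,
# L = ref-only) under the affine model cost(L) = open + (L-1) * ext, with
# terminal gap runs free in ends-free mode. enum_alignments() enumerates
# every global alignment of two short sequences; oracle_best() returns the
# maximum achievable score. Feasible for sequences up to ~8 residues.

score_moves <- function(q, r, moves, match, mismatch, open, ext,
                        free_ends = FALSE) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  mv <- strsplit(moves, "")[[1]]
  stopifnot(sum(mv != "L") == length(qc), sum(mv != "U") == length(rc))
  runs <- rle(mv)
  k <- length(runs$values)
  free <- rep(FALSE, k)
  if (free_ends) {
    if (runs$values[1] != "D") free[1] <- TRUE
    if (runs$values[k] != "D") free[k] <- TRUE
  }
  score <- 0; qi <- 0; rj <- 0; ri <- 0
  for (t in seq_len(k)) {
    v <- runs$values[t]; len <- runs$lengths[t]
    if (v == "D") {
      for (s in seq_len(len)) {
        qi <- qi + 1; rj <- rj + 1
        score <- score + if (qc[qi] == rc[rj]) match else mismatch
      }
    } else {
      if (v == "U") qi <- qi + len else rj <- rj + len
      if (!free[t]) score <- score - (open + (len - 1) * ext)
    }
  }
  score
}

enum_alignments <- function(n, m) {
  out <- character(0)
  rec <- function(i, j, acc) {
    if (i == n && j == m) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    if (i < n && j < m) rec(i + 1, j + 1, paste0(acc, "D"))
    if (i < n) rec(i + 1, j, paste0(acc, "U"))
    if (j < m) rec(i, j + 1, paste0(acc, "L"))
  }
  rec(0L, 0L, "")
  out
}

oracle_best <- function(q, r, match, mismatch, open, ext, free_ends = FALSE) {
  als <- enum_alignments(nchar(q), nchar(r))
  max(vapply(als, function(mv)
    score_moves(q, r, mv, match, mismatch, open, ext, free_ends), numeric(1)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
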
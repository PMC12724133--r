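#' Compact protein-variant labels
#'
#' Pure function of (kind, consensus position, residues): substitutions are
#' `N2H`, single-residue deletions `E34del`, multi-residue deletions
#' `E34_K36del`, insertions `62insK` (residues inserted before that
#' consensus position).
#'
#' @param kind `"substitution"`, `"deletion"` or `"insertion"`.
#' @param con_position 1-based consensus position (first deleted residue for
#'   deletions; the consensus residue the insertion precedes for insertions,
#'   consensus length + 1 for a terminal extension).
#' @param ref_aa consensus residue(s) (empty for insertions).
#' @param alt_aa replacement/inserted residue(s) (empty for deletions).
#' @return Label string.
#' @export
variant_label <- function(kind, con_position, ref_aa, alt_aa) {
  switch(kind,
    substitution = paste0(ref_aa, con_position, alt_aa),
    deletion = if (nchar(ref_aa) == 1L) {
      paste0(ref_aa, con_position, "del")
    } else {
      paste0(substr(ref_aa, 1L, 1L), con_position, "_",
             substr(ref_aa, nchar(ref_aa), nchar(ref_aa)),
             con_position + nchar(ref_aa) - 1L, "del")
    },
    insertion = paste0(con_position, "ins", alt_aa),
    stop("unknown variant kind: ", kind))
}

#' Call protein variants against the consensus Rec
#'
#' Globally aligns a full-length (or extended) Rec protein to the consensus
#' with BLOSUM62 scores and penalised end gaps, then reads off the edit
#' script: mismatched columns become substitutions, consensus-only runs
#' deletions, query-only runs insertions. Positions are numbered on the
#' consensus, so a deletion at consensus residue 34 is `E34del` regardless of
#' downstream shifts. NLS/NES overlap flags come from the profile intervals.
#'
#' @param aa the mature protein (no stops); must classify as `full_length`
#'   or `extended` against `con`.
#' @param con a [con_rec_profile()].
#' @return A `data.frame`: kind, con_position, ref_aa, alt_aa, label,
#'   in_nls, in_nes (zero rows for a consensus-identical protein).
#' @export
call_variants <- function(aa, con) {
  stopifnot(inherits(con, "con_rec_profile"))
  if (grepl("*", aa, fixed = TRUE))
    stop("protein contains stop codons; classify_protein() first and pass the mature sequence")
  cls <- classify_protein(aa, con)
  if (!cls$category %in% c("full_length", "extended"))
    stop("protein classifies as '", cls$category,
         "'; variant calling is defined for full_length/extended proteins only")

  map <- align_proteins(aa, con$aa, free_end_gaps = FALSE)
  qc <- strsplit(aa, "")[[1]]
  rc <- strsplit(con$aa, "")[[1]]
  mv <- strsplit(map$moves, "")[[1]]

  out <- list()
  add <- function(kind, pos, ref_aa, alt_aa) {
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind, con_position = pos, ref_aa = ref_aa, alt_aa = alt_aa,
      label = variant_label(kind, pos, ref_aa, alt_aa),
      stringsAsFactors = FALSE)
  }
  i <- 1L
  n <- length(mv)
  while (i <= n) {
    if (mv[i] == "D") {
      qp <- map$qpos[i]; rp <- map$rpos[i]
      if (qc[qp] != rc[rp]) add("substitution", rp, rc[rp], qc[qp])
      i <- i + 1L
    } else {
      j <- i
      while (j < n && mv[j + 1L] == mv[i]) j <- j + 1L
      if (mv[i] == "L") {            # consensus-only: deletion
        rs <- map$rpos[i]; re <- map$rpos[j]
        add("deletion", rs, paste(rc[rs:re], collapse = ""), "")
      } else {                       # query-only: insertion
        nxt <- if (j < n) map$rpos[j + 1L] else NA_integer_
        pos <- if (!is.na(nxt)) nxt else nchar(con$aa) + 1L
        add("insertion", pos, "", paste(qc[map$qpos[i]:map$qpos[j]], collapse = ""))
      }
      i <- j + 1L
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), con_position = integer(),
               ref_aa = character(), alt_aa = character(), label = character(),
               stringsAsFactors = FALSE)
  in_range <- function(p, r) p >= r[1] & p <= r[2]
  res$in_nls <- in_range(res$con_position, con$nls)
  res$in_nes <- in_range(res$con_position, con$nes)
  res
}

#' Apply called variants to the consensus
#'
#' Sequence-level inverse of [call_variants()]: applying the variant table
#' called from any full-length protein to the consensus reconstructs that
#' protein exactly.
#'
#' @param con a [con_rec_profile()].
#' @param variants a variant table from [call_variants()].
#' @return The reconstructed protein string.
#' @export
apply_variants <- function(con, variants) {
  rc <- strsplit(con$aa, "")[[1]]
  n <- length(rc)
  keep <- rep(TRUE, n)
  repl <- rc
  ins <- vector("list", n + 1L)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind == "substitution") {
      repl[v$con_position] <- v$alt_aa
    } else if (v$kind == "deletion") {
      idx <- v$con_position:(v$con_position + nchar(v$ref_aa) - 1L)
      keep[idx] <- FALSE
    } else {
      ins[[v$con_position]] <- c(ins[[v$con_position]], v$alt_aa)
    }
  }
  pieces <- character(0)
  for (p in seq_len(n + 1L)) {
    if (!is.null(ins[[p]])) pieces <- c(pieces, ins[[p]])
    if (p <= n && keep[p]) pieces <- c(pieces, repl[p])
  }
  paste(pieces, collapse = "")
}
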
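#' Alignment scoring parameters
#'
#' Scores for pairwise global DNA alignment with affine gaps. A gap run of
#' length L costs `gap_open + (L - 1) * gap_extend`. With `free_end_gaps`,
#' terminal gap runs in either sequence are unpenalised (ends-free global
#' alignment), which is appropriate when proviral loci are truncated at their
#' boundaries relative to the reference.
#'
#' @param match,mismatch match and mismatch scores (match must exceed mismatch).
#' @param gap_open,gap_extend affine gap penalties, both non-negative with
#'   `gap_open >= gap_extend`.
#' @param free_end_gaps logical; leave end gaps unpenalised.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(match = 5, mismatch = -4, gap_open = 10,
                             gap_extend = 0.5, free_end_gaps = TRUE) {
  stopifnot(match > mismatch, gap_open >= gap_extend, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, free_end_gaps = free_end_gaps),
            class = "alignment_params")
}

dna_submat <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  s <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(s) <- match
  s["N", ] <- 0; s[, "N"] <- 0   # N is neutral
  s
}

#' Global pairwise alignment of a provirus against a reference
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap penalties and a
#' deterministic traceback (fixed source preference: diagonal, then query-
#' consuming gap, then reference-consuming gap). Returns a per-column
#' coordinate correspondence used for annotation liftover.
#'
#' @param query,ref DNA strings (or [genome_sequence()] objects). Lowercase
#'   input is accepted; sequences are handled uppercase.
#' @param params an [alignment_params()] object.
#' @return An `alignment_map`: query/ref ids, parallel integer vectors
#'   `qpos`/`rpos` (1-based residue index per alignment column, `NA` for a
#'   gap), the alignment `score`, the `identity` over aligned columns, and a
#'   `high_n` flag when either sequence exceeds 10% ambiguous bases.
#' @export
align_global <- function(query, ref, params = alignment_params()) {
  q <- as_genome_sequence(query)
  r <- as_genome_sequence(ref)
  if (nchar(q$seq) == 0L || nchar(r$seq) == 0L) stop("empty sequence")
  high_n <- max(n_fraction(q$seq), n_fraction(r$seq)) > 0.10
  if (high_n) warning("sequence contains >10% ambiguous bases; alignment flagged")
  res <- .gotoh_align_cpp(q$seq, r$seq, dna_submat(params$match, params$mismatch),
                          params$gap_open, params$gap_extend, params$free_end_gaps)
  new_alignment_map(q, r, res, high_n = high_n)
}

new_alignment_map <- function(q, r, res, high_n = FALSE) {
  qc <- strsplit(q$seq, "")[[1]]
  rc <- strsplit(r$seq, "")[[1]]
  aligned <- !is.na(res$qpos) & !is.na(res$rpos)
  ident <- if (any(aligned)) {
    mean(qc[res$qpos[aligned]] == rc[res$rpos[aligned]])
  } else 0
  structure(list(query_id = q$id, ref_id = r$id,
                 qpos = res$qpos, rpos = res$rpos,
                 query_seq = q$seq, ref_seq = r$seq,
                 score = res$score, identity = ident,
                 moves = res$moves, high_n = high_n),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map: %s vs %s | score %.1f | identity %.3f | %d columns\n",
              x$query_id, x$ref_id, x$score, x$identity, length(x$qpos)))
  invisible(x)
}

n_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(0)
  (n - nchar(gsub("N", "", seq, fixed = TRUE))) / n
}

#' Global protein alignment against the consensus Rec
#'
#' Same Gotoh machinery as [align_global()] with a BLOSUM62 substitution
#' matrix; used for variant calling and full-length classification.
#'
#' @param query,ref amino-acid strings (stops as `*` are scored against the
#'   BLOSUM62 `*` column).
#' @param gap_open,gap_extend affine gap penalties.
#' @param free_end_gaps logical; terminal gaps free (default), so truncations
#'   appear as uncovered consensus tails rather than heavily penalised gaps.
#' @return An `alignment_map` over protein residues.
#' @export
align_proteins <- function(query, ref, gap_open = 11, gap_extend = 1,
                           free_end_gaps = TRUE) {
  if (nchar(query) == 0L || nchar(ref) == 0L) stop("empty sequence")
  q <- list(id = "query", seq = toupper(query))
  r <- list(id = "ref", seq = toupper(ref))
  res <- .gotoh_align_cpp(q$seq, r$seq, blosum62(), gap_open, gap_extend,
                          free_end_gaps)
  new_alignment_map(q, r, res)
}

#' Map a reference position through an alignment
#'
#' @param map an `alignment_map`.
#' @param ref_pos 0-based reference coordinate(s).
#' @return 0-based query coordinate(s); `NA` where the reference base is
#'   aligned to a gap.
#' @export
map_position <- function(map, ref_pos) {
  idx <- match(ref_pos + 1L, map$rpos)
  map$qpos[idx] - 1L
}

#' Determine provirus orientation against a reference
#'
#' Aligns the query on both strands and keeps the one with the higher global
#' score. On an exact score tie the forward strand is kept with a warning.
#'
#' @inheritParams align_global
#' @return A list with the oriented `query` (a [genome_sequence()]), the
#'   `orientation` (`"+"` or `"-"`), the two strand scores, and `map` (the
#'   winning strand's `alignment_map`, so callers need not re-align).
#' @export
choose_orientation <- function(query, ref, params = alignment_params()) {
  q <- as_genome_sequence(query)
  fwd <- align_global(q, ref, params)
  qrc <- genome_sequence(q$id, revcomp(q$seq))
  rev <- align_global(qrc, ref, params)
  if (rev$score > fwd$score) {
    list(query = qrc, orientation = "-", score_fwd = fwd$score,
         score_rev = rev$score, map = rev)
  } else {
    if (rev$score == fwd$score)
      warning("strand scores tie; keeping '+' orientation")
    list(query = q, orientation = "+", score_fwd = fwd$score,
         score_rev = rev$score, map = fwd)
  }
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
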
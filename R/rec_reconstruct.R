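#' Translate a cDNA with stops rendered and read through
#'
#' Standard genetic code, first codon at position 0. Stop codons are rendered
#' `*` and translation continues past them, so premature stops remain visible
#' in the reported protein. Codons containing a non-ACGT base translate to
#' `X`; a trailing partial codon is dropped.
#'
#' @param cdna DNA string, length >= 3.
#' @return Amino-acid string.
#' @export
translate_cdna <- function(cdna) {
  cdna <- toupper(cdna)
  if (nchar(cdna) < 3L) stop("cDNA shorter than one codon")
  n <- nchar(cdna) %/% 3L
  codons <- substring(cdna, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Check lifted splice sites on a provirus
#'
#' Reads the observed dinucleotide at each lifted intron edge (donor: the
#' first two intronic bases, expected GT; acceptor: the last two, expected
#' AG) and compares to the expectation. Sites that failed to lift or fall
#' within 2 bp of a sequence end are reported not assessable (`intact = NA`).
#'
#' @param genome the oriented provirus [genome_sequence()].
#' @param lifted_sites output of [lift_splice_sites()].
#' @return The table with `observed` and `intact` columns added.
#' @export
check_splice_sites <- function(genome, lifted_sites) {
  obs <- character(nrow(lifted_sites))
  intact <- rep(NA, nrow(lifted_sites))
  for (i in seq_len(nrow(lifted_sites))) {
    p <- lifted_sites$q_position[i]
    kind <- lifted_sites$kind[i]
    if (is.na(p) || p < 2L || p > genome$length - 2L) {
      obs[i] <- NA_character_
      next
    }
    obs[i] <- if (kind == "donor") {
      substr(genome$seq, p + 1L, p + 2L)
    } else {
      substr(genome$seq, p, p + 1L)
    }
    intact[i] <- obs[i] == lifted_sites$expected[i]
  }
  lifted_sites$observed <- obs
  lifted_sites$intact <- intact
  lifted_sites
}

#' Reconstruct the Rec transcript for one locus
#'
#' If both the exon-1 donor and exon-2 acceptor are intact, the two lifted
#' rec exons are spliced together. If either site is mutated (or not
#' assessable), the first coding exon is kept contiguous with the env
#' sequence, extending to the provirus region aligned to the reference env
#' stop codon (readthrough mode). When exon 1 failed to lift at all the mode
#' is `no_exon1`.
#'
#' @param genome oriented provirus [genome_sequence()].
#' @param lifted lifted feature table from [liftover()].
#' @param checks splice-check table from [check_splice_sites()].
#' @return A `rec_transcript` list: `mode` (`spliced`, `exon1_readthrough`,
#'   `no_exon1`), `cdna`, and `segments` (provenance intervals on the
#'   provirus, 0-based half-open).
#' @export
build_transcript <- function(genome, lifted, checks) {
  row <- function(tbl, nm, col = "name") tbl[tbl[[col]] == nm, , drop = FALSE]
  e1 <- row(lifted, "rec_exon1")
  if (nrow(e1) != 1L || e1$coverage == 0) {
    return(structure(list(mode = "no_exon1", cdna = "", segments = NULL),
                     class = "rec_transcript"))
  }
  donor <- row(checks, "rec_exon1_donor", "label")
  acceptor <- row(checks, "rec_exon2_acceptor", "label")
  donor_ok <- nrow(donor) == 1L && isTRUE(donor$intact)
  acceptor_ok <- nrow(acceptor) == 1L && isTRUE(acceptor$intact)
  e2 <- row(lifted, "rec_exon2")

  if (donor_ok && acceptor_ok && nrow(e2) == 1L && e2$coverage > 0) {
    seg <- rbind(c(e1$q_start, e1$q_end), c(e2$q_start, e2$q_end))
    cdna <- paste0(substr(genome$seq, e1$q_start + 1L, e1$q_end),
                   substr(genome$seq, e2$q_start + 1L, e2$q_end))
    mode <- "spliced"
  } else {
    env <- row(lifted, "env")
    end <- if (nrow(env) == 1L && env$coverage > 0) env$q_end else genome$length
    seg <- rbind(c(e1$q_start, end))
    cdna <- substr(genome$seq, e1$q_start + 1L, end)
    mode <- "exon1_readthrough"
  }
  structure(list(mode = mode, cdna = cdna, segments = seg),
            class = "rec_transcript")
}

#' Detect a frameshift at cDNA level
#'
#' Aligns the reconstructed cDNA to the reference Rec cDNA and tracks the
#' running reading-frame offset (+1 per query-only column, -1 per
#' reference-only column) across the internal alignment. A frameshift is
#' called when the offset modulo 3 is non-zero at the end of the coding
#' region, or stays non-zero over a sustained stretch (>= `persist` aligned
#' columns). The persistence requirement keeps balanced, closely spaced
#' insertion/deletion pairs -- which an affine-gap aligner may prefer over a
#' column of three mismatches when a codon is substituted -- from being
#' mistaken for a shift.
#'
#' @param cdna reconstructed cDNA.
#' @param ref_cdna spliced reference Rec cDNA.
#' @param params [alignment_params()] for the DNA alignment.
#' @param persist columns a non-zero frame offset must persist to count.
#' @return Logical.
#' @export
detect_frameshift <- function(cdna, ref_cdna, params = alignment_params(),
                              persist = 15L) {
  if (nchar(cdna) == 0L) return(FALSE)
  map <- align_global(cdna, ref_cdna, params)
  mv <- strsplit(map$moves, "")[[1]]
  is_d <- mv == "D"
  if (!any(is_d)) return(FALSE)
  inside <- seq(min(which(is_d)), max(which(is_d)))  # strip terminal gap runs
  step <- ifelse(mv[inside] == "U", 1L, ifelse(mv[inside] == "L", -1L, 0L))
  off <- cumsum(step) %% 3L
  if (off[length(off)] != 0L) return(TRUE)
  r <- rle(off != 0L)
  any(r$values & r$lengths >= persist)
}

#' Classify a reconstructed Rec protein against the consensus
#'
#' The translated-through protein (stops as `*`) is cut at its first stop
#' and the prefix aligned to the consensus Rec. The protein is `full_length`
#' when the aligned consensus coverage reaches `full_cov`, the consensus
#' C-terminal residue is covered with no preceding stop, and the
#' exon-2-encoded segment of the consensus is recognisably present (identity
#' over that segment at least `exon2_min_ident` -- an exon-1/env readthrough
#' aligns env-frame residues there and fails this); `extended` when the
#' full-length criteria hold and residues continue past the consensus
#' C-terminus; `no_acceptor` when the exon-2 acceptor check failed (AG
#' mutated); otherwise `truncated`. A cDNA-level frameshift forces
#' `truncated`. A stop is premature when it falls strictly before the last
#' translated residue (a terminal stop is the natural terminator).
#'
#' @param aa translated-through protein string.
#' @param con a [con_rec_profile()].
#' @param acceptor_intact outcome of the exon-2 acceptor check (`FALSE`
#'   yields category `no_acceptor`).
#' @param frameshifted cDNA-level frameshift flag from [detect_frameshift()].
#' @param full_cov aligned consensus coverage required for full length.
#' @param exon2_min_ident minimum identity over the exon-2-encoded consensus
#'   segment.
#' @return A list: `category`, `premature_stop_position` (1-based index of
#'   the first stop when it is internal, else `NA`), `frameshifted`,
#'   `coverage`, `exon2_identity`.
#' @export
classify_protein <- function(aa, con, acceptor_intact = TRUE,
                             frameshifted = FALSE, full_cov = 0.9,
                             exon2_min_ident = 0.5) {
  stopifnot(inherits(con, "con_rec_profile"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  first_stop <- if (stop_at > 0) as.integer(stop_at) else NA_integer_
  premature <- if (!is.na(first_stop) && first_stop < nchar(aa))
    first_stop else NA_integer_
  effective <- if (!is.na(first_stop)) substr(aa, 1L, first_stop - 1L) else aa

  if (nchar(effective) == 0L) {
    return(list(category = if (isFALSE(acceptor_intact)) "no_acceptor" else "truncated",
                premature_stop_position = if (!is.na(first_stop)) first_stop else NA_integer_,
                frameshifted = isTRUE(frameshifted), coverage = 0,
                exon2_identity = 0))
  }
  map <- align_proteins(effective, con$aa)
  clen <- nchar(con$aa)
  qc <- strsplit(effective, "")[[1]]
  rc <- strsplit(con$aa, "")[[1]]
  ok <- !is.na(map$rpos) & !is.na(map$qpos)
  matched <- rep(FALSE, clen); covered <- rep(FALSE, clen)
  covered[map$rpos[ok]] <- TRUE
  matched[map$rpos[ok]] <- qc[map$qpos[ok]] == rc[map$rpos[ok]]
  coverage <- mean(covered)
  exon2_seg <- (con$exon1_aa_len + 1L):clen
  exon2_identity <- mean(matched[exon2_seg])
  cterm_covered <- covered[clen]
  q_at_cterm <- map$qpos[match(clen, map$rpos)]
  extends <- cterm_covered && !is.na(q_at_cterm) && q_at_cterm < nchar(effective)

  category <-
    if (isFALSE(acceptor_intact)) "no_acceptor"
    else if (isTRUE(frameshifted)) "truncated"
    else if (coverage >= full_cov && cterm_covered &&
             exon2_identity >= exon2_min_ident) {
      if (extends) "extended" else "full_length"
    } else "truncated"

  list(category = category, premature_stop_position = premature,
       frameshifted = isTRUE(frameshifted), coverage = coverage,
       exon2_identity = exon2_identity)
}

#' Group identical Rec proteins
#'
#' Exact-string grouping of protein sequences; one representative per group.
#'
#' @param aa named character vector of protein sequences.
#' @return A list with `group_id` (integer vector parallel to `aa`) and
#'   `groups` (data.frame: group_id, representative locus, size, sequence).
#' @export
dedupe_proteins <- function(aa) {
  if (length(aa) == 0L)
    return(list(group_id = integer(0),
                groups = data.frame(group_id = integer(), representative = character(),
                                    size = integer(), aa = character())))
  uniq <- unique(aa)
  gid <- match(aa, uniq)
  reps <- names(aa)[match(seq_along(uniq), gid)]
  list(group_id = gid,
       groups = data.frame(group_id = seq_along(uniq),
                           representative = if (is.null(reps)) NA_character_ else reps,
                           size = as.integer(table(factor(gid, levels = seq_along(uniq)))),
                           aa = uniq, stringsAsFactors = FALSE))
}
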
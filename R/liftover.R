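#' Transfer reference annotations onto a provirus through an alignment
#'
#' Each reference feature is mapped to the smallest query interval containing
#' every query base aligned to one of its reference bases. Coverage is the
#' fraction of reference feature bases aligned to query bases, identity the
#' fraction of those that are identical.
#'
#' @param map an `alignment_map` from [align_global()] (query = provirus,
#'   ref = annotated reference genome).
#' @param features a [feature_table()].
#' @param disrupted_below coverage threshold under which a feature is flagged
#'   disrupted.
#' @return A `data.frame` of lifted features: name, 0-based half-open
#'   `q_start`/`q_end` (`NA` when coverage is 0), `coverage`, `identity`,
#'   `disrupted`.
#' @export
liftover <- function(map, features, disrupted_below = 0.5) {
  if (nrow(features) && max(features$end) > nchar(map$ref_seq))
    stop("feature outside reference bounds")
  qc <- strsplit(map$query_seq, "")[[1]]
  rc <- strsplit(map$ref_seq, "")[[1]]
  ok <- !is.na(map$rpos)
  q_of_r <- rep(NA_integer_, nchar(map$ref_seq))
  q_of_r[map$rpos[ok]] <- map$qpos[ok]   # 1-based query index per ref base

  out <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    qi <- q_of_r[(f$start + 1L):f$end]
    aligned <- !is.na(qi)
    cov <- mean(aligned)
    if (cov == 0) {
      data.frame(name = f$name, q_start = NA_integer_, q_end = NA_integer_,
                 coverage = 0, identity = 0, disrupted = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      ident <- mean(qc[qi[aligned]] == rc[(f$start + 1L):f$end][aligned])
      data.frame(name = f$name,
                 q_start = min(qi, na.rm = TRUE) - 1L,
                 q_end = max(qi, na.rm = TRUE),
                 coverage = cov, identity = ident,
                 disrupted = cov < disrupted_below,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Map splice sites onto a provirus through an alignment
#'
#' @param map an `alignment_map`.
#' @param splice_sites a [splice_table()].
#' @return The table with an added 0-based `q_position` column (`NA` where
#'   the site falls in a deletion) .
#' @export
lift_splice_sites <- function(map, splice_sites) {
  splice_sites$q_position <- map_position(map, splice_sites$position)
  splice_sites
}

#' Call deletions (reference-only runs) within a reference region
#'
#' Maximal runs of alignment columns where the reference base is unaligned
#' (deleted from the query), restricted to `region`, kept when at least
#' `min_len` bases long after merging runs separated by fewer than
#' `merge_gap` aligned columns.
#'
#' @param map an `alignment_map`.
#' @param region 0-based half-open reference interval to scan; defaults to
#'   the whole reference.
#' @param min_len minimum deletion length to report.
#' @param merge_gap runs separated by fewer than this many aligned columns
#'   are merged.
#' @return A `data.frame`: `ref_start`, `ref_end` (0-based half-open),
#'   `length`, `query_breakpoint` (0-based query coordinate preceding the
#'   deletion, `NA` at the query start), `flank_identity` (identity in the
#'   +-20 bp aligned flanks).
#' @export
call_deletions <- function(map, region = NULL, min_len = 1L, merge_gap = 10L) {
  stopifnot(min_len >= 1L)
  rlen <- nchar(map$ref_seq)
  if (is.null(region)) region <- c(0L, rlen)
  if (region[1] < 0 || region[2] > rlen) stop("region outside reference")

  ok <- !is.na(map$rpos)
  deleted <- rep(FALSE, rlen)
  deleted[map$rpos[ok & is.na(map$qpos)]] <- TRUE

  r <- rle(deleted)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end > region[1] & runs$start <= region[2], , drop = FALSE]
  if (!nrow(runs)) return(empty_deletions())

  # merge runs separated by < merge_gap aligned reference columns
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L < merge_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged$len <- vapply(seq_len(nrow(merged)), function(i)
    sum(deleted[merged$start[i]:merged$end[i]]), integer(1))
  merged <- merged[merged$len >= min_len, , drop = FALSE]
  if (!nrow(merged)) return(empty_deletions())

  q_of_r <- rep(NA_integer_, rlen)
  q_of_r[map$rpos[ok]] <- map$qpos[ok]
  qc <- strsplit(map$query_seq, "")[[1]]
  rc <- strsplit(map$ref_seq, "")[[1]]
  flank_ident <- function(s, e) {
    idx <- c(max(1L, s - 20L):(s - 1L), (e + 1L):min(rlen, e + 20L))
    idx <- idx[idx >= 1L & idx <= rlen]
    qi <- q_of_r[idx]
    al <- !is.na(qi)
    if (!any(al)) return(0)
    mean(qc[qi[al]] == rc[idx][al])
  }
  data.frame(ref_start = merged$start - 1L, ref_end = merged$end,
             length = merged$len,
             query_breakpoint = vapply(merged$start, function(s) {
               prev <- q_of_r[seq_len(s - 1L)]
               prev <- prev[!is.na(prev)]
               if (length(prev)) prev[length(prev)] - 1L else NA_integer_
             }, integer(1)),
             flank_identity = vapply(seq_len(nrow(merged)), function(i)
               flank_ident(merged$start[i], merged$end[i]), numeric(1)),
             stringsAsFactors = FALSE)
}

empty_deletions <- function() {
  data.frame(ref_start = integer(), ref_end = integer(), length = integer(),
             query_breakpoint = integer(), flank_identity = numeric())
}

#' Assess LTR status from a lifted feature
#'
#' @param lifted one row of a [liftover()] result for an LTR feature.
#' @param intact_cov,intact_ident coverage/identity required for `intact`.
#' @param partial_cov coverage required for `partial`.
#' @return `"intact"`, `"partial"` or `"absent"`.
#' @export
assess_ltr <- function(lifted, intact_cov = 0.9, intact_ident = 0.8,
                       partial_cov = 0.3) {
  if (lifted$coverage >= intact_cov && lifted$identity >= intact_ident) "intact"
  else if (lifted$coverage >= partial_cov) "partial"
  else "absent"
}

#' Classify a provirus as type 1 or type 2
#'
#' Orients the provirus against the type-2 reference, aligns it to both
#' references and calls the type: type 1 when a deletion of at least
#' `min_del_len` bases overlaps `rec_exon1` on the type-2 alignment; else
#' type 2 when `rec_exon1` coverage is at least `exon1_cov`; otherwise (or
#' when overall identity falls below `min_identity`) ambiguous. The A->T
#' stop/new-donor signature at the configured position is recorded
#' independently of the call, since it occurs in many but not all type-1
#' proviruses.
#'
#' @param genome a provirus [genome_sequence()] (either strand).
#' @param ref2,ref1 annotated type-2 and type-1 references.
#' @param params [alignment_params()].
#' @param min_del_len minimum deletion length that drives a type-1 call.
#' @param exon1_cov rec_exon1 coverage required for type 2.
#' @param min_identity overall alignment identity below which the call is
#'   ambiguous.
#' @return A `provirus_call` list: `locus_id`, `orientation`,
#'   `provirus_type`, `deletions` (table over the rec_exon1 region),
#'   `donor_signature_present`, `ltr5_status`, `ltr3_status`,
#'   `score_vs_type2`, `score_vs_type1`, `identity`, plus the oriented query
#'   and the type-2 `alignment_map` for downstream reconstruction.
#' @export
classify_type <- function(genome, ref2, ref1, params = alignment_params(),
                          min_del_len = 100L, exon1_cov = 0.5,
                          min_identity = 0.6) {
  ori <- choose_orientation(genome, ref2$genome, params)
  map2 <- ori$map
  map1 <- align_global(ori$query, ref1$genome, params)

  e1 <- ref_feature(ref2, "rec_exon1")
  lifted <- liftover(map2, ref2$features)
  dels <- call_deletions(map2, region = c(e1$start, e1$end),
                         min_len = min_del_len)
  overlaps_e1 <- nrow(dels) > 0 &
    any(dels$ref_end > e1$start & dels$ref_start < e1$end)
  e1_cov <- lifted$coverage[lifted$name == "rec_exon1"]

  type <-
    if (map2$identity < min_identity) "ambiguous"
    else if (overlaps_e1) "type1"
    else if (length(e1_cov) && e1_cov >= exon1_cov) "type2"
    else "ambiguous"

  sig <- FALSE
  if (!is.null(ref2$config$stop_mutation_pos)) {
    qp <- map_position(map2, ref2$config$stop_mutation_pos)
    if (!is.na(qp))
      sig <- substr(ori$query$seq, qp + 1L, qp + 1L) == "T"
  }

  ltr_status <- function(nm) {
    row <- lifted[lifted$name == nm, ]
    if (nrow(row) != 1L) return(NA_character_)
    assess_ltr(row)
  }

  structure(list(locus_id = genome$id, orientation = ori$orientation,
                 provirus_type = type, deletions = dels,
                 donor_signature_present = sig,
                 ltr5_status = ltr_status("ltr5"),
                 ltr3_status = ltr_status("ltr3"),
                 score_vs_type2 = map2$score, score_vs_type1 = map1$score,
                 identity = map2$identity,
                 oriented_query = ori$query, map2 = map2, lifted = lifted),
            class = "provirus_call")
}

#' @export
print.provirus_call <- function(x, ...) {
  cat(sprintf("provirus_call %s: %s (%s), %d deletion(s), LTR5 %s / LTR3 %s\n",
              x$locus_id, x$provirus_type, x$orientation, nrow(x$deletions),
              x$ltr5_status, x$ltr3_status))
  invisible(x)
}
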
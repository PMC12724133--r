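#' Full per-locus analysis: type call and Rec reconstruction
#'
#' Runs the whole chain for one proviral genome: orientation, global
#' alignment to both references, type call, and -- for type-2 loci -- splice
#' checks, transcript reconstruction, translation, cDNA-level frameshift
#' detection, protein classification, and variant calling for full-length or
#' extended proteins.
#'
#' @param genome a provirus [genome_sequence()] or plain DNA string.
#' @param ref2,ref1 annotated type-2 and type-1 references (`ref1` defaults
#'   to [derive_type1_reference()] of `ref2`).
#' @param params [alignment_params()].
#' @param con optional [con_rec_profile()]; defaults to the reference's own
#'   spliced Rec.
#' @param ... further arguments passed to [classify_type()].
#' @return A `rec_scan` list: `call` (the [classify_type()] result),
#'   `checks`, `transcript`, `aa`, `classification`, `variants` (or `NULL`
#'   where not applicable).
#' @export
scan_locus <- function(genome, ref2, ref1 = NULL, params = alignment_params(),
                       con = NULL, ...) {
  genome <- as_genome_sequence(genome)
  if (is.null(ref1)) ref1 <- derive_type1_reference(ref2)
  refrec <- reference_rec(ref2)
  if (is.null(con)) con <- refrec$profile

  call <- classify_type(genome, ref2, ref1, params, ...)
  out <- list(call = call, checks = NULL, transcript = NULL, aa = NULL,
              classification = NULL, variants = NULL)
  if (call$provirus_type != "type2") return(structure(out, class = "rec_scan"))

  lifted_ss <- lift_splice_sites(call$map2, ref2$splice_sites)
  checks <- check_splice_sites(call$oriented_query, lifted_ss)
  tx <- build_transcript(call$oriented_query, call$lifted, checks)

  acceptor <- checks[checks$label == "rec_exon2_acceptor", ]
  acceptor_intact <- if (nrow(acceptor) == 1L) acceptor$intact else NA

  aa <- NULL; cls <- NULL; variants <- NULL
  if (nchar(tx$cdna) >= 3L) {
    aa <- translate_cdna(tx$cdna)
    fshift <- if (tx$mode == "spliced")
      detect_frameshift(tx$cdna, refrec$cdna, params) else FALSE
    cls <- classify_protein(aa, con,
                            acceptor_intact = !isFALSE(acceptor_intact),
                            frameshifted = fshift)
    if (isFALSE(acceptor_intact)) cls$category <- "no_acceptor"
    if (cls$category %in% c("full_length", "extended")) {
      mature <- sub("\\*.*$", "", aa)
      variants <- call_variants(mature, con)
    }
  } else {
    cls <- list(category = "truncated", premature_stop_position = 0L,
                frameshifted = FALSE, coverage = 0)
  }
  out$checks <- checks; out$transcript <- tx; out$aa <- aa
  out$classification <- cls; out$variants <- variants
  structure(out, class = "rec_scan")
}

#' @export
print.rec_scan <- function(x, ...) {
  print(x$call)
  if (!is.null(x$transcript))
    cat(sprintf("  transcript: %s (%d nt); category: %s\n",
                x$transcript$mode, nchar(x$transcript$cdna),
                x$classification$category))
  if (!is.null(x$variants) && nrow(x$variants))
    cat("  variants:", paste(x$variants$label, collapse = ", "), "\n")
  invisible(x)
}

#' Scan a panel of proviral sequences
#'
#' Applies [scan_locus()] to every sequence and assembles a per-locus
#' results table, protein set and variant table. Distinct-protein groups are
#' computed over the full-length/extended loci (mature sequences).
#'
#' @param sequences named character vector of proviral genomes.
#' @param ref2,ref1,params,con as in [scan_locus()].
#' @param ... passed to [classify_type()].
#' @return A list: `results` (one row per locus), `scans` (raw [scan_locus()]
#'   outputs), `proteins` (mature proteins of full-length/extended loci),
#'   `groups` ([dedupe_proteins()] over those), `variants` (long table).
#' @export
scan_panel <- function(sequences, ref2, ref1 = NULL,
                       params = alignment_params(), con = NULL, ...) {
  if (is.null(ref1)) ref1 <- derive_type1_reference(ref2)
  scans <- lapply(names(sequences), function(id)
    scan_locus(genome_sequence(id, sequences[[id]]), ref2, ref1, params, con, ...))
  names(scans) <- names(sequences)

  rows <- lapply(scans, function(s) {
    cl <- s$call
    data.frame(
      locus_id = cl$locus_id, orientation = cl$orientation,
      provirus_type = cl$provirus_type,
      n_deletions = nrow(cl$deletions),
      donor_signature = cl$donor_signature_present,
      ltr5_status = cl$ltr5_status, ltr3_status = cl$ltr3_status,
      donor_intact = splice_flag(s, "rec_exon1_donor"),
      acceptor_intact = splice_flag(s, "rec_exon2_acceptor"),
      transcript_mode = if (is.null(s$transcript)) NA_character_ else s$transcript$mode,
      category = if (is.null(s$classification)) NA_character_ else s$classification$category,
      premature_stop_position = if (is.null(s$classification)) NA_integer_
        else as.integer(s$classification$premature_stop_position),
      frameshifted = if (is.null(s$classification)) NA else s$classification$frameshifted,
      coverage = if (is.null(s$classification)) NA_real_ else s$classification$coverage,
      variant_labels = if (is.null(s$variants)) "" else
        paste(sort(s$variants$label), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  full <- results$locus_id[!is.na(results$category) &
                           results$category %in% c("full_length", "extended")]
  proteins <- vapply(full, function(id) sub("\\*.*$", "", scans[[id]]$aa),
                     character(1))
  groups <- dedupe_proteins(proteins)

  var_tabs <- lapply(full, function(id) {
    v <- scans[[id]]$variants
    if (is.null(v) || !nrow(v)) return(NULL)
    cbind(locus_id = id, v)
  })
  variants <- do.call(rbind, var_tabs)

  list(results = results, scans = scans, proteins = proteins,
       groups = groups, variants = variants)
}

splice_flag <- function(s, label) {
  if (is.null(s$checks)) return(NA)
  row <- s$checks[s$checks$label == label, ]
  if (nrow(row) != 1L) NA else row$intact
}

#' Compare panel scan results against a generator truth table
#'
#' Checks, locus by locus, the calls the truth table fixes: orientation,
#' provirus type and -- for type-2 loci -- splice-site flags, transcript
#' mode, protein category, frameshift flag, premature-stop index (for
#' non-frameshifted loci, where it is deterministic) and variant labels.
#'
#' @param results the `results` table from [scan_panel()].
#' @param truth the truth table from [make_panel()]/[make_study_panel()].
#' @return A data.frame with one row per locus and logical columns per
#'   check, plus `all_ok`.
#' @export
compare_truth <- function(results, truth) {
  m <- merge(truth, results, by = "locus_id", suffixes = c(".t", ".o"))
  eq <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  # an all-empty label column round-trips through TSV as logical NA
  m$variant_labels.t <- ifelse(is.na(m$variant_labels.t), "",
                               as.character(m$variant_labels.t))
  m$variant_labels.o <- ifelse(is.na(m$variant_labels.o), "",
                               as.character(m$variant_labels.o))
  out <- data.frame(
    locus_id = m$locus_id,
    orientation = eq(m$orientation.t, m$orientation.o),
    provirus_type = eq(m$provirus_type.t, m$provirus_type.o),
    transcript_mode = eq(m$transcript_mode.t, m$transcript_mode.o),
    category = eq(m$category.t, m$category.o),
    frameshifted = eq(m$frameshifted.t, m$frameshifted.o),
    variant_labels = eq(m$variant_labels.t, m$variant_labels.o),
    stringsAsFactors = FALSE)
  # splice flags are asserted only for type-2 loci (not assessed otherwise)
  t2 <- m$provirus_type.t == "type2"
  out$donor_intact <- !t2 | eq(m$donor_intact.t, m$donor_intact.o)
  out$acceptor_intact <- !t2 | eq(m$acceptor_intact.t, m$acceptor_intact.o)
  # the stop index is deterministic except after a frameshift
  det_stop <- t2 & !m$frameshifted.t
  out$premature_stop <- !det_stop |
    eq(m$premature_stop_position.t, m$premature_stop_position.o)
  out$all_ok <- Reduce(`&`, out[, setdiff(names(out), "locus_id")])
  out
}
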
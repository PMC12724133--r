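#' Genome sequence container
#'
#' A minimal locus container: identifier plus an uppercase DNA string over
#' A/C/G/T/N. All internal coordinates in the package are 0-based half-open;
#' on-disk formats (FASTA/GFF3) use the usual 1-based inclusive convention.
#'
#' @param id locus identifier.
#' @param seq DNA string; lowercase accepted, stored uppercase.
#' @return An object of class `genome_sequence` with fields `id`, `seq`,
#'   `length`.
#' @export
genome_sequence <- function(id, seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence for '", id,
                                   "' contains characters outside A/C/G/T/N")
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

as_genome_sequence <- function(x, id = "seq") {
  if (inherits(x, "genome_sequence")) x else genome_sequence(id, x)
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence %s: %d bp\n", x$id, x$length))
  invisible(x)
}

FEATURE_NAMES <- c("ltr5", "ltr3", "gag", "pro", "pol", "env",
                   "rec_exon1", "rec_exon2", "np9_region", "env_sp")

SPLICE_LABELS <- c("major_donor", "rec_exon1_acceptor", "rec_exon1_donor",
                   "rec_exon2_acceptor")

#' Feature table constructor
#'
#' @param name feature names from the controlled vocabulary (`ltr5`, `ltr3`,
#'   `gag`, `pro`, `pol`, `env`, `rec_exon1`, `rec_exon2`, `np9_region`,
#'   `env_sp`).
#' @param start,end 0-based half-open interval on the reference.
#' @param phase CDS phase (0-2) or `NA`.
#' @return A `data.frame` with columns name/start/end/strand/phase.
#' @export
feature_table <- function(name, start, end, phase = NA_integer_) {
  stopifnot(all(name %in% FEATURE_NAMES), all(start >= 0), all(start < end))
  n <- length(name)
  data.frame(name = name, start = as.integer(start), end = as.integer(end),
             strand = rep("+", n),
             phase = rep_len(as.integer(phase), n),
             stringsAsFactors = FALSE)
}

#' Splice-site table constructor
#'
#' `position` is the 0-based coordinate of the first intronic base for a
#' donor and of the last intronic base for an acceptor, so the expected
#' dinucleotide occupies `[position, position + 2)` (donor) or
#' `[position - 1, position + 1)` (acceptor).
#'
#' @param label site labels (`major_donor`, `rec_exon1_acceptor`,
#'   `rec_exon1_donor`, `rec_exon2_acceptor`).
#' @param kind `"donor"` or `"acceptor"`.
#' @param position 0-based coordinates as described above.
#' @return A `data.frame` with the expected GT/AG dinucleotide filled in by
#'   kind.
#' @export
splice_table <- function(label, kind, position) {
  stopifnot(all(label %in% SPLICE_LABELS), all(kind %in% c("donor", "acceptor")))
  data.frame(label = label, kind = kind, position = as.integer(position),
             expected = ifelse(kind == "donor", "GT", "AG"),
             stringsAsFactors = FALSE)
}

#' Annotated reference genome
#'
#' Bundles a reference provirus sequence with its feature set (LTRs, ORFs,
#' rec exons) and splice sites, and validates the structural invariants: a
#' type-2 reference must carry both rec exons with exon 1 preceding exon 2;
#' all intervals must lie inside the genome.
#'
#' @param genome a [genome_sequence()].
#' @param features a [feature_table()].
#' @param splice_sites a [splice_table()] (may be empty).
#' @param provirus_type `"type1"` or `"type2"`.
#' @param config named list of derived coordinates kept with the reference
#'   (e.g. the type-1 deletion interval and the A->T stop/new-donor position).
#' @return An object of class `annotated_reference`.
#' @export
annotated_reference <- function(genome, features, splice_sites = splice_table(
                                  character(), character(), integer()),
                                provirus_type = "type2", config = list()) {
  stopifnot(inherits(genome, "genome_sequence"),
            provirus_type %in% c("type1", "type2"))
  if (any(features$end > genome$length) || any(features$start < 0))
    stop("feature coordinates outside genome in reference '", genome$id, "'")
  if (nrow(splice_sites) && (any(splice_sites$position < 0) ||
                             any(splice_sites$position >= genome$length)))
    stop("splice-site position outside genome")
  if (provirus_type == "type2") {
    e1 <- features[features$name == "rec_exon1", ]
    e2 <- features[features$name == "rec_exon2", ]
    if (nrow(e1) != 1L || nrow(e2) != 1L)
      stop("type-2 reference '", genome$id, "' must carry rec_exon1 and rec_exon2")
    if (e1$end > e2$start)
      stop("rec_exon1 must end before rec_exon2 starts")
  }
  structure(list(genome = genome, features = features,
                 splice_sites = splice_sites, provirus_type = provirus_type,
                 config = config),
            class = "annotated_reference")
}

#' @export
print.annotated_reference <- function(x, ...) {
  cat(sprintf("annotated_reference %s (%s): %d bp, %d features, %d splice sites\n",
              x$genome$id, x$provirus_type, x$genome$length,
              nrow(x$features), nrow(x$splice_sites)))
  invisible(x)
}

ref_feature <- function(ref, name) {
  f <- ref$features[ref$features$name == name, ]
  if (nrow(f) != 1L) stop("reference lacks a unique '", name, "' feature")
  f
}

#' Extract the sequence of a named reference feature
#'
#' @param ref an [annotated_reference()].
#' @param name a feature name present exactly once in the reference.
#' @return The feature's DNA string.
#' @export
feature_seq <- function(ref, name) {
  f <- ref_feature(ref, name)
  substr(ref$genome$seq, f$start + 1L, f$end)
}

#' Consensus Rec protein profile
#'
#' The consensus Rec amino-acid sequence with its exon structure and the
#' NLS/NES annotation intervals. Exon 1 contributes the first 87 residues,
#' which coincide with the start of the 95-residue Env signal peptide; exon 2
#' is translated in a different reading frame of env.
#'
#' @param aa_sequence consensus Rec protein (no terminal stop).
#' @param exon1_aa_len residues contributed by exon 1 (87).
#' @param env_sp_aa_len length of the Env signal peptide (95).
#' @param nls,nes 1-based inclusive residue ranges of the NLS and NES.
#' @return An object of class `con_rec_profile`.
#' @export
con_rec_profile <- function(aa_sequence, exon1_aa_len = 87L,
                            env_sp_aa_len = 95L, nls = c(13L, 20L),
                            nes = c(50L, 60L)) {
  len <- nchar(aa_sequence)
  stopifnot(exon1_aa_len < len, nls[2] <= len, nes[2] <= len,
            nls[1] >= 1, nes[1] >= 1)
  structure(list(aa = toupper(aa_sequence), exon1_aa_len = as.integer(exon1_aa_len),
                 env_sp_aa_len = as.integer(env_sp_aa_len),
                 nls = as.integer(nls), nes = as.integer(nes)),
            class = "con_rec_profile")
}

#' Spliced Rec cDNA and consensus profile of a type-2 reference
#'
#' Joins the annotated rec exons of the reference, translates them and
#' returns the [con_rec_profile()] (terminal stop removed).
#'
#' @param ref a type-2 [annotated_reference()].
#' @param nls,nes NLS/NES residue ranges passed through to the profile.
#' @return A list with `cdna` and `profile`.
#' @export
reference_rec <- function(ref, nls = c(13L, 20L), nes = c(50L, 60L)) {
  stopifnot(ref$provirus_type == "type2")
  cdna <- paste0(feature_seq(ref, "rec_exon1"), feature_seq(ref, "rec_exon2"))
  aa <- translate_cdna(cdna)
  aa <- sub("\\*$", "", aa)
  if (grepl("\\*", aa)) stop("reference Rec contains an internal stop codon")
  list(cdna = cdna, profile = con_rec_profile(aa, nls = nls, nes = nes))
}

#' Derive the type-1 reference from an annotated type-2 reference
#'
#' Excises the diagnostic 292-bp pol-env deletion and applies the A->T point
#' mutation that introduces a stop codon in the env frame (and creates the
#' GA->GT Np9 donor). Features to the right of the deletion are shifted left;
#' features overlapping it are truncated, and `rec_exon1` (mostly removed by
#' the deletion) is dropped. Splice sites inside the deletion are dropped.
#'
#' @param ref2 the type-2 [annotated_reference()].
#' @param deletion 0-based half-open interval to excise; defaults to
#'   `ref2$config$type1_deletion`. Must be 292 bp unless `check_length` is
#'   `FALSE`, and must overlap `rec_exon1`.
#' @param stop_mutation_pos 0-based position of the A->T substitution,
#'   upstream of the deletion; defaults to `ref2$config$stop_mutation_pos`.
#' @param check_length enforce the canonical 292-bp length.
#' @return A type-1 [annotated_reference()].
#' @export
derive_type1_reference <- function(ref2,
                                   deletion = ref2$config$type1_deletion,
                                   stop_mutation_pos = ref2$config$stop_mutation_pos,
                                   check_length = TRUE) {
  stopifnot(inherits(ref2, "annotated_reference"), ref2$provirus_type == "type2")
  if (is.null(deletion) || is.null(stop_mutation_pos))
    stop("deletion interval and stop_mutation_pos required (no config on reference)")
  del_len <- deletion[2] - deletion[1]
  if (del_len <= 0) stop("zero-length or inverted deletion interval")
  if (deletion[1] < 0 || deletion[2] > ref2$genome$length)
    stop("deletion outside genome")
  if (check_length && del_len != 292L)
    stop("type-1 deletion must be 292 bp (got ", del_len, ")")
  e1 <- ref_feature(ref2, "rec_exon1")
  if (deletion[2] <= e1$start || deletion[1] >= e1$end)
    stop("deletion does not overlap rec_exon1")
  if (stop_mutation_pos >= deletion[1])
    stop("stop_mutation_pos must lie upstream of the deletion")
  base <- substr(ref2$genome$seq, stop_mutation_pos + 1L, stop_mutation_pos + 1L)
  if (base != "A")
    stop("base at stop_mutation_pos is '", base, "', expected 'A'")

  seq <- ref2$genome$seq
  substr(seq, stop_mutation_pos + 1L, stop_mutation_pos + 1L) <- "T"
  seq <- paste0(substr(seq, 1L, deletion[1]),
                substr(seq, deletion[2] + 1L, nchar(seq)))

  shift_iv <- function(s, e) {
    ns <- ifelse(s >= deletion[2], s - del_len, pmin(s, deletion[1]))
    ne <- ifelse(e >= deletion[2], e - del_len, pmin(e, deletion[1]))
    cbind(ns, ne)
  }
  ft <- ref2$features[ref2$features$name != "rec_exon1", , drop = FALSE]
  iv <- shift_iv(ft$start, ft$end)
  ft$start <- as.integer(iv[, 1]); ft$end <- as.integer(iv[, 2])
  ft <- ft[ft$end > ft$start, , drop = FALSE]

  ss <- ref2$splice_sites
  inside <- ss$position >= deletion[1] & ss$position < deletion[2]
  ss <- ss[!inside, , drop = FALSE]
  ss$position <- ifelse(ss$position >= deletion[2],
                        ss$position - del_len, ss$position)
  ss$position <- as.integer(ss$position)
  ss <- ss[ss$label != "rec_exon1_donor" | ss$position < nchar(seq), , drop = FALSE]

  annotated_reference(genome_sequence(paste0(ref2$genome$id, "_t1"), seq),
                      features = ft, splice_sites = ss,
                      provirus_type = "type1",
                      config = list(derived_from = ref2$genome$id,
                                    deletion = deletion,
                                    stop_mutation_pos = stop_mutation_pos))
}
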
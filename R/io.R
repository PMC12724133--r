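#' Read an annotated reference from FASTA + GFF3
#'
#' The FASTA record supplies the genome; the GFF3 file supplies features
#' (rows whose `type` is one of the controlled feature names) and splice
#' sites (rows of type `splice_site` with `label` and `site_kind`
#' attributes). On-disk coordinates are 1-based inclusive and are converted
#' to the internal 0-based half-open convention.
#'
#' @param fasta_path path to a single-record FASTA file.
#' @param gff3_path path to the GFF3 annotation.
#' @param provirus_type declared type of the reference; a type-2 reference
#'   missing either rec exon is a validation error.
#' @return An [annotated_reference()].
#' @export
read_reference <- function(fasta_path, gff3_path, provirus_type = "type2") {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  if (!file.exists(gff3_path)) stop("no such file: ", gff3_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L) stop("expected a single FASTA record in ", fasta_path)
  genome <- genome_sequence(sub("\\s.*$", "", names(dna)[1]),
                            as.character(dna[[1]]))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  bad <- GenomicRanges::start(gr) < 1 | GenomicRanges::end(gr) > genome$length
  if (any(bad))
    stop("malformed coordinates in ", gff3_path, " for record(s): ",
         paste(type[bad], collapse = ", "))

  keep <- type %in% FEATURE_NAMES
  ft <- feature_table(type[keep],
                      start = GenomicRanges::start(gr)[keep] - 1L,
                      end = GenomicRanges::end(gr)[keep])
  if (!is.null(gr$phase)) {
    ph <- suppressWarnings(as.integer(as.character(gr$phase)[keep]))
    ft$phase <- ph
  }

  ss_rows <- type == "splice_site"
  if (any(ss_rows)) {
    ss <- splice_table(as.character(gr$label)[ss_rows],
                       as.character(gr$site_kind)[ss_rows],
                       GenomicRanges::start(gr)[ss_rows] - 1L)
  } else {
    ss <- splice_table(character(), character(), integer())
  }
  cfg <- list()
  hdr <- readLines(gff3_path, n = 20L)
  cfg_line <- grep("^#config ", hdr, value = TRUE)
  for (cl in cfg_line) {
    kv <- strsplit(sub("^#config ", "", cl), "=", fixed = TRUE)[[1]]
    cfg[[kv[1]]] <- as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]])
  }
  annotated_reference(genome, ft, ss, provirus_type = provirus_type,
                      config = cfg)
}

#' Write reference annotations as GFF3
#'
#' Emits one row per feature and splice site (1-based inclusive), plus a
#' `mRNA` parent with two `CDS` parts for the spliced rec transcript of a
#' type-2 reference. `read_reference()` after `write_annotations()` is the
#' identity on features and splice sites.
#'
#' @param ref an [annotated_reference()].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ref, path) {
  ft <- ref$features
  ss <- ref$splice_sites
  n_ft <- nrow(ft); n_ss <- nrow(ss)
  seqid <- ref$genome$id

  rows <- character(0)
  mk <- function(type, start0, end0, phase, attrs) {
    sprintf("%s\thervrec\t%s\t%d\t%d\t.\t+\t%s\t%s",
            seqid, type, start0 + 1L, end0, phase, attrs)
  }
  if (n_ft) {
    ph <- ifelse(is.na(ft$phase), ".", as.character(ft$phase))
    rows <- c(rows, mk(ft$name, ft$start, ft$end, ph,
                       sprintf("ID=%s", ft$name)))
  }
  if (n_ss) {
    rows <- c(rows, mk("splice_site", ss$position, ss$position + 1L, ".",
                       sprintf("ID=ss_%s;label=%s;site_kind=%s",
                               ss$label, ss$label, ss$kind)))
  }
  if (ref$provirus_type == "type2") {
    e1 <- ref_feature(ref, "rec_exon1"); e2 <- ref_feature(ref, "rec_exon2")
    rows <- c(rows,
              mk("mRNA", e1$start, e2$end, ".", "ID=rec_mRNA"),
              mk("CDS", e1$start, e1$end, "0", "ID=rec_cds1;Parent=rec_mRNA"),
              mk("CDS", e2$start, e2$end,
                 as.character((3L - (e1$end - e1$start) %% 3L) %% 3L),
                 "ID=rec_cds2;Parent=rec_mRNA"))
  }
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", seqid, ref$genome$length))
  if (!is.null(ref$config$type1_deletion))
    hdr <- c(hdr, sprintf("#config type1_deletion=%d,%d",
                          ref$config$type1_deletion[1],
                          ref$config$type1_deletion[2]))
  if (!is.null(ref$config$stop_mutation_pos))
    hdr <- c(hdr, sprintf("#config stop_mutation_pos=%d",
                          ref$config$stop_mutation_pos))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write one or more sequences as FASTA
#'
#' @param seqs a named character vector of sequences, or a single
#'   [genome_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "genome_sequence")) {
    seqs <- stats::setNames(seqs$seq, seqs$id)
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a multi-record FASTA panel
#'
#' @param path FASTA path.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write protein sequences as FASTA
#'
#' @param seqs named character vector of amino-acid sequences (stops allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
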
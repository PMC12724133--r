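test_that("genome_sequence validates and normalises its input", {
  g <- genome_sequence("x", "acgtn")
  expect_equal(g$seq, "ACGTN")
  expect_equal(g$length, 5L)
  expect_error(genome_sequence("x", "ACGU"), "outside")
})

test_that("rec exon 1 of the reference translates to 87 residues", {
  ref <- make_reference(1)
  e1_aa <- translate_cdna(feature_seq(ref, "rec_exon1"))
  expect_equal(nchar(e1_aa), 87L)
  expect_false(grepl("\\*", e1_aa))
  # exon 1 is the prefix of the 95-residue Env signal peptide
  sp_aa <- translate_cdna(feature_seq(ref, "env_sp"))
  expect_equal(nchar(sp_aa), 95L)
  expect_equal(substr(sp_aa, 1, 87), e1_aa)
  # consensus Rec: 87 exon-1 residues + 18 exon-2 residues
  expect_equal(nchar(reference_rec(ref)$profile$aa), 105L)
})

test_that("annotation write/read round-trips features, sites and config", {
  ref <- make_reference(8)
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "ref.gff3"); fa <- file.path(dir, "ref.fa")
  write_annotations(ref, gff)
  write_fasta(ref$genome, fa)
  back <- read_reference(fa, gff)
  expect_equal(back$genome$seq, ref$genome$seq)
  expect_equal(back$features[order(back$features$name), ],
               ref$features[order(ref$features$name), ],
               ignore_attr = TRUE)
  expect_equal(back$splice_sites[order(back$splice_sites$label), ],
               ref$splice_sites[order(ref$splice_sites$label), ],
               ignore_attr = TRUE)
  expect_equal(back$config$type1_deletion, ref$config$type1_deletion)
  expect_equal(back$config$stop_mutation_pos, ref$config$stop_mutation_pos)
})

test_that("the rec transcript is written as two CDS parts under one parent", {
  ref <- make_reference(8)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotations(ref, gff)
  lines <- readLines(gff)
  cds <- grep("\tCDS\t", lines, value = TRUE)
  expect_length(cds, 2L)
  parents <- sub(".*Parent=([^;]+).*", "\\1", cds)
  expect_equal(unique(parents), "rec_mRNA")
  expect_length(grep("\tmRNA\t", lines), 1L)
})

test_that("a declared type-2 reference without rec exons is rejected", {
  ref <- make_reference(8)
  ft <- ref$features[ref$features$name != "rec_exon2", ]
  expect_error(annotated_reference(ref$genome, ft, ref$splice_sites, "type2"),
               "rec_exon")
  # GFF3 coordinates outside the sequence are a parse error naming the record
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "bad.gff3"); fa <- file.path(dir, "ref.fa")
  write_annotations(ref, gff)
  write_fasta(ref$genome, fa)
  lines <- readLines(gff)
  lines <- sub("^(\\S+\thervrec\tltr3\t\\d+\t)\\d+", "\\199999", lines)
  writeLines(lines, gff)
  expect_error(read_reference(fa, gff), "malformed")
})

test_that("an empty feature set writes a header-only GFF3", {
  g <- genome_sequence("bare", strrep("ACGT", 25))
  ref <- annotated_reference(g, feature_table(character(), integer(), integer()),
                             provirus_type = "type1")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotations(ref, gff)
  lines <- readLines(gff)
  expect_true(all(grepl("^#", lines)))
})

test_that("the derived type-1 reference carries the deletion and A->T stop", {
  ref <- make_reference(1)
  t1 <- derive_type1_reference(ref)
  expect_equal(ref$genome$length - t1$genome$length, 292L)
  expect_equal(t1$provirus_type, "type1")
  expect_false("rec_exon1" %in% t1$features$name)

  del <- ref$config$type1_deletion
  sp <- ref$config$stop_mutation_pos
  expect_equal(substr(ref$genome$seq, sp + 1, sp + 1), "A")
  expect_equal(substr(t1$genome$seq, sp + 1, sp + 1), "T")
  # sequence conserved base-by-base outside the excised interval and the SNV
  left_ref <- substr(ref$genome$seq, 1, del[1])
  left_t1 <- substr(t1$genome$seq, 1, del[1])
  expect_equal(which(strsplit(left_ref, "")[[1]] != strsplit(left_t1, "")[[1]]),
               sp + 1L)
  expect_equal(substr(t1$genome$seq, del[1] + 1, t1$genome$length),
               substr(ref$genome$seq, del[2] + 1, ref$genome$length))
})

test_that("degenerate or misplaced deletions are rejected", {
  ref <- make_reference(1)
  expect_error(derive_type1_reference(ref, deletion = c(100, 100)),
               "zero-length")
  expect_error(derive_type1_reference(ref, deletion = c(100, 392),
                                      stop_mutation_pos = 50),
               "overlap rec_exon1")
  expect_error(derive_type1_reference(ref, deletion = c(1700, 1800)), "292")
})
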
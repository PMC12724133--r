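ref <- make_reference(4)
con <- reference_rec(ref)$profile

test_that("translation follows the standard code and reads through stops", {
  expect_equal(translate_cdna("ATGGAA"), "ME")
  expect_equal(translate_cdna("ATGTAAGAA"), "M*E")
  expect_equal(translate_cdna("ATGNNA"), "MX")
  expect_error(translate_cdna("AT"), "codon")
  # all 64 codons against the canonical code table
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  expect_equal(vapply(codons, translate_cdna, character(1), USE.NAMES = FALSE),
               unname(Biostrings::GENETIC_CODE[codons]))
})

test_that("splice sites on the reference itself all read intact", {
  m <- align_global(ref$genome, ref$genome)
  checks <- check_splice_sites(ref$genome,
                               lift_splice_sites(m, ref$splice_sites))
  expect_true(all(checks$intact))
  expect_equal(checks$observed[checks$kind == "donor"], c("GT", "GT"))
  expect_equal(checks$observed[checks$kind == "acceptor"], c("AG", "AG"))
})

test_that("the reference splices its own exons into the consensus cDNA", {
  sc <- scan_locus(ref$genome, ref)
  expect_equal(sc$transcript$mode, "spliced")
  expect_equal(sc$transcript$cdna, reference_rec(ref)$cdna)
  expect_equal(sc$classification$category, "full_length")
  expect_equal(nrow(sc$variants), 0L)
})

test_that("an AG->GG acceptor mutant loses its second exon (no_acceptor)", {
  d <- degrade(ref, list(edit_splice("rec_exon2_acceptor", "GG")), "accmut")
  sc <- scan_locus(d$genome, ref)
  acc <- sc$checks[sc$checks$label == "rec_exon2_acceptor", ]
  expect_equal(acc$observed, "GG")
  expect_false(acc$intact)
  expect_equal(sc$transcript$mode, "exon1_readthrough")
  expect_equal(sc$classification$category, "no_acceptor")
})

test_that("a donor mutant keeps exon 1 contiguous with env", {
  d <- degrade(ref, list(edit_splice("rec_exon1_donor", "GA")), "donmut")
  sc <- scan_locus(d$genome, ref)
  expect_equal(sc$transcript$mode, "exon1_readthrough")
  e1 <- feature_seq(ref, "rec_exon1")
  expect_equal(substr(sc$transcript$cdna, 1, nchar(e1)), e1)
  # contiguous with env: the readthrough is a verbatim genome substring
  seg <- sc$transcript$segments
  expect_equal(sc$transcript$cdna,
               substr(d$genome$seq, seg[1, 1] + 1, seg[1, 2]))
  expect_equal(sc$classification$category, "truncated")
})

test_that("a 1-bp exon-2 insertion still splices, one base longer", {
  d <- degrade(ref, list(edit_frameshift(95L, 1L)), "ins1")
  sc <- scan_locus(d$genome, ref)
  expect_equal(sc$transcript$mode, "spliced")
  expect_equal(nchar(sc$transcript$cdna), nchar(reference_rec(ref)$cdna) + 1L)
  expect_true(sc$classification$frameshifted)
  expect_equal(sc$classification$category, "truncated")
})

test_that("protein classification flags stops, coverage and extension", {
  expect_equal(classify_protein(paste0(con$aa, "*"), con)$category, "full_length")
  injected <- paste0(substr(con$aa, 1, 39), "*", substr(con$aa, 41, 105), "*")
  cls <- classify_protein(injected, con)
  expect_equal(cls$category, "truncated")
  expect_equal(cls$premature_stop_position, 40L)
  # reading past the natural stop makes the protein extended
  cls_ext <- classify_protein(paste0(con$aa, "GSSG", "*"), con)
  expect_equal(cls_ext$category, "extended")
  # acceptor failure dominates
  expect_equal(classify_protein(paste0(con$aa, "*"), con,
                                acceptor_intact = FALSE)$category, "no_acceptor")
  # a cDNA-level frameshift forces truncated
  expect_equal(classify_protein(paste0(con$aa, "*"), con,
                                frameshifted = TRUE)$category, "truncated")
  expect_equal(classify_protein("*", con)$category, "truncated")
})

test_that("variant calls on the engineered trans-dominant analog and its revertants", {
  # N2H + E34del (the strongly trans-dominant two-change pattern)
  v12 <- call_variants(apply_variants(con, data.frame(
    kind = c("substitution", "deletion"), con_position = c(2L, 34L),
    ref_aa = c("N", "E"), alt_aa = c("H", ""))), con)
  expect_setequal(v12$label, c("N2H", "E34del"))
  # revertant 1 restores E34: only the N-terminal substitution remains
  v1 <- call_variants(apply_variants(con, data.frame(
    kind = "substitution", con_position = 2L, ref_aa = "N", alt_aa = "H")), con)
  expect_equal(v1$label, "N2H")
  # revertant 2 restores the N2 residue: only the deletion remains
  v2 <- call_variants(apply_variants(con, data.frame(
    kind = "deletion", con_position = 34L, ref_aa = "E", alt_aa = "")), con)
  expect_equal(v2$label, "E34del")
  # lysine insertion at position 62
  vK <- call_variants(apply_variants(con, data.frame(
    kind = "insertion", con_position = 62L, ref_aa = "", alt_aa = "K")), con)
  expect_equal(vK$label, "62insK")
  expect_false(any(v12$in_nls) || any(v12$in_nes))
  # consensus vs consensus: no variants
  expect_equal(nrow(call_variants(con$aa, con)), 0L)
  # truncated input is refused with a pointer to classification
  expect_error(call_variants(substr(con$aa, 1, 40), con), "classif")
  expect_error(call_variants(paste0(substr(con$aa, 1, 40), "*"), con), "stop")
})

test_that("labels are pure functions of kind, position and residues", {
  expect_equal(variant_label("substitution", 2, "N", "H"), "N2H")
  expect_equal(variant_label("deletion", 34, "E", ""), "E34del")
  expect_equal(variant_label("deletion", 34, "EKL", ""), "E34_L36del")
  expect_equal(variant_label("insertion", 62, "", "K"), "62insK")
  expect_error(variant_label("inversion", 1, "A", "B"), "unknown")
})

test_that("called variants applied to the consensus rebuild the protein (200 mutants)", {
  set.seed(1234)
  aa_pool <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "")
  clen <- nchar(con$aa)
  for (case in 1:200) {
    k <- sample(1:5, 1)
    # widely separated internal edits keep the edit set unambiguous: closely
    # spaced insertion/deletion pairs have equivalent substitution scripts,
    # and deleting one of two identical neighbours has two equivalent names
    pos <- sort(sample(seq(5, clen - 5, by = 8), k))
    vars <- NULL
    for (p in pos) {
      kind <- sample(c("substitution", "deletion", "insertion"), 1)
      refres <- substr(con$aa, p, p)
      if (kind == "deletion" &&
          refres %in% c(substr(con$aa, p - 1, p - 1), substr(con$aa, p + 1, p + 1)))
        kind <- "substitution"
      if (kind == "substitution") {
        alt <- sample(setdiff(aa_pool, refres), 1)
        vars <- rbind(vars, data.frame(kind = kind, con_position = p,
                                       ref_aa = refres, alt_aa = alt))
      } else if (kind == "deletion") {
        vars <- rbind(vars, data.frame(kind = kind, con_position = p,
                                       ref_aa = refres, alt_aa = ""))
      } else {
        flank <- c(substr(con$aa, p - 1, p - 1), refres)
        alt <- sample(setdiff(aa_pool, flank), 1)
        vars <- rbind(vars, data.frame(kind = kind, con_position = p,
                                       ref_aa = "", alt_aa = alt))
      }
    }
    mutant <- apply_variants(con, vars)
    called <- call_variants(mutant, con)
    # round trip: applying the called variants reconstructs the mutant
    expect_equal(apply_variants(con, called), mutant)
    # exact edit-set recovery for separated edits
    expect_setequal(called$label,
                    vapply(seq_len(nrow(vars)), function(i)
                      variant_label(vars$kind[i], vars$con_position[i],
                                    vars$ref_aa[i], vars$alt_aa[i]),
                      character(1)))
  }
})

test_that("identical proteins group together", {
  aa <- c(a = "MAR", b = "MAR", c = "MKR", d = "MAR", e = "MQR", f = "MAR",
          g = "MAR")
  d <- dedupe_proteins(aa)
  expect_equal(nrow(d$groups), 3L)
  expect_equal(sort(d$groups$size, decreasing = TRUE), c(5L, 1L, 1L))
  expect_equal(d$group_id[1], d$group_id[2])
  empty <- dedupe_proteins(character(0))
  expect_equal(nrow(empty$groups), 0L)
})
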
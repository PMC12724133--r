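test_that("aligner matches the brute-force enumeration oracle", {
  schemes <- list(list(match = 5, mismatch = -4, open = 10, ext = 0.5),
                  list(match = 2, mismatch = -2, open = 3, ext = 1))
  check_pair <- function(q, r, sc, free) {
    p <- alignment_params(sc$match, sc$mismatch, sc$open, sc$ext,
                          free_end_gaps = free)
    got <- align_global(q, r, p)
    my_score <- score_moves(q, r, got$moves, sc$match, sc$mismatch,
                            sc$open, sc$ext, free_ends = free)
    # the emitted alignment must price at the reported score (validity) ...
    expect_equal(my_score, got$score)
    # ... and the reported score must equal the enumeration optimum
    expect_equal(got$score,
                 oracle_best(q, r, sc$match, sc$mismatch, sc$open, sc$ext,
                             free_ends = free))
  }
  # exhaustive over all pairs of lengths 1-2
  bases <- c("A", "C", "G", "T")
  short <- c(bases, as.vector(outer(bases, bases, paste0)))
  for (sc in schemes) for (q in short[c(1, 3, 5:12, 17)]) for (r in short)
    check_pair(q, r, sc, free = FALSE)
  # seeded random pairs up to length 5, both end-gap modes
  set.seed(42)
  for (k in 1:30) {
    q <- random_dna(sample(3:5, 1)); r <- random_dna(sample(3:5, 1))
    check_pair(q, r, schemes[[k %% 2 + 1]], free = k %% 3 == 0)
  }
  # a few longer pairs (enumeration is heavier here)
  for (k in 1:3) {
    q <- random_dna(7); r <- random_dna(8)
    check_pair(q, r, schemes[[1]], free = FALSE)
  }
})

test_that("worked example: ACGT vs AGT carries a single gap", {
  p <- alignment_params(2, -2, 3, 1, free_end_gaps = FALSE)
  got <- align_global("ACGT", "AGT", p)
  expect_equal(got$score,
               oracle_best("ACGT", "AGT", 2, -2, 3, 1))
  expect_equal(sum(strsplit(got$moves, "")[[1]] == "U"), 1L)
})

test_that("alignment score agrees with Biostrings pairwiseAlignment", {
  set.seed(7)
  for (k in 1:5) {
    q <- random_dna(60); r <- random_dna(55)
    p <- alignment_params(5, -4, 10, 1, free_end_gaps = FALSE)
    got <- align_global(q, r, p)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                    baseOnly = TRUE)
    # Biostrings prices a gap of length L at gapOpening + L * gapExtension
    ref <- Biostrings::pairwiseAlignment(q, r, substitutionMatrix = mat,
                                         gapOpening = 9, gapExtension = 1,
                                         type = "global", scoreOnly = TRUE)
    expect_equal(got$score, ref)
  }
})

test_that("self-alignment is the identity with full identity", {
  ref <- make_reference(11)
  m <- align_global(ref$genome, ref$genome)
  expect_equal(m$identity, 1)
  expect_false(grepl("[UL]", m$moves))
  expect_equal(m$score, 5 * ref$genome$length)
})

test_that("alignment is deterministic across repeated calls", {
  set.seed(5)
  q <- random_dna(300); r <- random_dna(280)
  m1 <- align_global(q, r); m2 <- align_global(q, r)
  expect_identical(m1$moves, m2$moves)
  expect_identical(m1$score, m2$score)
})

test_that("an engineered 292-base excision aligns as one reference-only run", {
  ref <- make_reference(3)
  t1 <- derive_type1_reference(ref)
  m <- align_global(t1$genome, ref$genome)
  runs <- rle(strsplit(m$moves, "")[[1]])
  lruns <- runs$lengths[runs$values == "L"]
  expect_equal(lruns, 292L)
})

test_that("empty sequences and high-N content are handled as specified", {
  expect_error(align_global("", "ACGT"), "empty")
  expect_warning(m <- align_global("ANNNN", "ACGTA"), "ambiguous")
  expect_true(m$high_n)
})

test_that("orientation detection recovers the strand and is an involution", {
  ref <- make_reference(21)
  expect_equal(choose_orientation(ref$genome, ref$genome)$orientation, "+")
  rc <- genome_sequence("rc", revcomp(ref$genome$seq))
  o <- choose_orientation(rc, ref$genome)
  expect_equal(o$orientation, "-")
  expect_equal(o$query$seq, ref$genome$seq)
  # involution: re-running on the oriented output returns "+"
  expect_equal(choose_orientation(o$query, ref$genome)$orientation, "+")

  set.seed(99)
  ref1k <- substr(ref$genome$seq, 1001, 2000)
  hits <- 0L
  for (k in 1:50) {
    qc <- strsplit(ref1k, "")[[1]]
    idx <- sample(1000, 25)   # sprinkle mutations so strands are asymmetric
    qc[idx] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
    q <- paste(qc, collapse = "")
    flip <- k %% 2 == 0
    if (flip) q <- revcomp(q)
    o <- choose_orientation(q, ref1k)
    hits <- hits + (o$orientation == if (flip) "-" else "+")
  }
  expect_equal(hits, 50L)
})
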
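# Truth-labelled synthetic inputs. The toy reference reproduces the layout the
# analysis assumes -- LTRs, a major splice donor, an env ORF whose first 87
# codons form rec exon 1, a GT donor / AG acceptor pair, and an overlapping
# rec exon 2 in a shifted reading frame -- at ~3.6 kb so that alignment
# oracles stay feasible in tests. It is synthetic throughout: no real HERV-K
# sequence is embedded.

# fixed layout (0-based, half-open)
TOY <- list(
  len = 2800L,
  ltr5 = c(0L, 250L), ltr3 = c(2550L, 2800L),
  major_donor = 260L,
  gag = c(300L, 700L), pro = c(700L, 950L), pol = c(950L, 1550L),
  exon1_acceptor = 1599L,
  env = c(1600L, 2500L), env_sp = c(1600L, 1885L),
  rec_exon1 = c(1600L, 1861L),
  exon1_donor = 1861L,
  exon2_acceptor = 2399L,
  rec_exon2 = c(2400L, 2457L),
  stop_mutation_pos = 1609L,
  type1_deletion = c(1617L, 1909L)
)

NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all3[!all3 %in% c("TAA", "TAG", "TGA")]
}

#' Generate the annotated toy type-2 reference
#'
#' Builds a seeded, deterministic ~3.6 kb provirus with 5'/3' LTRs, gag/pro/
#' pol/env spans, a 261-nt rec exon 1 (87 codons, mirroring the exon-1
#' protein length), a 57-nt rec exon 2 in a shifted env frame, correct GT/AG
#' dinucleotides at all four annotated splice sites, and the A (-> T)
#' stop/new-donor signature context upstream of the configured 292-bp
#' type-1 deletion interval. The env frame is stop-free from its ATG to its
#' terminal stop, as is rec exon 2 in its own frame, so the spliced Rec cDNA
#' translates cleanly.
#'
#' @param seed integer seed; the same seed always returns the same reference.
#' @param nls,nes NLS/NES residue ranges recorded in the consensus profile.
#' @return An [annotated_reference()] whose `config` carries the type-1
#'   deletion interval and signature position.
#' @export
make_reference <- function(seed = 1L, nls = c(13L, 20L), nes = c(50L, 60L)) {
  rng <- local_rng(seed)
  g <- rng$sample(c("A", "C", "G", "T"), TOY$len, replace = TRUE)

  # env region as env-frame codons [2200, 3100): 300 codons
  n_codons <- (TOY$env[2] - TOY$env[1]) %/% 3L
  codons <- rng$sample(NONSTOP_CODONS, n_codons, replace = TRUE)
  fixed <- c("1" = "ATG",   # exon-1 start
             "2" = "AAC",   # N at protein position 2
             "3" = "CCG",   # ends G: the GA context of the type-1 signature
             "4" = "AAA",   # A->T at codon 4 gives a TAA stop and a GT donor
             "33" = "CAA", "34" = "GAA", "35" = "CCA", # E34 flanked by non-E
             "61" = "CAC", "62" = "GAC",  # keep K insertions at 62 unambiguous
             "88" = "GTC",  # GT donor at the exon-1/intron boundary
             "267" = "AGC", # AG acceptor ending the intron before exon 2
             "285" = "CCT", "286" = "AAC", # exon-2 frame TAA terminator
             "300" = "TAA") # env stop
  codons[as.integer(names(fixed))] <- fixed
  # remove stops arising in the exon-2 reading frame (third-base T followed
  # by AA/AG/GA across env-codon junctions), within rec exon 2 only; the
  # replacement set can break neither the forward nor the backward junction
  safe <- NONSTOP_CODONS[substr(NONSTOP_CODONS, 3, 3) != "T" &
                         !substr(NONSTOP_CODONS, 1, 2) %in% c("AA", "AG", "GA")]
  for (i in 267:284) {
    if (substr(codons[i], 3, 3) == "T" &&
        substr(codons[i + 1], 1, 2) %in% c("AA", "AG", "GA")) {
      codons[i] <- rng$sample(safe, 1)
    }
  }
  g[(TOY$env[1] + 1L):TOY$env[2]] <- strsplit(paste(codons, collapse = ""), "")[[1]]

  g[(TOY$ltr3[1] + 1L):TOY$ltr3[2]] <- g[(TOY$ltr5[1] + 1L):TOY$ltr5[2]] # LTR repeat
  g[TOY$major_donor + 1:2] <- c("G", "T")
  g[TOY$exon1_acceptor + 0:1] <- c("A", "G")

  seq <- paste(g, collapse = "")
  ft <- feature_table(
    name = c("ltr5", "gag", "pro", "pol", "env", "env_sp", "rec_exon1",
             "rec_exon2", "ltr3"),
    start = c(TOY$ltr5[1], TOY$gag[1], TOY$pro[1], TOY$pol[1], TOY$env[1],
              TOY$env_sp[1], TOY$rec_exon1[1], TOY$rec_exon2[1], TOY$ltr3[1]),
    end = c(TOY$ltr5[2], TOY$gag[2], TOY$pro[2], TOY$pol[2], TOY$env[2],
            TOY$env_sp[2], TOY$rec_exon1[2], TOY$rec_exon2[2], TOY$ltr3[2]),
    phase = c(NA, 0L, 0L, 0L, 0L, 0L, 0L, 0L, NA))
  ss <- splice_table(
    label = c("major_donor", "rec_exon1_acceptor", "rec_exon1_donor",
              "rec_exon2_acceptor"),
    kind = c("donor", "acceptor", "donor", "acceptor"),
    position = c(TOY$major_donor, TOY$exon1_acceptor, TOY$exon1_donor,
                 TOY$exon2_acceptor))
  ref <- annotated_reference(genome_sequence("toyK_con", seq), ft, ss,
                             provirus_type = "type2",
                             config = list(type1_deletion = TOY$type1_deletion,
                                           stop_mutation_pos = TOY$stop_mutation_pos,
                                           nls = as.integer(nls),
                                           nes = as.integer(nes)))
  # self-checks: the construction must satisfy its own contract
  rec <- reference_rec(ref, nls = nls, nes = nes)
  stopifnot(nchar(rec$profile$aa) == 105L,
            substr(rec$profile$aa, 1, 1) == "M",
            !grepl("\\*", rec$profile$aa))
  env_aa <- translate_cdna(feature_seq(ref, "env"))
  stopifnot(regexpr("*", env_aa, fixed = TRUE) == 300L)
  ref
}

# tiny seeded RNG scope helper: isolates generator randomness from the
# caller's RNG state
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  with_state <- function(f) function(...) {
    old2 <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old2)) assign(".Random.seed", old2, globalenv()) else
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    f(...)
  }
  list(sample = with_state(sample),
       runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       rlnorm = with_state(stats::rlnorm),
       rbinom = with_state(stats::rbinom))
}

# --- mutation edits ---------------------------------------------------------

#' Mutation edit constructors for the synthetic generator
#'
#' Each constructor returns one edit of a `mutation_spec` (a plain list of
#' edits) applied by [degrade()]. Edits address either genome coordinates or
#' consensus Rec codon positions (1-based, 1-87 in exon 1, 88-105 in exon 2).
#'
#' @param pos,base genome position (0-based) and replacement base.
#' @param site_label,dinucleotide splice-site label and its replacement 2-mer.
#' @param codon_index consensus codon receiving a TAA stop.
#' @param con_pos consensus position of an amino-acid edit.
#' @param new_aa replacement or inserted residue.
#' @param n_codons length of an in-frame deletion.
#' @param indel_len inserted (+) or deleted (-) base count, not a multiple
#'   of 3.
#' @name mutation_edits
NULL

#' @rdname mutation_edits
#' @export
edit_type1_deletion <- function() list(type = "type1_deletion")
#' @rdname mutation_edits
#' @export
edit_point <- function(pos, base) list(type = "point", pos = pos, base = base)
#' @rdname mutation_edits
#' @export
edit_splice <- function(site_label, dinucleotide)
  list(type = "splice", label = site_label, dinuc = dinucleotide)
#' @rdname mutation_edits
#' @export
edit_premature_stop <- function(codon_index)
  list(type = "stop", codon = codon_index)
#' @rdname mutation_edits
#' @export
edit_frameshift <- function(con_pos, indel_len = 1L)
  list(type = "frameshift", con_pos = con_pos, indel_len = indel_len)
#' @rdname mutation_edits
#' @export
edit_aa_sub <- function(con_pos, new_aa)
  list(type = "aa_sub", con_pos = con_pos, new_aa = new_aa)
#' @rdname mutation_edits
#' @export
edit_aa_del <- function(con_pos, n_codons = 1L)
  list(type = "aa_del", con_pos = con_pos, n_codons = n_codons)
#' @rdname mutation_edits
#' @export
edit_aa_ins <- function(con_pos, new_aa)
  list(type = "aa_ins", con_pos = con_pos, new_aa = new_aa)
#' @rdname mutation_edits
#' @export
edit_synonymous <- function(con_pos) list(type = "synonymous", con_pos = con_pos)
#' @rdname mutation_edits
#' @export
edit_strand_flip <- function() list(type = "strand_flip")

codon_genome_start <- function(con_pos) {
  stopifnot(con_pos >= 1L, con_pos <= 105L)
  if (con_pos <= 87L) TOY$rec_exon1[1] + 3L * (con_pos - 1L)
  else TOY$rec_exon2[1] + 3L * (con_pos - 88L)
}

# fixed codon per amino acid (first of the sorted synonymous set)
aa_to_codon <- function(aa) {
  tab <- Biostrings::GENETIC_CODE
  sort(names(tab)[tab == aa])[1]
}

#' Apply a mutation spec to the reference and derive the expected calls
#'
#' Edits are validated for overlap and applied from the highest genome
#' coordinate down (so stored coordinates stay valid); a strand flip, if
#' present, is applied last. The truth row is derived deterministically from
#' the edit list alone -- never by running the analysis pipeline -- and
#' records the expected provirus type, splice intactness, transcript mode,
#' protein category, premature-stop index, frameshift flag, variant labels
#' and orientation.
#'
#' @param ref the [make_reference()] output the panel is degraded from.
#' @param edits a list of edits from the [mutation_edits] constructors.
#' @param locus_id identifier for the derived locus.
#' @return A list with `genome` (a [genome_sequence()]) and `truth` (one-row
#'   data.frame).
#' @export
degrade <- function(ref, edits, locus_id = "locus") {
  con <- reference_rec(ref)$profile
  con_aa <- strsplit(con$aa, "")[[1]]

  flip <- any(vapply(edits, function(e) e$type == "strand_flip", logical(1)))
  edits <- Filter(function(e) e$type != "strand_flip", edits)

  # genome interval touched by each edit, for overlap validation
  span <- function(e) {
    switch(e$type,
      type1_deletion = ref$config$type1_deletion,
      point = c(e$pos, e$pos + 1L),
      splice = {
        s <- ref$splice_sites[ref$splice_sites$label == e$label, ]
        if (s$kind == "donor") c(s$position, s$position + 2L)
        else c(s$position - 1L, s$position + 1L)
      },
      stop = c(codon_genome_start(e$codon), codon_genome_start(e$codon) + 3L),
      frameshift = c(codon_genome_start(e$con_pos), codon_genome_start(e$con_pos) + 3L),
      aa_sub = c(codon_genome_start(e$con_pos), codon_genome_start(e$con_pos) + 3L),
      aa_del = c(codon_genome_start(e$con_pos),
                 codon_genome_start(e$con_pos) + 3L * e$n_codons),
      aa_ins = c(codon_genome_start(e$con_pos), codon_genome_start(e$con_pos)),
      synonymous = c(codon_genome_start(e$con_pos), codon_genome_start(e$con_pos) + 3L))
  }
  if (length(edits) > 1L) {
    sp <- t(vapply(edits, span, numeric(2)))
    ord <- order(sp[, 1])
    s <- sp[ord, , drop = FALSE]
    if (any(s[-1, 1] < s[-nrow(s), 2]))
      stop("conflicting (overlapping) edits in mutation spec")
  }

  seq <- ref$genome$seq
  patch <- function(seq, at0, replacement) {   # replace [at0, at0+len)
    paste0(substr(seq, 1L, at0),
           replacement,
           substr(seq, at0 + nchar(replacement) + 1L, nchar(seq)))
  }
  excise <- function(seq, iv) paste0(substr(seq, 1L, iv[1]),
                                     substr(seq, iv[2] + 1L, nchar(seq)))

  # truth accumulators
  type <- "type2"; donor_ok <- TRUE; acceptor_ok <- TRUE
  stop_idx <- NA_integer_; fshift <- FALSE
  labels <- character(0); big_del <- FALSE

  ord <- order(vapply(edits, function(e) span(e)[1], numeric(1)), decreasing = TRUE)
  for (e in edits[ord]) {
    switch(e$type,
      type1_deletion = {
        iv <- ref$config$type1_deletion
        seq <- patch(seq, ref$config$stop_mutation_pos, "T")
        seq <- excise(seq, iv)
        type <- "type1"
      },
      point = { seq <- patch(seq, e$pos, e$base) },
      splice = {
        s <- ref$splice_sites[ref$splice_sites$label == e$label, ]
        at <- if (s$kind == "donor") s$position else s$position - 1L
        seq <- patch(seq, at, e$dinuc)
        if (e$label == "rec_exon1_donor" && e$dinuc != "GT") donor_ok <- FALSE
        if (e$label == "rec_exon2_acceptor" && e$dinuc != "AG") acceptor_ok <- FALSE
      },
      stop = {
        seq <- patch(seq, codon_genome_start(e$codon), "TAA")
        stop_idx <- min(stop_idx, e$codon, na.rm = TRUE)
      },
      frameshift = {
        at <- codon_genome_start(e$con_pos)
        if (e$indel_len > 0L) {
          seq <- paste0(substr(seq, 1L, at),
                        strrep("C", e$indel_len),
                        substr(seq, at + 1L, nchar(seq)))
        } else {
          seq <- excise(seq, c(at, at - e$indel_len))
        }
        fshift <- TRUE
      },
      aa_sub = {
        seq <- patch(seq, codon_genome_start(e$con_pos), aa_to_codon(e$new_aa))
        labels <- c(labels, variant_label("substitution", e$con_pos,
                                          con_aa[e$con_pos], e$new_aa))
      },
      aa_del = {
        at <- codon_genome_start(e$con_pos)
        seq <- excise(seq, c(at, at + 3L * e$n_codons))
        run <- paste(con_aa[e$con_pos:(e$con_pos + e$n_codons - 1L)], collapse = "")
        if (3L * e$n_codons >= 30L) big_del <- TRUE
        else labels <- c(labels, variant_label("deletion", e$con_pos, run, ""))
      },
      aa_ins = {
        at <- codon_genome_start(e$con_pos)
        seq <- paste0(substr(seq, 1L, at), aa_to_codon(e$new_aa),
                      substr(seq, at + 1L, nchar(seq)))
        labels <- c(labels, variant_label("insertion", e$con_pos, "", e$new_aa))
      },
      synonymous = {
        at <- codon_genome_start(e$con_pos)
        cur <- substr(seq, at + 1L, at + 3L)
        syn <- sort(names(Biostrings::GENETIC_CODE)[
          Biostrings::GENETIC_CODE == Biostrings::GENETIC_CODE[[cur]]])
        alt <- setdiff(syn, cur)
        if (!length(alt)) stop("codon at consensus position ", e$con_pos,
                               " has no synonym")
        seq <- patch(seq, at, alt[1])
      })
  }

  orientation <- "+"
  if (flip) { seq <- revcomp(seq); orientation <- "-" }

  # expected downstream calls
  if (type == "type1") {
    mode <- NA_character_; category <- NA_character_
    stop_idx <- NA_integer_; fshift <- NA; labels <- character(0)
  } else if (!donor_ok || !acceptor_ok) {
    mode <- "exon1_readthrough"
    category <- if (!acceptor_ok) "no_acceptor" else "truncated"
    # the readthrough runs clean to the env terminal stop: no internal stop
    labels <- character(0)
  } else {
    mode <- "spliced"
    category <- if (!is.na(stop_idx) || fshift || big_del) "truncated" else "full_length"
    if (category == "truncated") labels <- character(0)
  }

  truth <- data.frame(
    locus_id = locus_id, orientation = orientation, provirus_type = type,
    donor_intact = donor_ok, acceptor_intact = acceptor_ok,
    transcript_mode = mode, category = category,
    premature_stop_position = stop_idx, frameshifted = fshift,
    variant_labels = paste(sort(labels), collapse = ";"),
    stringsAsFactors = FALSE)
  list(genome = genome_sequence(locus_id, seq), truth = truth)
}

# neutral point mutations in gag/pro/pol filler, away from annotated motifs
neutral_snps <- function(ref, rng, n) {
  pos <- rng$sample(320:1540, n)
  edits <- lapply(pos, function(p) {
    cur <- substr(ref$genome$seq, p + 1L, p + 1L)
    edit_point(p, rng$sample(setdiff(c("A", "C", "G", "T"), cur), 1))
  })
  edits
}

#' Generate a truth-labelled provirus panel with a class mixture
#'
#' Draws `n_loci` degraded copies of the reference with stratified class
#' counts: type-1 deletion carriers, clean type-2 loci, premature-stop
#' mutants, splice-site mutants, and strand-flipped clean loci. Every locus
#' additionally carries a few neutral substitutions in the gag/pro/pol
#' filler so alignments are non-trivial. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_loci panel size.
#' @param mixture named class proportions summing to 1 (`type1`, `clean`,
#'   `stop`, `splice`, `flip`).
#' @param ref optional prebuilt reference (defaults to `make_reference(seed)`).
#' @return A list: `ref`, `sequences` (named character vector), `truth`
#'   (data.frame).
#' @export
make_panel <- function(seed = 1L, n_loci = 60L,
                       mixture = c(type1 = 0.30, clean = 0.25, stop = 0.25,
                                   splice = 0.10, flip = 0.10),
                       ref = NULL) {
  stopifnot(n_loci >= 1L, abs(sum(mixture) - 1) < 1e-9)
  if (is.null(ref)) ref <- make_reference(seed)
  rng <- local_rng(seed + 104729L)

  counts <- floor(mixture * n_loci)
  rem <- n_loci - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  classes <- rep(names(counts), counts)

  seqs <- character(n_loci); names(seqs) <- sprintf("locus%02d", seq_len(n_loci))
  truth <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    id <- names(seqs)[i]
    edits <- neutral_snps(ref, rng, n = 3L + rng$sample(0:5, 1))
    edits <- c(edits, switch(classes[i],
      type1 = list(edit_type1_deletion()),
      clean = list(),
      stop = list(edit_premature_stop(rng$sample(10:100, 1))),
      splice = if (rng$runif(1) < 0.5)
        list(edit_splice("rec_exon1_donor", "GA"))
      else list(edit_splice("rec_exon2_acceptor", "GG")),
      flip = list(edit_strand_flip())))
    d <- degrade(ref, edits, locus_id = id)
    seqs[i] <- d$genome$seq
    d$truth$class <- classes[i]
    truth[[i]] <- d$truth
  }
  list(ref = ref, sequences = seqs, truth = do.call(rbind, truth))
}

#' Generate the synthetic 55-locus study-composition panel
#'
#' A synthetic stand-in for the study's 55 type-2 loci, engineered so the
#' known truth reproduces the reported composition: 25 loci encode
#' full-length Rec proteins (1 consensus-identical clean locus, 4 loci whose
#' nucleotide changes are all synonymous, 18 loci with 1-3 distinct amino
#' acid substitutions, one locus carrying \{N2H, E34del\} and one carrying
#' 62insK), 29 loci are truncated (premature stops, frameshifts, large
#' in-frame deletions, donor-site mutants, stop+substitution combinations),
#' and 1 locus carries the AG->GG exon-2 acceptor mutation. Several loci are
#' deposited on the minus strand. All sequences are synthetic; locus ids
#' ending in `_like` mark loci that mirror a reported mutation pattern, not
#' real genomic sequence.
#'
#' @param seed integer seed.
#' @param ref optional prebuilt reference.
#' @return As [make_panel()]: `ref`, `sequences`, `truth`.
#' @export
make_study_panel <- function(seed = 1L, ref = NULL) {
  if (is.null(ref)) ref <- make_reference(seed)
  rng <- local_rng(seed + 224737L)
  con_aa <- strsplit(reference_rec(ref)$profile$aa, "")[[1]]

  sub_alphabet <- c("A", "S", "G", "V", "R", "Q")
  pick_sub <- function(pos, k) {
    aa <- sub_alphabet[(k - 1L) %% length(sub_alphabet) + 1L]
    if (aa == con_aa[pos]) aa <- sub_alphabet[k %% length(sub_alphabet) + 1L]
    edit_aa_sub(pos, aa)
  }

  loci <- list()
  add <- function(id, edits) loci[[id]] <<- edits

  # -- 25 full-length --
  add("synCon", list())
  # exon-1 positions with degenerate codons, skipping the pinned residues
  degenerate <- which(vapply(seq_len(87L), function(p) {
    cod <- substr(ref$genome$seq, codon_genome_start(p) + 1L,
                  codon_genome_start(p) + 3L)
    sum(Biostrings::GENETIC_CODE == Biostrings::GENETIC_CODE[[cod]]) > 1L
  }, logical(1)))
  syn_positions <- setdiff(degenerate, c(1:4, 33:35, 61:62))
  syn_positions <- syn_positions[c(5L, 15L, 25L, 35L)]
  for (i in 1:4) add(sprintf("synSyn%02d", i),
                     lapply(syn_positions[seq_len(1L + (i - 1L) %% 3L)],
                            function(p) edit_synonymous(p)))
  add("syn12q14_like", list(edit_aa_sub(2L, "H"), edit_aa_del(34L)))
  add("syn12p11_like", list(edit_aa_ins(62L, "K")))
  for (i in 1:18) {
    pos <- if (i <= 6) 10L + i
           else if (i <= 12) c(10L + i, 40L + i)
           else c(10L + i, 40L + i, 58L + i)
    add(sprintf("synVar%02d", i),
        lapply(seq_along(pos), function(j) pick_sub(pos[j], i + j)))
  }

  # -- 29 truncated --
  stop_at <- c(12L, 19L, 26L, 33L, 40L, 47L, 54L, 61L, 68L, 75L)
  for (i in seq_along(stop_at))
    add(sprintf("synStop%02d", i), list(edit_premature_stop(stop_at[i])))
  fs <- list(c(20L, 1L), c(35L, 2L), c(50L, 1L), c(25L, -1L), c(45L, -2L), c(65L, -1L))
  for (i in seq_along(fs))
    add(sprintf("synFs%02d", i), list(edit_frameshift(fs[[i]][1], fs[[i]][2])))
  bigdel <- list(c(30L, 15L), c(35L, 18L), c(40L, 20L), c(28L, 22L),
                 c(32L, 25L), c(45L, 16L))
  for (i in seq_along(bigdel))
    add(sprintf("synDel%02d", i),
        list(edit_aa_del(bigdel[[i]][1], bigdel[[i]][2])))
  for (i in 1:4)
    add(sprintf("synDonor%02d", i), list(edit_splice("rec_exon1_donor", "GA")))
  for (i in 1:3)
    add(sprintf("synCombo%02d", i),
        list(pick_sub(8L + i, i + 3L), edit_premature_stop(28L + 7L * i)))

  # -- 1 acceptor mutant (AG -> GG) --
  add("syn10q24_like", list(edit_splice("rec_exon2_acceptor", "GG")))

  flip_ids <- c("synSyn02", "synVar03", "synVar11", "synStop04", "synFs02",
                "synDel05", "synDonor03")
  stopifnot(length(loci) == 55L)

  seqs <- character(length(loci)); names(seqs) <- names(loci)
  truth <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    id <- names(loci)[i]
    edits <- c(neutral_snps(ref, rng, n = 2L + rng$sample(0:4, 1)), loci[[id]])
    if (id %in% flip_ids) edits <- c(edits, list(edit_strand_flip()))
    d <- degrade(ref, edits, locus_id = id)
    seqs[i] <- d$genome$seq
    truth[[i]] <- d$truth
  }
  list(ref = ref, sequences = seqs, truth = do.call(rbind, truth))
}
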
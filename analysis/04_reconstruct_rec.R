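#!/usr/bin/env Rscript
# Reconstruct Rec for the type-2 loci of the study-composition panel:
# splice-site checks, in-silico splicing (or exon-1/env readthrough),
# translation, truncation classification, deduplication and variant calling.
# Reports the full-length/truncated partition, the distinct-protein count,
# the consensus-identical group, and the variant table.
#
# Reads:  results/panels/study.fasta (run 02 first)
# Writes: results/rec/rec_cdna.fasta, rec_protein.fasta, categories.tsv,
#         variants.tsv, groups.tsv

library(hervrec)

seed <- 1L
dir.create("results/rec", recursive = TRUE, showWarnings = FALSE)
ref <- make_reference(seed)
seqs <- read_fasta("results/panels/study.fasta")

out <- scan_panel(seqs, ref2 = ref)

cdnas <- vapply(out$scans, function(s)
  if (is.null(s$transcript)) "" else s$transcript$cdna, character(1))
keep <- nchar(cdnas) >= 3
write_fasta(cdnas[keep], "results/rec/rec_cdna.fasta")
write_protein_fasta(vapply(out$scans[keep], function(s) s$aa, character(1)),
                    "results/rec/rec_protein.fasta")

write.table(out$results[, c("locus_id", "transcript_mode", "category",
                            "premature_stop_position", "frameshifted",
                            "coverage", "variant_labels")],
            "results/rec/categories.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (!is.null(out$variants))
  write.table(out$variants, "results/rec/variants.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
write.table(out$groups$groups, "results/rec/groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("category counts:\n")
print(table(out$results$category, useNA = "ifany"))
cat(sprintf("\ndistinct full-length Rec proteins: %d\n",
            nrow(out$groups$groups)))
con_aa <- reference_rec(ref)$profile$aa
cat(sprintf("consensus-identical group size: %d\n",
            out$groups$groups$size[out$groups$groups$aa == con_aa]))
v <- out$variants[out$variants$locus_id == "syn12q14_like", ]
cat(sprintf("trans-dominant analog variants: %s\n",
            paste(v$label, collapse = ", ")))
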
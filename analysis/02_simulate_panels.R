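#!/usr/bin/env Rscript
# Generate the truth-labelled proviral panels: a 60-locus mixture panel
# (type-1 carriers, clean type-2, premature stops, splice mutants, strand
# flips) and the 55-locus study-composition panel whose engineered truth
# mirrors the reported composition (25 full-length / 29 truncated / 1
# acceptor mutant; 5 consensus-identical proteins; an N2H+E34del locus and a
# 62insK locus).
#
# Writes: results/panels/{mixture,study}.fasta and *_truth.tsv

library(hervrec)

seed <- 1L
dir.create("results/panels", recursive = TRUE, showWarnings = FALSE)

p <- make_panel(seed = seed, n_loci = 60)
write_fasta(p$sequences, "results/panels/mixture.fasta")
write.table(p$truth, "results/panels/mixture_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mixture panel classes:\n")
print(table(p$truth$class))

sp <- make_study_panel(seed = seed)
write_fasta(sp$sequences, "results/panels/study.fasta")
write.table(sp$truth, "results/panels/study_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nstudy-composition panel truth categories:\n")
print(table(sp$truth$category, useNA = "ifany"))
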
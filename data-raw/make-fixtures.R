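# Builds the packaged synthetic sequence-family fixture and its golden
# classification report. Run from the package root with the package installed.
library(ndqkit)

fam <- generate_sequence_family(
  n_per_class = c(Subgroup1 = 30, Subgroup2 = 30),
  mutation_rate = 0.20, gap_rate = 0.02, seed = 42L)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_fasta(fam$records, "inst/extdata/ndq_family_aln.fasta")
write.table(fam$labels, "inst/extdata/ndq_family_labels.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

aln <- ref_alignment(fam$records, reference_id = fam$reference_id)
report <- classify_ndq(aln)
write.table(report, "inst/extdata/ndq_family_report.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("kept:", sum(report$kept),
    "representatives:", length(attr(report, "clustering")$representatives), "\n")
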
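#!/usr/bin/env Rscript

# Apply the dataset filters (nonstandard residues, minimum length 10, the
# 100-residue cap for antimicrobial peptides, exact-duplicate removal) and
# record the per-step removal ledger for every set. On clean synthetic data
# the interesting check is the duplicate step: random peptides of length 10+
# essentially never collide, so removals here should be zero — corrupted
# variants with planted violations are exercised in the test suite instead.

suppressPackageStartupMessages(library(gappedmotifs))

ddir <- "results/data"
out <- "results/filtered"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (stem in c("cTP_like", "mTP_like", "SP_like", "AMP_like", "two_taxon_demo")) {
  recs <- read_peptides(file.path(ddir, paste0(stem, ".fasta")),
                        file.path(ddir, paste0(stem, ".tsv")))
  is_amp <- all(recs$seq_type == "AMP")
  fl <- filter_dataset(recs, min_len = 10, max_len = if (is_amp) 100 else NULL)
  write_filter_report(fl$report, file.path(out, paste0(stem, "_filter_report.json")))
  write_peptides(fl$records, file.path(out, paste0(stem, ".fasta")),
                 file.path(out, paste0(stem, ".tsv")))
  message(stem, ": ", fl$report$n_input, " -> ", fl$report$n_output,
          " (", fl$report$n_removed_duplicate, " duplicates)")
}
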
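#!/usr/bin/env Rscript

# Generate the four synthetic peptide classes plus the two-taxon comparison
# demo, and write them to disk in the formats the rest of the workflow reads
# (FASTA + TSV metadata). Ground truth goes alongside as JSON so every later
# stage can be checked against what was actually planted.

suppressPackageStartupMessages(library(gappedmotifs))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260926L

sizes <- c("cTP-like" = 1000L, "mTP-like" = 1000L, "SP-like" = 800L,
           "AMP-like" = 1200L, "two-taxon-demo" = 600L)

for (preset in names(sizes)) {
  gen <- generate_peptides(preset_spec(preset, n = sizes[[preset]], seed = seed))
  stem <- file.path(out, gsub("-", "_", preset))
  write_peptides(gen$records, paste0(stem, ".fasta"), paste0(stem, ".tsv"))
  jsonlite::write_json(
    list(preset = preset, n = sizes[[preset]], seed = seed,
         planted_fractions = gen$ground_truth$planted_fractions,
         n_insertions = nrow(gen$ground_truth$insertions),
         intact_rate = mean(gen$ground_truth$insertions$intact)),
    paste0(stem, "_ground_truth.json"), auto_unbox = TRUE, pretty = TRUE,
    dataframe = "rows")
  message(sprintf("%-15s n=%4d  insertions=%5d  intact=%.3f", preset,
                  sizes[[preset]], nrow(gen$ground_truth$insertions),
                  mean(gen$ground_truth$insertions$intact)))
}
message("datasets written under ", out)
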
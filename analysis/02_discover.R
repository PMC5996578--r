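#!/usr/bin/env Rscript
# Stage 2: extract ORFs, run the translated homology screen (query panel =
# the embedded precursor proteins, standing in for known precursors from
# related species), and classify precursor candidates by the four
# criteria. Writes the candidate table and reports recall/precision
# against the ground-truth manifest.

suppressPackageStartupMessages(library(neuropeptidome))

transcripts <- read_transcripts("results/transcriptome.fa")
manifest <- read_manifest("results/manifest.json")

orfs <- find_orfs_set(transcripts, min_len = 60)
cat(sprintf("%d ORFs (>= 60 aa) across %d transcripts\n",
            nrow(orfs), length(transcripts)))

panel_ids <- names(manifest)[vapply(manifest, function(r)
  r$label == "precursor", logical(1))]
# pro-region (signal-stripped) queries: the conserved peptide domains, not
# the low-complexity hydrophobic signal peptides
queries <- setNames(
  vapply(manifest[panel_ids], function(r)
    substr(r$protein, r$signal_length + 1, nchar(r$protein)), ""),
  paste0("known_", vapply(manifest[panel_ids],
                          function(r) r$template, "")))
hits <- search_panel(queries, transcripts)
write.table(hits, "results/homology_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("homology: %d transcripts flagged by the %d-protein panel\n",
            length(unique(hits$transcript_id)), length(queries)))

candidates <- discover_precursors(
  orfs, homology_transcripts = unique(hits$transcript_id))
write.table(candidates, "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ev <- evaluate_against_manifest(candidates, candidates[0, ], manifest)
cat(sprintf("accepted %d candidates: recall %.2f, precision %.2f\n",
            sum(candidates$accepted), ev$recall, ev$precision))
cat(sprintf("evidence: %d both, %d de novo only, %d homology only\n",
            sum(candidates$evidence == "both"),
            sum(candidates$evidence == "de_novo"),
            sum(candidates$evidence == "homology")))
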
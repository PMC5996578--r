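#!/usr/bin/env Rscript
# Stage 1: build the synthetic ganglia transcriptome used by the rest of
# the analysis — 20 precursor genes with characterised molluscan
# architectures plus 200 decoys — and an MS observed-peptide table
# emulating a proteomic run that samples 80% of the true peptides.

suppressPackageStartupMessages(library(neuropeptidome))
dir.create("results", showWarnings = FALSE)

seed <- 1
sim <- generate_transcriptome(templates = default_templates(),
                              n_decoys = 200, noise = 0, seed = seed)
write_transcripts(sim$transcripts, "results/transcriptome.fa")
write_manifest(sim$manifest, "results/manifest.json")

obs <- generate_observed_peptides(sim$manifest, detection_rate = 0.8,
                                  decoy_peptide_rate = 0.05, seed = seed)
write.table(obs, "results/observed_peptides.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_prec <- sum(vapply(sim$manifest, function(r) r$label == "precursor",
                     logical(1)))
cat(sprintf("wrote %d transcripts (%d precursors, %d decoys)\n",
            length(sim$transcripts), n_prec,
            length(sim$transcripts) - n_prec))
cat(sprintf("observed-peptide table: %d rows (detection 0.8, decoys 0.05)\n",
            nrow(obs)))
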
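#!/usr/bin/env Rscript
# Stage 4: filter the observed-peptide table at score > 20 and match it
# against the predicted mature peptides (sequence + modification
# compatibility, 10 ppm precursor-mass gate), then report per-precursor
# confirmation and the confirmation percentage.

suppressPackageStartupMessages(library(neuropeptidome))

observed <- read_observed_peptides("results/observed_peptides.tsv")
peptides <- read.delim("results/mature_peptides.tsv",
                       stringsAsFactors = FALSE)
peptides$modifications <- NULL

filtered <- filter_observations(observed, min_score = 20)
cat(sprintf("score filter (> 20): %d of %d observations retained\n",
            nrow(filtered), nrow(observed)))

report <- match_observations(filtered, peptides, ppm_tol = 10)
write.table(report$per_precursor, "results/confirmation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(report$orphans, "results/orphan_observations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

s <- report$summary
cat(sprintf("confirmed %d of %d precursors (%.2f%%); %d orphan observations\n",
            s$confirmed, s$total, s$percentage, nrow(report$orphans)))
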
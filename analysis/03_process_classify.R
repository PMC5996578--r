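#!/usr/bin/env Rscript
# Stage 3: process accepted precursors into mature peptides (cleavage,
# basic-residue trimming, amidation, pyroglutamate), annotate peptide
# families from the rulebook, and summarise family copy numbers — e.g.
# the 24-copy FMRFamide domain.

suppressPackageStartupMessages(library(neuropeptidome))

candidates <- read.delim("results/candidates.tsv", stringsAsFactors = FALSE)
manifest <- read_manifest("results/manifest.json")

peptides <- process_candidates(candidates)
peptides <- classify_peptides(peptides)
peptides$rendered <- render_peptide(peptides$sequence, peptides$amidated,
                                    peptides$pyroglu)
write.table(peptides, "results/mature_peptides.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ev <- evaluate_against_manifest(candidates, peptides, manifest)
cat(sprintf("released %d mature peptides (%d amidated); %.1f%% of the\n",
            nrow(peptides), sum(peptides$amidated),
            100 * ev$peptide_recovery))
cat("manifest's expected peptides recovered with matching flags\n")

# copy counts for the FMRFamide precursor
rules <- read_family_rules()
tid <- sub("[|].*$", "", peptides$precursor_id)
fm_ids <- names(manifest)[vapply(manifest, function(r)
  identical(r$template, "fmrfamide"), logical(1))]
fm <- peptides[tid %in% fm_ids, ]
cat(sprintf("FMRFamide precursor: %d FMRFamide copies, %d RFamides total\n",
            sum(fm$sequence == "FMRF" & fm$amidated),
            count_family_copies(fm, "rfamide", rules)))

# a C-terminally anchored frequency matrix of all RFamide peptides
rf <- peptides[grepl("(^|;)rfamide(;|$)", peptides$families), ]
m <- frequency_matrix(pad_c_terminal(rf$sequence))
write.table(round(m, 4), "results/rfamide_frequency_matrix.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat(sprintf("RFamide position-frequency matrix: %d peptides, %d columns\n",
            nrow(rf), ncol(m)))
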
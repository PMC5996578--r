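---
title: "Methods: neuropeptide precursor discovery and in silico prohormone processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuropeptide precursor discovery and in silico prohormone processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropeptidome)
```

## The problem

Neuropeptides are short secreted signalling peptides produced from larger
precursor proteins (prepropeptides). A precursor carries an N-terminal
signal peptide, one or more bioactive peptide units separated by basic
cleavage sites recognised by prohormone convertases, and frequently a
C-terminal Gly on each unit that is converted into a C-terminal amide.
Mining a *de novo* transcriptome assembly of molluscan nerve ganglia for
such genes involves a chain of small, well-defined analyses: ORF
extraction, homology search against known precursors, a structural
criteria screen, in silico processing of accepted precursors into mature
peptides, family annotation, confirmation against peptides observed by
LC-MS/MS, and selection-pressure analysis of the resulting gene set. This
package implements that chain as composable functions plus a seeded
synthetic-data generator, so that every stage is testable end to end
without external data or programs.

## Synthetic transcriptomes as the test substrate

`generate_transcriptome()` instantiates a panel of precursor *templates*
(`default_templates()`), each describing one architecture: signal-peptide
length, an ordered list of peptide units with copy numbers and amidation
flags, per-copy basic junctions, and an optional C-terminal tail. The
default panel of 20 follows characterised molluscan precursors: the
FMRFamide gene with an N-terminal FLRFamide-type domain separated from a
24-copy FMRFamide domain by a tetrabasic furin site (RKRR); luqin with a
single amidated peptide directly after the signal and a Cys-bearing tail;
FxRIamide with 17 xSSFxRI-type units; the 39-residue NPF; pyroglutamylated
CCK/SK peptides; the 11-mer GnRH; myomodulin, allatostatin B/C,
conopressin, APGWamide and several plausible fillers (named `syn_*`).

Reverse translation uses a fixed codon per amino acid so nucleotide output
is byte-stable. Two codon choices deviate from "first codon in the table":
Leu is TTA and Ser is TCA, whose reverse complements are stop codons. Any
protein that contains Leu or Ser therefore seeds stops on the reverse
strand, keeping spurious minus-strand ORFs short. Random 5'/3' UTRs flank
the coding region, with the 5' UTR ending in an in-frame stop so the
embedded ORF is exactly the precursor.

Decoys come in three classes so each clause of the accept rule is
stressed in isolation: signal peptide but no cleavage sites; signal peptide and
dibasic sites but no amidation Gly, no Cys pair and no repeats; and
repeated amidated units without a signal peptide. Decoy bodies are drawn
from an alphabet without Cys and Gly, so a decoy can only be accepted
through a genuine criteria failure, not by compositional luck. Because an
off-frame or reverse-strand translation of a random decoy occasionally
satisfies the criteria anyway, the generator verifies each assembled
decoy transcript and redraws the rare offender: a decoy is *defined* as a
transcript carrying no precursor-like ORF. The repeat-bearing decoys use
three copies of a 10-14 residue unit: long and few enough that their
basic junctions cannot chain into extended local alignments with genuine
repeat-domain queries, while still tripping the repeat criterion.

Default scale is 20 precursors and 200 decoys: large enough for stable
recall/precision, and the whole benchmark (generation, ORFs, homology,
discovery, processing) runs in a few seconds on one core. What passing
these tests shows — and does not show — about real data: the generator
emulates precursor *architecture* faithfully but not assembly artefacts,
sequencing error (beyond uniform substitution noise up to 20%), UTR
biology, isoforms, or the compositional diversity of real proteomes, so
benchmark precision is an upper bound on real-data precision.

## ORF extraction

`find_orfs()` scans all six frames. The default `stop_to_stop` dialect
reports every maximal stop-free stretch with leading residues retained
(the behaviour of the classic EMBOSS extractor); `atg_to_stop` starts at
the first Met because genuine precursors begin with one. Coordinates are
0-based half-open on the forward strand and include the terminating stop
codon when present; the reporting boundary (FASTA headers) is 1-based
inclusive. The default minimum of 60 residues sits below the shortest
full-length precursor class (~90 aa) with margin for partials while
suppressing random-sequence ORFs.

## Homology screen

`search_panel()` aligns a panel of known precursor proteins against all
six frame translations with Smith-Waterman local alignment (BLOSUM62, gap
open 11 / extend 1 — protein-BLAST defaults) via
`Biostrings::pairwiseAlignment`, keeping the best hit per
(query, transcript). The acceptance filter is a raw alignment score.
E-value statistics are engine-specific and not reproducible without the
engine, so the default threshold (60) was calibrated once on
shuffled-sequence nulls: the 99.9% quantile of best-hit scores for
shuffled precursor-scale proteins is ≈52, while true self-hits score in
the hundreds (`calibrate_score_threshold()` reproduces this). One known
limitation is inherent to raw scores: periodic repeat-bearing sequences
can align with unrelated repeat-bearing queries at 60-80 because the
shared basic junctions re-phase cheaply under affine gaps — something an
E-value model with low-complexity masking would suppress. Such flags are
rare (a few percent of decoys), carry no de novo support, and are
reported as homology-only/partial rather than accepted. Queries are best
supplied signal-stripped, since signal peptides are low-complexity
hydrophobic stretches that align with each other regardless of homology.

## Precursor criteria

An ORF is accepted when it has (i) a signal peptide AND (ii) basic
cleavage sites in the pro-region AND (iii or iv or repeats): a Gly
immediately N-terminal to a site (amidation substrate), or at least two
downstream Cys, or at least two mutually similar inter-site fragments.

*Signal peptides* (`predict_signal()`): external predictors are separate
unredistributable programs, so the package ships a two-feature heuristic —
the best 8-residue Kyte-Doolittle window within the first 30 residues
must exceed mean hydropathy 2.0 (the h-region), and a cleavage point in
residues 15-40 must carry small residues (A/G/S/C/T) at its −1 and −3
positions, the classical (−3,−1) rule. The leftmost qualifying point
wins. External predictions can be supplied instead via
`discover_precursors(signal_table =)`.

*Cleavage sites* (`find_cleavage_sites()`): maximal K/R runs — length ≥4
tetrabasic (furin-type, reported once), 2-3 dibasic, and single Arg
monobasic only with a supporting basic residue 2, 4 or 6 positions
N-terminal (the −3/−5/−7 rule) *and* a +1 residue that is not Pro or
hydrophobic/aromatic. The +1 restriction is this package's rulebook
choice: without it the bare −3/−5/−7 rule cleaves inside most amidated
bioactive cores, whose C-terminal motifs (…RFamide, …RIamide) are exactly
Arg followed by an aromatic/aliphatic residue. Both context rules are
arguments, so the rulebook can be tightened or relaxed.

*Repeats* (`detect_repeats()`): fragments between consecutive sites are
compared by length-normalised edit-distance identity and single-linkage
clustered at 50% identity; the largest cluster size is the repeat count.

Homology evidence is merged by transcript identity; candidates whose ORF
coordinates overlap >50% deduplicate to the higher score. The additive
score (signal + cleavage + amidation + 0.5·Cys + 0.5·[repeats ≥ 3]) ranks
candidates only and never gates acceptance.

## Prohormone processing

`release_peptides()` removes the signal region, cuts at cleavage sites,
strips a terminal Gly as the amidation substrate when it directly
precedes the cleaved basic site, trims up to four flanking K/R per
terminus (the tetrabasic maximum), discards fragments shorter than 3
residues (the shortest discussed bioactive unit is a tetrapeptide; a
floor of 3 avoids discarding unreported tripeptides), and annotates
N-terminal Gln/Glu as *potential* pyroglutamate — the modification is
variable in MS practice, so it is annotated rather than applied.
By default cleavage uses dibasic and tetrabasic sites; monobasic sites
are annotations unless `cleave_monobasic = TRUE`. This asymmetry is
deliberate: monobasic cleavage is the least reliable prediction and, if
applied blindly, dissects genuine peptides, which is also why published
precursor schematics imply curated rather than exhaustive monobasic
processing. `cleave_segments()` exposes the full segmentation (signal,
fragments, removed Gly, site motifs, trimmed basics); its concatenation
reconstructs the precursor exactly, which the tests assert over thousands
of random proteins. Degenerate input — a pro-region without any cleavable
site — returns the whole pro-region as a single peptide flagged
`uncleaved`.

## Peptide families

`read_family_rules()` loads a declarative rulebook (one rule per line:
family, kind, pattern, amidation flag, priority). Wildcard motifs
(`x` = any residue, bracket classes allowed) anchor at the C-terminus or
span the whole peptide; two structural kinds cover spacing families:
exactly two Cys with six residues between (allatostatin C) and N-/C-
terminal Trp separated by four or five residues (molluscan allatostatin
B — insect spacings of six or seven are rejected). A peptide may match
several families (luqin peptides are also RFamides); all matches are
returned in priority order, and peptides matching no rule are
unclassified rather than guessed. `frequency_matrix()` computes the
per-column residue frequencies a sequence logo draws letter heights from;
multiple alignment is out of scope, so input must be pre-aligned or
anchored with `pad_c_terminal()`.

## MS confirmation

The package does not search spectra: the interface is an observed-peptide
table (sequence, modification tokens, score, optional observed mass), so
any search engine can feed it. Filtering is strictly score > 20, the
conventional significance cut for the upstream engine — the boundary test
at exactly 20 is part of the acceptance suite. A match requires exact
sequence equality (Leu/Ile distinct by default, since database-driven
searches preserve the database residue; `collapse_li` switches this),
modification compatibility (predicted *potential* pyroglutamate matches
observed peptides with or without the modification; amidation must
agree), and, when an observed mass is present, agreement of the computed
monoisotopic mass within 10 ppm. Each observation confirms at most one
precursor position; ties break by precursor id then coordinate. The
fragment-ion tolerance (0.05 Da) is configuration metadata only. The
report's percentage is 100·confirmed/total rounded to two decimals.

## Selection pressure

`ng86_kaks()` implements the Nei-Gojobori counting method in full:
per-codon synonymous-site fractions averaged over both sequences
(mutations to stops count as non-synonymous), pathway-averaged
substitution counts over all orderings of multi-hit codons (pathways
through stop codons excluded unless all are blocked), and the
Jukes-Cantor correction on both proportions. When a proportion reaches
3/4 the correction is undefined; the result keeps the raw proportion and
a `saturated` flag rather than a number. The model is NG86 and is
documented as such — maximum-likelihood codon models with
transition/transversion and codon-frequency corrections are a possible
extension, not silently approximated. Selection classes follow the
thresholds used for neuropeptide gene screens exactly: ratio > 1 strong
positive, 0.5 < ratio ≤ 1 moderate-positive candidate (the 0.5 bound
strict), otherwise purifying; Ks = 0 or saturation gives `undefined`.
Alignment is caller-provided; gap codons are stripped pairwise.

## Orchestration and reproducibility

`run_pipeline()` executes all stages from a configuration list (YAML
round-trip supported) and writes tab-separated stage artifacts plus a
JSON summary; reruns are byte-identical. The numbered scripts under
`analysis/` drive the same functions as a narrative workflow (simulate →
discover → process/classify → confirm → selection) writing under
`results/`. All randomness flows through explicit seeds; library code
saves and restores the caller's RNG state. Problem sizes used throughout
(20 precursors + 200 decoys; 63-gene inventory for the confirmation-rate
experiment; oracle cross-checks at 50-200 random cases each) keep the
full test suite and the acceptance script in the minutes range on a
single core.

## Known limitations

The signal heuristic is far weaker than modern predictors and is tuned to
canonical architectures; real partial transcripts and non-canonical
signals will be missed (the pluggable prediction table is the escape
hatch). The homology stage has no E-value model or masking, with the
repeat-flag behaviour described above. Monobasic processing is
annotate-only by default. Family rules operate on single sequences;
assignments that require cross-species alignment context stay
unclassified. NG86 ignores transition/transversion bias and codon
frequencies and will differ from ML estimates, particularly at high
divergence.
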
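# neuropeptidome

Discovery and characterisation of neuropeptide precursor genes in
transcriptome assemblies of molluscan nerve ganglia.

Neuropeptide precursors (prepropeptides) share a recognisable
architecture: an N-terminal signal peptide, one or more bioactive peptide
units flanked by mono-/di-/tetrabasic prohormone-convertase cleavage
sites, a C-terminal Gly on amidated units, and often disulfide-forming
cysteines. This package implements the full analysis chain used to mine
such genes from a ganglia transcriptome and characterise their products:

- **ORF extraction** — six-frame translation and getorf-style
  stop-to-stop / ATG-to-stop scanning (`find_orfs`).
- **Homology screen** — translated Smith–Waterman search of a panel of
  known precursor proteins against the assembly (BLOSUM62, affine gaps,
  raw-score threshold calibrated on shuffled nulls; `search_panel`).
- **De novo criteria screen** — signal-peptide heuristic
  (Kyte–Doolittle h-region + the (−3,−1) small-residue rule), basic
  cleavage-site grammar, repeated-peptide detection, and the accept rule
  *signal AND cleavage AND (amidation-Gly OR repeats OR Cys pair)*
  (`discover_precursors`).
- **In silico prohormone processing** — cleavage, basic-residue
  trimming, amidation (terminal Gly substrate), potential N-terminal
  pyroglutamate, disulfide candidates (`release_peptides`).
- **Peptide families** — a declarative rulebook (C-terminal motifs such
  as RFamide/WRPQGRFamide/xxxMLRLamide, Cys- and Trp-spacing rules) plus
  position-frequency matrices for logo-style summaries
  (`classify_peptide`, `frequency_matrix`).
- **MS confirmation** — modification-aware matching of an
  observed-peptide table (Mascot-style score > 20 filter, 10 ppm
  monoisotopic-mass gate) against predictions (`match_observations`).
- **Selection pressure** — Nei–Gojobori (NG86) Ka/Ks with Jukes–Cantor
  correction and the selection classes Ka/Ks > 1 (strong positive),
  0.5 < Ka/Ks ≤ 1 (moderate-positive candidate), ≤ 0.5 (purifying)
  (`ng86_kaks`).
- **Synthetic data** — a seeded generator embedding precursor genes with
  realistic architectures (e.g. a 24-copy FMRFamide domain behind a
  tetrabasic RKRR furin site) plus stratified decoys, with a
  ground-truth manifest (`generate_transcriptome`).

## Worked example

```r
library(neuropeptidome)

# a luqin-type pro-region: peptide, amidation Gly, dibasic site
release_peptides("APQWRPQGRFGKR", signal_end = 0)
#>   precursor_id start end   sequence amidated pyroglu copy_index uncleaved
#> 1    precursor     0  10 APQWRPQGRF     TRUE    none          1     FALSE

classify_peptide("APQWRPQGRF", amidated = TRUE)
#> [1] "luqin"   "rfamide"

ng86_kaks("TTTAAAGGG", "TTCAAAGGG")
#> NG86 Ka/Ks [pair]
#>   Ka = 0  (Nd = 0.00 over N = 7.33 sites)
#>   Ks = 1.207  (Sd = 1.00 over S = 1.67 sites)
#>   Ka/Ks = 0 -> purifying
```

The `analysis/` directory holds the end-to-end workflow over a synthetic
benchmark (20 precursor genes, 200 decoys, fixed seed):

```sh
Rscript analysis/01_simulate.R         # transcriptome + manifest + MS table
Rscript analysis/02_discover.R         # ORFs, homology, criteria screen
Rscript analysis/03_process_classify.R # mature peptides + families
Rscript analysis/04_confirm.R          # MS confirmation report
Rscript analysis/05_selection.R        # Ka/Ks over emulated ortholog pairs
```

which prints, among others:

```
accepted 20 candidates: recall 1.00, precision 1.00
released 116 mature peptides (95 amidated); 100.0% of the
manifest's expected peptides recovered with matching flags
FMRFamide precursor: 24 FMRFamide copies, 27 RFamides total
score filter (> 20): 103 of 107 observations retained
confirmed 19 of 20 precursors (95.00%); 6 orphan observations
```

with tables under `results/`.

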
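# The default synthetic benchmark (20 precursor templates, 200 decoys,
# noise 0, fixed seed), generated once per test run and shared.

.benchmark_cache <- new.env()

default_benchmark <- function() {
  if (!exists("result", envir = .benchmark_cache)) {
    sim <- generate_transcriptome(templates = default_templates(),
                                  n_decoys = 200, noise = 0, seed = 20260929)
    orfs <- find_orfs_set(sim$transcripts)
    cand <- discover_precursors(orfs)
    pep <- process_candidates(cand)
    assign("result",
           list(sim = sim, orfs = orfs, candidates = cand, peptides = pep),
           envir = .benchmark_cache)
  }
  get("result", envir = .benchmark_cache)
}

# released peptides of one benchmark precursor template
benchmark_peptides_for <- function(bm, template_name) {
  ids <- names(bm$sim$manifest)[vapply(bm$sim$manifest, function(r)
    identical(r$template, template_name), logical(1))]
  tid <- sub("[|].*$", "", bm$peptides$precursor_id)
  bm$peptides[tid %in% ids, , drop = FALSE]
}
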
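# Seeded synthetic transcriptomes: precursor genes with realistic
# architectures (signal peptide, basic cleavage sites, repeated amidated
# units, Cys patterns) plus decoy transcripts, with a ground-truth manifest
# so every downstream stage is testable without external data.

SIGNAL_CORE_ALPHABET <- c("L", "V", "I", "F")
# decoy bodies exclude C and G so the Cys-pair and amidation-Gly criteria
# are exercised by the precursors only
DECOY_ALPHABET <- c("A", "D", "E", "F", "H", "I", "L", "M", "N", "P",
                    "Q", "S", "T", "V", "W", "Y")

#' Construct a precursor template
#'
#' A template describes one precursor architecture: an N-terminal signal
#' peptide, an ordered series of peptide units (each emitted `copies`
#' times, with a trailing Gly when amidated, each copy followed by its
#' junction's basic cleavage motif), and an optional C-terminal extension
#' (e.g. a Cys-bearing tail).
#'
#' @param name template label.
#' @param signal_length signal-peptide length in residues (>= 10; the
#'   built-in signal heuristic can only place cleavage points at >= 15).
#' @param units list of `list(core =, copies =, amidated =, junction =)`;
#'   junction is the basic motif emitted after every copy ("KR", "RR",
#'   "KK", "RK" dibasic; a 4-mer of K/R tetrabasic; "R" monobasic).
#' @param cterm_extension optional tail after the final junction.
#' @return object of class `precursor_template`.
#' @export
precursor_template <- function(name, signal_length, units,
                               cterm_extension = NULL) {
  check(signal_length >= 10, "signal_length must be >= 10")
  if (signal_length < 15) {
    warning("signal_length < 15 is outside the default signal heuristic's ",
            "cleavage search window", call. = FALSE)
  }
  for (u in units) {
    check(all(c("core", "copies", "amidated") %in% names(u)),
          "each unit needs core, copies, amidated")
    check(u$copies >= 1, "copy counts must be >= 1")
    check(!grepl("[KR]{2}", u$core), paste("unit core", u$core,
          "contains adjacent basic residues"))
    check(!substr(u$core, 1, 1) %in% c("K", "R"),
          "unit core must not start with a basic residue")
    if (!isTRUE(u$amidated)) {
      check(substr(u$core, nchar(u$core), nchar(u$core)) != "G",
            paste("non-amidated core", u$core,
                  "ends in Gly (would be read as an amidation substrate)"))
    }
    j <- if (is.null(u$junction)) "KR" else u$junction
    check(grepl("^[KR]+$", j) && nchar(j) %in% c(1, 2, 4),
          "junction must be a 1/2/4-mer of K and R")
  }
  if (!is.null(cterm_extension)) {
    check(!grepl("[KR]{2}", cterm_extension),
          "extension contains adjacent basic residues")
    check(!substr(cterm_extension, nchar(cterm_extension),
                  nchar(cterm_extension)) %in% c("G", "K", "R"),
          "extension must not end in G/K/R")
  }
  structure(list(name = name, signal_length = signal_length, units = units,
                 cterm_extension = cterm_extension),
            class = "precursor_template")
}

# deterministic-given-RNG signal peptide: Met-Lys, hydrophobic h-region,
# Ala-X-Ala cleavage context
build_signal <- function(n) {
  core <- paste(sample(SIGNAL_CORE_ALPHABET, n - 5, replace = TRUE),
                collapse = "")
  paste0("MK", core, "ALA")
}

#' Assemble the protein and expected peptides of a template
#'
#' @param template a [precursor_template()].
#' @param signal the signal-peptide sequence (length
#'   `template$signal_length`); generated randomly when NULL.
#' @return list with `protein`, `signal_length` and `expected_peptides`
#'   (data.frame `sequence`, `amidated`, `pyroglu`).
#' @export
template_protein <- function(template, signal = NULL) {
  if (is.null(signal)) signal <- build_signal(template$signal_length)
  check(nchar(signal) == template$signal_length,
        "signal length mismatch")
  parts <- signal
  exp_seq <- character(0); exp_amid <- logical(0)
  for (u in template$units) {
    j <- if (is.null(u$junction)) "KR" else u$junction
    for (k in seq_len(u$copies)) {
      parts <- c(parts, u$core, if (isTRUE(u$amidated)) "G", j)
      exp_seq <- c(exp_seq, u$core)
      exp_amid <- c(exp_amid, isTRUE(u$amidated))
    }
  }
  if (!is.null(template$cterm_extension)) {
    parts <- c(parts, template$cterm_extension)
    exp_seq <- c(exp_seq, template$cterm_extension)
    exp_amid <- c(exp_amid, FALSE)
  }
  first <- substr(exp_seq, 1, 1)
  expected <- data.frame(
    sequence = exp_seq, amidated = exp_amid,
    pyroglu = ifelse(first == "Q", "fromQ",
                     ifelse(first == "E", "fromE", "none")),
    stringsAsFactors = FALSE)
  list(protein = paste(parts, collapse = ""),
       signal_length = template$signal_length,
       expected_peptides = expected)
}

unit <- function(core, copies = 1, amidated = TRUE, junction = "KR") {
  list(core = core, copies = copies, amidated = amidated,
       junction = junction)
}

#' Default panel of 20 precursor templates
#'
#' Architectures follow the characterised molluscan precursors: the
#' FMRFamide gene with its two domains split by a tetrabasic furin site
#' (RKRR) and 24 FMRFamide copies, luqin with a single amidated peptide
#' right after the signal and a Cys-bearing tail, FxRIamide with 17
#' xSSFxRI-like units, the 39-residue NPF, pyroglutamylated CCK/SK
#' peptides, the 11-mer GnRH, myomodulin xxxMLRLamide copies, allatostatin
#' B (W-x5-W) and C (C-x6-C), conopressin, APGWamide, and several
#' synthetic-but-plausible fillers (marked `syn_`).
#'
#' @return named list of [precursor_template()] objects.
#' @export
default_templates <- function() {
  t <- list(
    precursor_template("fmrfamide", 22, list(
      unit("TFLRF"), unit("ALSGDAFFRF"), unit("FLRF", junction = "RKRR"),
      unit("FMRF", copies = 24))),
    precursor_template("luqin", 23, list(unit("APQWRPQGRF")),
      cterm_extension = "SSEECQISPNSWCMLDEQNSMDESALNSE"),
    precursor_template("fxriamide", 16, list(
      unit("MSSFMRI", copies = 7), unit("LSSFMRI", copies = 6),
      unit("GLSSFVRI"), unit("IPTSSFMRI"), unit("ASSFNRI"),
      unit("TSSFLRI"))),
    precursor_template("syn_fcap", 20, list(
      unit("NFDEIDRSSFA", copies = 5))),
    precursor_template("npf", 22, list(
      unit("QEAMLEPPDRPHSFRTPDQLRSYLRALNEYYSIVGRPRF"))),
    precursor_template("cck_sk", 21, list(
      unit("QGRWDLDYGLGGGRF"), unit("EYDDYRLGGGRF")),
      cterm_extension = "ADPSSFNELSQE"),
    precursor_template("gnrh", 24, list(unit("QNFHYSNGWQP")),
      cterm_extension = "DSLAESLIDNTPEAFNDQSRVSELA"),
    precursor_template("myomodulin", 19, list(
      unit("GMNMLRL", copies = 3), unit("GGLSMLRL", copies = 2),
      unit("PMSMLRL", copies = 2))),
    precursor_template("allatostatin_b", 25, list(
      unit("GWKDMGTW", copies = 3), unit("AWKSLGSW", copies = 2),
      unit("SWADMGSW", copies = 2), unit("TWSNLGQW", copies = 2),
      unit("AWSDFSHW"))),
    precursor_template("allatostatin_c", 28, list(
      unit("GHIQCLVNLVACY")),
      cterm_extension = "SDLENAPQFSELMDNSIRES"),
    precursor_template("conopressin", 21, list(unit("CFIRNCPPG")),
      cterm_extension = "NPDLSAQNELFDSTMRSLENPQASIDEMSA"),
    precursor_template("allatotropin", 20, list(
      unit("GFRQGIVMRIGHGF")),
      cterm_extension = "SDMENQLLSTFDESNRALENSDQTA"),
    precursor_template("apgwamide", 22, list(
      unit("APGW", copies = 6), unit("TPGW", copies = 4))),
    precursor_template("syn_elh", 25, list(
      unit("SLDSELNQRLMDSINNLQESNLASNVSDFASQTQFDEAA", amidated = FALSE),
      unit("NQDSLMNSELRSAFDETQLA", amidated = FALSE)),
      cterm_extension = "SDQCNELSFAMCDESNQLA"),
    precursor_template("syn_pedal_peptide", 20, list(
      unit("PADSLDSFVGSA", copies = 4, amidated = FALSE))),
    precursor_template("syn_buccalin", 20, list(
      unit("DSFNAGAL", copies = 3), unit("NSDMAGGL", copies = 2))),
    precursor_template("lfrfamide", 21, list(
      unit("GSLFRF", copies = 3), unit("SLFRF", copies = 2))),
    precursor_template("achatin_like", 19, list(
      unit("GFWD", copies = 3, amidated = FALSE),
      unit("GYGD", copies = 2, amidated = FALSE)),
      cterm_extension = "SDLENQAFMDSITE"),
    precursor_template("ggnamide", 22, list(
      unit("GKCRGRWSIHACLGGN")),
      cterm_extension = "SDQNELAFMDSLTNEQSAFNDMSE"),
    precursor_template("syn_insulin_like", 24, list(
      unit("SSSCNALDTLCQVSELNEACASSLCDMQNSAEFNSA", amidated = FALSE)))
  )
  setNames(t, vapply(t, function(x) x$name, ""))
}

#' Generate an inventory of distinct single-peptide precursor templates
#'
#' Builds `n` precursor templates that each carry one distinct amidated
#' peptide unit and a distinct pro-region tail (drawn from a
#' Gly/Cys/basic-free alphabet so the units stay cleanly classifiable).
#' Useful for emulating a genome-scale precursor inventory, e.g. in
#' confirmation-rate experiments where every precursor must be separable
#' by its peptide sequence.
#'
#' @param n number of templates.
#' @param seed integer RNG seed.
#' @return named list of [precursor_template()] objects.
#' @export
random_inventory_templates <- function(n, seed) {
  check(!missing(seed), "seed must be provided")
  with_seed(seed, {
    seen <- character(0)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        core <- paste(sample(DECOY_ALPHABET, sample(8:12, 1),
                             replace = TRUE), collapse = "")
        if (!core %in% seen) break
      }
      seen <- c(seen, core)
      # long enough that even the shortest signal + single-copy unit clears
      # the default 60-residue ORF floor
      ext <- paste(sample(DECOY_ALPHABET, 36, replace = TRUE),
                   collapse = "")
      out[[i]] <- precursor_template(
        sprintf("inv%03d", i), sample(18:28, 1),
        list(unit(core, copies = sample(1:3, 1))),
        cterm_extension = ext)
    }
    setNames(out, vapply(out, function(t) t$name, ""))
  })
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

apply_noise <- function(nt, noise) {
  if (noise <= 0) return(nt)
  ch <- chars(nt)
  hit <- runif(length(ch)) < noise
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      "")
  }
  paste(ch, collapse = "")
}

build_decoy_protein <- function(class) {
  body_len <- sample(60:110, 1)
  body <- paste(sample(DECOY_ALPHABET, body_len, replace = TRUE),
                collapse = "")
  if (class == "sig_nocleave") {
    paste0(build_signal(sample(18:24, 1)), body)
  } else if (class == "sig_featureless") {
    # two dibasic sites but no amidation Gly, no Cys, no repeats
    p1 <- sample(10:30, 1)
    p2 <- p1 + sample(15:25, 1)
    b <- paste0(substr(body, 1, p1), "KR",
                substr(body, p1 + 1, p2), "KR",
                substr(body, p2 + 1, body_len))
    paste0(build_signal(sample(18:24, 1)), b)
  } else {  # repeat_nosig: repeated amidated units without a signal peptide
    # units longer than neuropeptide-scale repeats and only three copies:
    # enough to trip the repeat criterion, while the shared basic junctions
    # cannot chain into extended local alignments with genuine
    # repeat-domain queries
    core <- paste(sample(DECOY_ALPHABET, sample(10:14, 1),
                         replace = TRUE), collapse = "")
    prefix <- paste(sample(c("D", "E", "N", "Q", "S", "T"), 12,
                           replace = TRUE), collapse = "")
    paste0(prefix, strrep(paste0(core, "GKR"), 3),
           substr(body, 1, 45))
  }
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Each template is instantiated (random signal core, fixed-codon reverse
#' translation, random UTRs with an in-frame stop terminating the 5' UTR),
#' decoys of three classes are added (signal-bearing without cleavage
#' sites, signal-bearing with featureless cleavage sites, repeat-bearing
#' without a signal), optional per-nucleotide substitution noise is
#' applied, and a manifest records the embedded ORF and expected mature
#' peptides per transcript. Identical seeds give byte-identical output.
#'
#' @param templates named list of [precursor_template()] objects.
#' @param n_decoys number of decoy transcripts.
#' @param noise per-nucleotide substitution probability in [0, 0.2].
#' @param seed integer RNG seed (required).
#' @return list with `transcripts` (named character vector) and `manifest`
#'   (list of per-transcript records; class `ground_truth_manifest`).
#' @export
generate_transcriptome <- function(templates = default_templates(),
                                   n_decoys = 200, noise = 0, seed) {
  check(!missing(seed), "seed must be provided")
  check(is.numeric(noise) && noise >= 0 && noise <= 0.2,
        "noise must be in [0, 0.2]")
  check(length(templates) > 0, "templates must be non-empty")
  with_seed(seed, {
    seqs <- character(0)
    manifest <- list()
    i <- 0L
    assemble <- function(protein) {
      cds <- reverse_translate(protein, stop = TRUE)
      utr5_len <- sample(10:30, 1) * 3L
      utr5 <- random_nt(utr5_len)
      substr(utr5, utr5_len - 2L, utr5_len) <- "TAA"
      utr3 <- random_nt(sample(30:90, 1))
      list(nt = paste0(utr5, cds, utr3), orf_start = utr5_len,
           orf_end = utr5_len + nchar(cds))  # stop codon included
    }
    emit <- function(asm, record) {
      i <<- i + 1L
      id <- sprintf("PY_T%04d", i)
      seqs[[id]] <<- apply_noise(asm$nt, noise)
      record$id <- id
      record$orf_start <- asm$orf_start
      record$orf_end <- asm$orf_end
      record$strand <- "+"
      manifest[[id]] <<- record
    }
    # does any ORF of the assembled transcript look like a precursor?
    has_precursor_like_orf <- function(nt) {
      orfs_probe <- find_orfs(nt, min_len = 60)
      for (k in seq_len(nrow(orfs_probe))) {
        p <- orfs_probe$protein[k]
        sig <- if (nchar(p) >= 30) predict_signal(p)
        else list(has_signal = FALSE, cleavage_after = NA, score = NA)
        st <- find_cleavage_sites(p)
        rp <- detect_repeats(p, st)
        if (classify_candidate(p, sig, st, rp)$accepted) return(TRUE)
      }
      FALSE
    }
    for (tm in templates) {
      tp <- template_protein(tm)
      emit(assemble(tp$protein), list(
        label = "precursor", template = tm$name, protein = tp$protein,
        signal_length = tp$signal_length,
        expected_peptides = tp$expected_peptides))
    }
    decoy_classes <- rep(c("sig_nocleave", "sig_featureless",
                           "repeat_nosig"), length.out = n_decoys)
    for (cl in decoy_classes) {
      # a decoy is by definition a transcript carrying no precursor-like
      # ORF on either strand; redraw the rare candidate whose off-frame or
      # reverse-strand translation happens to satisfy the criteria, so
      # ground-truth labels stay well-defined
      for (try in 1:20) {
        prot <- build_decoy_protein(cl)
        asm <- assemble(prot)
        if (!has_precursor_like_orf(asm$nt)) break
      }
      emit(asm, list(
        label = "decoy", template = cl, protein = prot,
        signal_length = NA_integer_,
        expected_peptides = data.frame(sequence = character(),
                                       amidated = logical(),
                                       pyroglu = character(),
                                       stringsAsFactors = FALSE)))
    }
    structure(list(transcripts = unlist(seqs), manifest =
                     structure(manifest, class = "ground_truth_manifest")),
              class = "synthetic_transcriptome")
  })
}

#' Emulate an MS observed-peptide table from a manifest
#'
#' Each expected mature peptide is emitted with probability
#' `detection_rate`, carrying its amidation token, optionally its
#' pyroglutamate token (each pyroGlu-capable peptide is observed in
#' cyclised form half the time), a significance score above 20 and its
#' computed monoisotopic mass. Decoy peptides (random sequences absent from
#' the manifest) are added at `decoy_peptide_rate` per true peptide with
#' scores straddling the score-20 threshold.
#'
#' @param manifest `ground_truth_manifest` from [generate_transcriptome()].
#' @param detection_rate per-peptide detection probability.
#' @param decoy_peptide_rate expected decoy fraction (per true peptide).
#' @param seed integer RNG seed.
#' @return data.frame: `peptide`, `modifications` (semicolon-joined),
#'   `score`, `observed_mass`.
#' @export
generate_observed_peptides <- function(manifest, detection_rate = 0.8,
                                       decoy_peptide_rate = 0.05, seed) {
  check(!missing(seed), "seed must be provided")
  check(detection_rate >= 0 && detection_rate <= 1 &&
          decoy_peptide_rate >= 0 && decoy_peptide_rate <= 1,
        "rates must be in [0, 1]")
  empty <- data.frame(peptide = character(), modifications = character(),
                      score = numeric(), observed_mass = numeric(),
                      stringsAsFactors = FALSE)
  pools <- lapply(manifest, function(r) r$expected_peptides)
  pool <- do.call(rbind, pools)
  if (is.null(pool) || nrow(pool) == 0) return(empty)
  with_seed(seed, {
    rows <- list()
    for (k in seq_len(nrow(pool))) {
      if (runif(1) >= detection_rate) next
      mods <- character(0)
      if (pool$amidated[k]) mods <- c(mods, "amidated")
      if (pool$pyroglu[k] == "fromQ" && runif(1) < 0.5)
        mods <- c(mods, "pyroglu_Q")
      if (pool$pyroglu[k] == "fromE" && runif(1) < 0.5)
        mods <- c(mods, "pyroglu_E")
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pool$sequence[k],
        modifications = paste(mods, collapse = ";"),
        score = round(runif(1, 25, 120), 2),
        observed_mass = round(monoisotopic_mass(pool$sequence[k], mods), 5),
        stringsAsFactors = FALSE)
    }
    n_decoy <- rbinom(1, nrow(pool), decoy_peptide_rate)
    for (k in seq_len(n_decoy)) {
      seq_d <- paste(sample(AA20, sample(6:15, 1), replace = TRUE),
                     collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = seq_d, modifications = "",
        score = round(runif(1, 5, 35), 2),
        observed_mass = round(monoisotopic_mass(seq_d), 5),
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write / read the ground-truth manifest as JSON
#'
#' @param manifest `ground_truth_manifest`.
#' @param path JSON file path.
#' @return `path` (write) or the manifest (read).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  manifest <- lapply(raw, function(r) {
    ep <- do.call(rbind, lapply(r$expected_peptides, function(p) {
      data.frame(sequence = p$sequence, amidated = p$amidated,
                 pyroglu = p$pyroglu, stringsAsFactors = FALSE)
    }))
    if (is.null(ep)) {
      ep <- data.frame(sequence = character(), amidated = logical(),
                       pyroglu = character(), stringsAsFactors = FALSE)
    }
    r$expected_peptides <- ep
    r
  })
  structure(manifest, class = "ground_truth_manifest")
}

#' Benchmark pipeline output against the manifest
#'
#' @param candidates data.frame from [discover_precursors()].
#' @param peptides data.frame from [process_candidates()].
#' @param manifest `ground_truth_manifest`.
#' @return list with `recall`, `precision` (transcript level over accepted
#'   candidates) and `peptide_recovery` (fraction of expected mature
#'   peptides recovered with matching amidation and pyroGlu flags).
#' @export
evaluate_against_manifest <- function(candidates, peptides, manifest) {
  truth <- names(manifest)[vapply(manifest,
                                  function(r) r$label == "precursor",
                                  logical(1))]
  pred <- unique(candidates$transcript_id[candidates$accepted])
  tp <- length(intersect(pred, truth))
  recall <- if (length(truth) > 0) tp / length(truth) else NA_real_
  precision <- if (length(pred) > 0) tp / length(pred) else NA_real_
  pep_tid <- sub("\\|.*$", "", peptides$precursor_id)
  n_exp <- 0L; n_rec <- 0L
  for (id in truth) {
    exp <- manifest[[id]]$expected_peptides
    got <- peptides[pep_tid == id, , drop = FALSE]
    gkey <- paste(got$sequence, got$amidated, got$pyroglu)
    gtab <- table(gkey)
    ekey <- paste(exp$sequence, exp$amidated, exp$pyroglu)
    etab <- table(ekey)
    n_exp <- n_exp + nrow(exp)
    for (k in names(etab)) {
      n_rec <- n_rec + min(etab[[k]],
                           if (k %in% names(gtab)) gtab[[k]] else 0L)
    }
  }
  list(recall = recall, precision = precision,
       peptide_recovery = if (n_exp > 0) n_rec / n_exp else NA_real_)
}
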
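# Modification-aware matching of MS-derived peptide observations against
# predicted mature peptides, with the score and precursor-mass filters used
# in database searches of neuropeptidomes.

# Monoisotopic residue masses (Da).
AA_MONOISOTOPIC <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565

# Variable-modification mass deltas (Da). Controlled vocabulary used in
# observed-peptide tables.
MOD_DELTAS <- c(
  amidated = -0.98402,       # C-terminal amide
  pyroglu_Q = -17.02655,     # Gln -> pyro-Glu (N-term Q)
  pyroglu_E = -18.01056,     # Glu -> pyro-Glu (N-term E)
  oxidation_M = 15.99491,    # Met oxidation
  dioxidation_M = 31.98983,  # Met dioxidation
  acetyl_Nterm = 42.01057    # N-terminal acetyl
)

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of residue monoisotopic masses plus water, adjusted per modification
#' token ([MOD_DELTAS] vocabulary; repeated tokens are applied repeatedly).
#'
#' @param sequence peptide over the 20 standard residues.
#' @param modifications character vector of modification tokens.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(sequence, modifications = character()) {
  aa <- chars(sequence)
  known <- aa %in% names(AA_MONOISOTOPIC)
  if (!all(known)) {
    stop("unknown residue '", aa[!known][1], "' at position ",
         which(!known)[1], call. = FALSE)
  }
  bad <- setdiff(modifications, names(MOD_DELTAS))
  check(length(bad) == 0,
        paste("unknown modification token:", paste(bad, collapse = ",")))
  sum(AA_MONOISOTOPIC[aa]) + MASS_WATER +
    sum(MOD_DELTAS[modifications])
}

parse_mod_tokens <- function(x) {
  if (is.na(x) || x == "") character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

validate_observation <- function(sequence, mods) {
  first <- substr(sequence, 1, 1)
  if ("pyroglu_Q" %in% mods && first != "Q")
    stop("pyroglu_Q requires N-terminal Q: ", sequence, call. = FALSE)
  if ("pyroglu_E" %in% mods && first != "E")
    stop("pyroglu_E requires N-terminal E: ", sequence, call. = FALSE)
  if (any(c("oxidation_M", "dioxidation_M") %in% mods) &&
      !grepl("M", sequence, fixed = TRUE))
    stop("Met oxidation requires a Met: ", sequence, call. = FALSE)
  invisible(TRUE)
}

#' Read an observed-peptide table
#'
#' Tab-separated with header: `peptide`, `modifications` (semicolon-joined
#' tokens from the [MOD_DELTAS] vocabulary), `score`, optional
#' `observed_mass`. Modification consistency (pyroGlu needs N-terminal Q/E,
#' oxidation needs Met) is validated on ingest.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_observed_peptides <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check(all(c("peptide", "modifications", "score") %in% names(df)),
        "observed table must have peptide, modifications, score columns")
  if (!"observed_mass" %in% names(df)) df$observed_mass <- NA_real_
  df$modifications[is.na(df$modifications)] <- ""
  for (i in seq_len(nrow(df))) {
    validate_observation(df$peptide[i], parse_mod_tokens(df$modifications[i]))
  }
  df
}

#' Filter observations by search-engine score
#'
#' Strictly-greater-than filter: an observation at exactly the threshold is
#' excluded.
#'
#' @param observations data.frame with a numeric `score` column.
#' @param min_score threshold (default 20, the usual Mascot significance
#'   cut).
#' @return filtered data.frame.
#' @export
filter_observations <- function(observations, min_score = 20) {
  check(is.numeric(observations$score), "scores must be numeric")
  out <- observations[observations$score > min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

mods_compatible <- function(obs_mods, pred_amidated, pred_pyroglu) {
  if (("amidated" %in% obs_mods) != isTRUE(pred_amidated)) return(FALSE)
  # predicted pyroglutamate is potential: observed may carry it or not,
  # but an observed pyroGlu must agree with the predicted potential
  if ("pyroglu_Q" %in% obs_mods && pred_pyroglu != "fromQ") return(FALSE)
  if ("pyroglu_E" %in% obs_mods && pred_pyroglu != "fromE") return(FALSE)
  TRUE
}

#' Match observed peptides to predictions and report confirmation
#'
#' A match requires exact sequence equality (Leu/Ile distinct unless
#' `collapse_li`), modification-set compatibility, and, when an observed
#' mass is present, agreement of the computed monoisotopic mass within
#' `ppm_tol`. Each observation confirms at most one precursor position;
#' ties are broken by precursor id then coordinate. The fragment-ion
#' tolerance of the upstream search is metadata only (no fragment matching
#' happens here).
#'
#' @param observations filtered data.frame
#'   (peptide / modifications / score / observed_mass).
#' @param predicted data.frame of mature peptides ([release_peptides()]
#'   columns `precursor_id`, `start`, `sequence`, `amidated`, `pyroglu`).
#' @param ppm_tol precursor-mass tolerance in parts per million.
#' @param collapse_li treat Leu and Ile as identical?
#' @return list with `matches`, `orphans`, `per_precursor` and `summary`
#'   (`confirmed`, `total`, `percentage` = 100 * confirmed / total, 2 dp).
#' @export
match_observations <- function(observations, predicted, ppm_tol = 10,
                               collapse_li = FALSE) {
  canon <- function(x) if (collapse_li) gsub("I", "L", x, fixed = TRUE) else x
  pred <- predicted[order(predicted$precursor_id, predicted$start), ,
                    drop = FALSE]
  pred_key <- canon(pred$sequence)
  matches <- list()
  orphan_idx <- integer(0)
  for (i in seq_len(nrow(observations))) {
    obs_seq <- observations$peptide[i]
    mods <- parse_mod_tokens(observations$modifications[i])
    cand <- which(pred_key == canon(obs_seq))
    cand <- cand[vapply(cand, function(j) {
      mods_compatible(mods, pred$amidated[j], pred$pyroglu[j])
    }, logical(1))]
    om <- observations$observed_mass[i]
    if (length(cand) > 0 && !is.na(om)) {
      calc <- monoisotopic_mass(obs_seq, mods)
      if (abs(calc - om) / calc * 1e6 > ppm_tol) cand <- integer(0)
    }
    if (length(cand) == 0) {
      orphan_idx <- c(orphan_idx, i)
    } else {
      j <- cand[1]  # pred is sorted by (precursor_id, start)
      matches[[length(matches) + 1L]] <- data.frame(
        observation = i, peptide = obs_seq,
        modifications = observations$modifications[i],
        score = observations$score[i],
        precursor_id = pred$precursor_id[j], start = pred$start[j],
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(matches) == 0) {
    data.frame(observation = integer(), peptide = character(),
               modifications = character(), score = numeric(),
               precursor_id = character(), start = integer(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, matches)
  precursors <- unique(pred$precursor_id)
  per <- data.frame(
    precursor_id = precursors,
    n_matched = vapply(precursors,
                       function(p) sum(matches$precursor_id == p), 0L),
    stringsAsFactors = FALSE)
  per$confirmed <- per$n_matched >= 1
  confirmed <- sum(per$confirmed)
  total <- length(precursors)
  list(
    matches = matches,
    orphans = observations[orphan_idx, , drop = FALSE],
    per_precursor = per,
    summary = list(
      confirmed = confirmed, total = total,
      percentage = if (total > 0) round(100 * confirmed / total, 2) else NA_real_)
  )
}
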
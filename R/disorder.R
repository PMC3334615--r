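#' Read per-residue score tracks from TSV
#'
#' Score tracks carry one value in \[0, 1\] per residue of a protein (for
#' example disorder propensities or binding propensities from an external
#' predictor). The file format is three tab-separated columns: `protein_id`,
#' `position` (1-based), `score`.
#'
#' @param path Path to the TSV file.
#' @return A named list of numeric vectors, one per protein, scores ordered by
#'   position.
#' @export
read_score_tracks <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    score = readr::col_double()))
  validate_scores(tbl$score)
  if (any(tbl$position < 1)) stop("positions must be 1-based (>= 1)")
  tracks <- split(tbl[c("position", "score")], tbl$protein_id)
  lapply(tracks, function(t) {
    if (anyDuplicated(t$position) || !setequal(t$position, seq_len(nrow(t)))) {
      stop("positions of a track must be exactly 1..length")
    }
    t$score[order(t$position)]
  })
}

#' Write score tracks to TSV
#' @param tracks Named list of numeric score vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_tracks <- function(tracks, path) {
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  tbl <- dplyr::bind_rows(lapply(names(tracks), function(id) {
    tibble::tibble(protein_id = id,
                   position = seq_along(tracks[[id]]),
                   score = tracks[[id]])
  }))
  readr::write_tsv(tbl, path)
  invisible(path)
}

validate_scores <- function(scores) {
  if (length(scores) == 0) stop("empty score track")
  if (anyNA(scores)) stop("NA scores are not allowed")
  if (any(scores < 0 | scores > 1)) {
    bad <- which(scores < 0 | scores > 1)[1]
    stop("score out of [0, 1] at position ", bad, ": ", scores[bad])
  }
  invisible(TRUE)
}

#' Per-residue disorder flags
#'
#' A residue is classified as locally disordered when its score is strictly
#' above the threshold; residues exactly at the threshold are ordered.
#'
#' @param scores Numeric vector of per-residue scores in \[0, 1\].
#' @param threshold Classification threshold (default 0.5).
#' @return Logical vector, `TRUE` for disordered residues.
#' @export
residue_disorder_flags <- function(scores, threshold = 0.5) {
  validate_scores(scores)
  scores > threshold
}

#' Percent disordered residues of one protein
#'
#' @inheritParams residue_disorder_flags
#' @return Percentage in \[0, 100\].
#' @examples
#' protein_disorder_percent(c(0.6, 0.6, 0.4, 0.5))  # 50
#' @export
protein_disorder_percent <- function(scores, threshold = 0.5) {
  100 * mean(residue_disorder_flags(scores, threshold))
}

#' Mean disorder of a proteome
#'
#' The proteome-level disorder is the unweighted mean over proteins of their
#' per-protein disorder percentages: a short fully disordered protein counts
#' as much as a long ordered one. A residue-weighted variant (total disordered
#' residues over total residues) is available as a diagnostic via
#' `weighting = "residue"`; it is not the headline statistic.
#'
#' @param tracks Named list of score vectors (one per protein).
#' @param threshold Classification threshold (default 0.5).
#' @param weighting `"protein"` (default) or `"residue"`.
#' @return Percentage in \[0, 100\].
#' @export
proteome_mean_disorder <- function(tracks, threshold = 0.5,
                                   weighting = c("protein", "residue")) {
  weighting <- match.arg(weighting)
  if (length(tracks) == 0) stop("no score tracks supplied")
  if (weighting == "protein") {
    mean(vapply(tracks, protein_disorder_percent, numeric(1),
                threshold = threshold))
  } else {
    flags <- unlist(lapply(tracks, residue_disorder_flags,
                           threshold = threshold), use.names = FALSE)
    100 * mean(flags)
  }
}

#' Per-protein disorder table
#' @param tracks Named list of score vectors.
#' @param threshold Classification threshold.
#' @return Tibble with `protein_id`, `length`, `disorder_percent`.
#' @export
disorder_table <- function(tracks, threshold = 0.5) {
  tibble::tibble(
    protein_id = names(tracks),
    length = lengths(tracks),
    disorder_percent = vapply(tracks, protein_disorder_percent, numeric(1),
                              threshold = threshold))
}

# Composition propensity scale in [0, 1]: the TOP-IDP discriminative scale of
# Campen et al. (2008), linearly rescaled from its native range so order-
# promoting residues (W, F, Y, I) sit near 0 and disorder-promoting residues
# (E, P) near 1. Ambiguity codes are uninformative and sit at 0.5.
TOP_IDP_RAW <- c(
  W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397, L = -0.326,
  V = -0.121, N =  0.007, C =  0.020, T =  0.059, A =  0.060, G =  0.166,
  R =  0.180, D =  0.192, H =  0.303, Q =  0.318, S =  0.341, K =  0.586,
  E =  0.736, P =  0.987)
DISORDER_PROPENSITY <- {
  p <- (TOP_IDP_RAW - min(TOP_IDP_RAW)) / diff(range(TOP_IDP_RAW))
  c(p, setNames(rep(0.5, length(AA_AMBIGUOUS)), AA_AMBIGUOUS))
}

#' Baseline composition scorer
#'
#' A deterministic stand-in scorer so the pipeline can run end to end when no
#' external per-residue predictions are provided. Each residue gets a fixed
#' disorder propensity in \[0, 1\] (a rescaled composition scale; ambiguity
#' codes score 0.5), smoothed by a centred sliding-window mean with truncated
#' edge windows. It makes no claim to predictive accuracy and is never used as
#' a test oracle.
#'
#' @param sequence Amino-acid string (20 standard letters plus X, B, Z, U, O,
#'   J).
#' @param window Odd window width for smoothing (default 21).
#' @return Numeric score vector, one value per residue, all in \[0, 1\].
#' @export
baseline_disorder_scorer <- function(sequence, window = 21) {
  stopifnot(length(sequence) == 1, window >= 1, window %% 2 == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0) stop("empty sequence")
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  }
  raw <- unname(DISORDER_PROPENSITY[chars])
  n <- length(raw)
  half <- (window - 1L) / 2L
  cs <- cumsum(c(0, raw))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Score a whole proteome with the baseline scorer
#' @param isoforms Isoform table with `protein_id` and `sequence` columns.
#' @param window Odd smoothing window.
#' @return Named list of score vectors.
#' @export
baseline_score_proteome <- function(isoforms, window = 21) {
  stopifnot("sequence" %in% names(isoforms))
  setNames(lapply(isoforms$sequence, baseline_disorder_scorer,
                  window = window),
           isoforms$protein_id)
}
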
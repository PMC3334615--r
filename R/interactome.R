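#' Read a STRING-style binary interaction table
#'
#' Expects columns `protein1`, `protein2`, `combined_score` (tab- or
#' space-delimited, as in STRING `protein.links` dumps). Pairs are
#' canonicalized to undirected form: self-interactions are dropped (with a
#' logged count), and exact or reversed duplicates collapse to a single row
#' keeping the maximum confidence.
#'
#' @param path Path to the table.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab versus
#'   whitespace from the header line.
#' @return Tibble with `protein_a`, `protein_b` (protein_a < protein_b),
#'   `confidence` (integer 0-1000).
#' @export
read_interactions <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else " "
  }
  tbl <- readr::read_delim(path, delim = delim, trim_ws = TRUE,
                           col_types = readr::cols(
                             protein1 = readr::col_character(),
                             protein2 = readr::col_character(),
                             combined_score = readr::col_character()))
  score <- suppressWarnings(as.numeric(tbl$combined_score))
  if (anyNA(score)) {
    stop("non-numeric combined_score at data row ", which(is.na(score))[1])
  }
  canonicalize_interactions(tibble::tibble(
    protein_a = tbl$protein1, protein_b = tbl$protein2,
    confidence = as.integer(score)))
}

canonicalize_interactions <- function(tbl) {
  if (any(tbl$confidence < 0 | tbl$confidence > 1000)) {
    stop("confidence scores must lie in [0, 1000]")
  }
  self <- tbl$protein_a == tbl$protein_b
  if (any(self)) {
    message("dropped ", sum(self), " self-interaction(s)")
    tbl <- tbl[!self, ]
  }
  a <- pmin(tbl$protein_a, tbl$protein_b)
  b <- pmax(tbl$protein_a, tbl$protein_b)
  tibble::tibble(protein_a = a, protein_b = b,
                 confidence = tbl$confidence) |>
    dplyr::summarise(confidence = max(.data$confidence),
                     .by = c("protein_a", "protein_b"))
}

#' Write interactions in STRING-style format
#'
#' Emits the `protein1`, `protein2`, `combined_score` schema that
#' [read_interactions()] reads, so generated interactomes round-trip through
#' the same validator path as real downloads.
#'
#' @param interactions Canonical interaction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  readr::write_tsv(tibble::tibble(protein1 = interactions$protein_a,
                                  protein2 = interactions$protein_b,
                                  combined_score = interactions$confidence),
                   path)
  invisible(path)
}

#' Filter interactions by confidence score
#'
#' Keeps interactions with `confidence >= min_score` (inclusive, so the
#' conventional high-confidence cut of 900 keeps a score of exactly 900).
#'
#' @param interactions Canonical interaction tibble.
#' @param min_score Minimum combined score (default 900).
#' @return Filtered tibble.
#' @export
filter_confidence <- function(interactions, min_score = 900) {
  dplyr::filter(interactions, .data$confidence >= min_score)
}

#' Restrict interactions to a tissue's expressed proteins
#'
#' An interaction counts for a tissue only when both partners are annotated
#' as expressed there.
#'
#' @param interactions Canonical interaction tibble.
#' @param expressed Character vector of expressed protein ids.
#' @return Filtered tibble.
#' @export
restrict_to_tissue <- function(interactions, expressed) {
  dplyr::filter(interactions,
                .data$protein_a %in% expressed &
                  .data$protein_b %in% expressed)
}

#' Interactome degree statistics over a reference proteome
#'
#' `interactions_per_protein` divides the number of undirected interactions
#' by the full proteome size, so proteins with no recorded interaction dilute
#' the ratio; each such protein also appears in the degree table with degree
#' 0.
#'
#' @param interactions Canonical interaction tibble.
#' @param proteome_ids Character vector of all protein ids in the reference
#'   proteome (non-empty).
#' @return List of class `interactome_summary`: `total_interactions`,
#'   `interactions_per_protein`, `degrees` (tibble `protein_id`, `degree`
#'   covering every proteome protein).
#' @export
degree_stats <- function(interactions, proteome_ids) {
  if (length(proteome_ids) == 0) stop("empty proteome_ids")
  proteome_ids <- unique(proteome_ids)
  endpoints <- c(interactions$protein_a, interactions$protein_b)
  outside <- setdiff(endpoints, proteome_ids)
  if (length(outside) > 0) {
    warning(length(outside),
            " interaction endpoint(s) absent from the reference proteome")
  }
  deg <- table(factor(endpoints, levels = proteome_ids))
  out <- list(total_interactions = nrow(interactions),
              interactions_per_protein =
                nrow(interactions) / length(proteome_ids),
              degrees = tibble::tibble(protein_id = proteome_ids,
                                       degree = as.integer(deg)))
  class(out) <- "interactome_summary"
  out
}

#' @export
print.interactome_summary <- function(x, ...) {
  cat("<interactome_summary> total:", x$total_interactions,
      " per-protein:", signif(x$interactions_per_protein, 4),
      " proteins:", nrow(x$degrees), "\n")
  invisible(x)
}
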
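#' Classify SCOP superfamilies by expansion correlation
#'
#' A superfamily's "expansion" is the Pearson correlation, taken from prior
#' comparative work, between its domain abundance across species and
#' organismal complexity. Superfamilies with R >= `hi` are "expanding",
#' with R <= `lo` "non-expanding", anything between is "neither". Both
#' boundaries are inclusive, as printed.
#'
#' @param expansion Tibble/data frame with columns `superfamily_id` and
#'   `expansion_r` (values in \[-1, 1\]).
#' @param hi Expanding cut-off (default 0.8).
#' @param lo Non-expanding cut-off (default 0.2).
#' @return The input with an added `class` column
#'   (`"expanding"`/`"non_expanding"`/`"neither"`).
#' @export
classify_superfamilies <- function(expansion, hi = 0.8, lo = 0.2) {
  stopifnot(all(c("superfamily_id", "expansion_r") %in% names(expansion)))
  r <- expansion$expansion_r
  if (any(r < -1 | r > 1, na.rm = TRUE) || anyNA(r)) {
    stop("expansion_r must lie in [-1, 1] with no missing values")
  }
  dplyr::mutate(tibble::as_tibble(expansion),
                class = dplyr::case_when(
                  .data$expansion_r >= hi ~ "expanding",
                  .data$expansion_r <= lo ~ "non_expanding",
                  TRUE ~ "neither"))
}

#' Read a BLAST-tabular domain-hit table
#'
#' Expects outfmt-6-like columns where the query is a SCOP domain sequence and
#' the subject is a proteome protein: `domain_id`, `protein_id`,
#' `percent_identity` as the first three columns (extra columns ignored), plus
#' a separate two-column map from domain to superfamily.
#'
#' @param path Hit-table TSV (no header, BLAST outfmt 6 order: qseqid sseqid
#'   pident ...).
#' @param domain_map Tibble with columns `domain_id`, `superfamily_id`, or a
#'   path to such a TSV (with header).
#' @return Tibble with `protein_id`, `domain_id`, `superfamily_id`,
#'   `percent_identity`.
#' @export
read_domain_hits <- function(path, domain_map) {
  hits <- readr::read_tsv(path, col_names = FALSE,
                          col_types = readr::cols(.default = readr::col_guess()))
  if (ncol(hits) < 3) stop("hit table needs at least 3 columns")
  hits <- tibble::tibble(domain_id = as.character(hits[[1]]),
                         protein_id = as.character(hits[[2]]),
                         percent_identity = as.numeric(hits[[3]]))
  if (any(is.na(hits$percent_identity)) ||
      any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("percent_identity must be numeric in [0, 100]")
  }
  if (is.character(domain_map)) {
    domain_map <- readr::read_tsv(domain_map, col_types = "cc")
  }
  stopifnot(all(c("domain_id", "superfamily_id") %in% names(domain_map)))
  dplyr::left_join(hits, tibble::as_tibble(domain_map), by = "domain_id") |>
    dplyr::select("protein_id", "domain_id", "superfamily_id",
                  "percent_identity")
}

#' Partition proteins by SCOP-domain expansion class
#'
#' A protein enters `any_domain` when it has at least one hit with sequence
#' identity strictly above `min_identity`; it enters `expanding`
#' (respectively `non_expanding`) when such a hit's superfamily carries that
#' class. Membership is non-exclusive: a protein hitting both classes appears
#' in both sets (and once in `any_domain`).
#'
#' @param hits Tibble with `protein_id`, `superfamily_id`,
#'   `percent_identity` (see [read_domain_hits()]).
#' @param classes Classified superfamily table from
#'   [classify_superfamilies()].
#' @param min_identity Identity cut-off, strict (default 50: a 50.0% hit does
#'   not qualify).
#' @return List of class `protein_partition` with character-vector members
#'   `expanding`, `non_expanding`, `any_domain`.
#' @export
partition_proteins <- function(hits, classes, min_identity = 50) {
  stopifnot(all(c("protein_id", "superfamily_id", "percent_identity")
                %in% names(hits)))
  qual <- dplyr::filter(tibble::as_tibble(hits),
                        .data$percent_identity > min_identity)
  cls <- setNames(classes$class, classes$superfamily_id)
  hit_class <- unname(cls[qual$superfamily_id])
  unknown <- is.na(hit_class)
  if (any(unknown)) {
    warning(sum(unknown), " hit(s) reference unknown superfamilies; ",
            "treated as class 'neither'")
    hit_class[unknown] <- "neither"
  }
  out <- list(
    expanding = sort(unique(qual$protein_id[hit_class == "expanding"])),
    non_expanding = sort(unique(qual$protein_id[hit_class == "non_expanding"])),
    any_domain = sort(unique(qual$protein_id)))
  class(out) <- "protein_partition"
  out
}

#' @export
print.protein_partition <- function(x, ...) {
  cat("<protein_partition> expanding:", length(x$expanding),
      " non-expanding:", length(x$non_expanding),
      " any-domain:", length(x$any_domain), "\n")
  invisible(x)
}

#' Compare disorder between expansion classes
#'
#' Computes the mean per-protein disorder percentage of each partition group
#' and a two-tailed Mann-Whitney test of expanding versus non-expanding.
#' Groups with no scored proteins are reported as missing and excluded from
#' the test.
#'
#' @param partition A [partition_proteins()] result.
#' @param tracks Named list of disorder score tracks.
#' @param threshold Disorder threshold (default 0.5).
#' @return List with `group_summary` (tibble: group, n, mean_disorder) and
#'   `test` (Mann-Whitney result, or NULL when a group is empty).
#' @export
compare_group_disorder <- function(partition, tracks, threshold = 0.5) {
  group_vals <- lapply(partition[c("expanding", "non_expanding",
                                   "any_domain")], function(ids) {
    ids <- intersect(ids, names(tracks))
    vapply(tracks[ids], protein_disorder_percent, numeric(1),
           threshold = threshold)
  })
  summary <- tibble::tibble(
    group = names(group_vals),
    n = lengths(group_vals),
    mean_disorder = vapply(group_vals, function(v) {
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1)))
  test <- NULL
  if (length(group_vals$expanding) > 0 && length(group_vals$non_expanding) > 0) {
    test <- mann_whitney(group_vals$expanding, group_vals$non_expanding)
  }
  list(group_summary = summary, test = test)
}
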
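#' Tissue complexity from a cell-type table
#'
#' A tissue's complexity is the number of distinct cell types composing it.
#' Names are case-normalized and trimmed before deduplication.
#'
#' @param cell_type_table Tibble/data frame with columns `tissue`,
#'   `cell_type`.
#' @return Tibble with `tissue`, `complexity` (distinct cell-type count).
#' @export
tissue_complexity <- function(cell_type_table) {
  stopifnot(all(c("tissue", "cell_type") %in% names(cell_type_table)))
  ct <- trimws(tolower(cell_type_table$cell_type))
  if (any(is.na(ct) | !nzchar(ct))) {
    stop("empty cell-type name for tissue ",
         cell_type_table$tissue[is.na(ct) | !nzchar(ct)][1])
  }
  tibble::tibble(tissue = cell_type_table$tissue, cell_type = ct) |>
    dplyr::distinct() |>
    dplyr::count(.data$tissue, name = "complexity")
}

#' Summarize one tissue's proteins
#'
#' Computes, over a tissue's protein set: the median per-protein disorder
#' percentage, the median number of interaction partners within the
#' tissue-restricted graph (proteins with no partner count as degree 0), the
#' total number of intra-tissue interactions, the total number of predicted
#' binding sites, and the alternatively spliced fraction. Proteins without a
#' score track are excluded from the medians with a logged warning.
#' Interactions should already be confidence-filtered (e.g. with
#' [filter_confidence()]).
#'
#' @param proteins Character vector of the tissue's protein ids.
#' @param tracks Named list of disorder score tracks (shared across tissues).
#' @param interactions Canonical interaction tibble, pre-filtered by
#'   confidence.
#' @param binding_tracks Named list of binding-propensity tracks used for
#'   site segmentation; defaults to `tracks` when the same predictor serves
#'   both purposes.
#' @param as_flags Optional named logical AS map (see
#'   [tissue_as_fraction()]); `NULL` omits the AS fraction.
#' @param alt_tracks Optional named list of score tracks for the
#'   alternative-isoform complement of the same tissue; when supplied,
#'   `median_disorder_alt` is computed from it.
#' @param threshold,min_run,min_sep Binding-site/disorder parameters.
#' @return One-row tibble: `n_proteins`, `median_disorder_percent`,
#'   `median_partners`, `total_ppis`, `total_binding_sites`, `as_fraction`,
#'   `median_disorder_alt`.
#' @export
summarize_tissue <- function(proteins, tracks, interactions,
                             as_flags = NULL, alt_tracks = NULL,
                             binding_tracks = tracks,
                             threshold = 0.5, min_run = 3, min_sep = 3) {
  stopifnot(length(proteins) >= 1)
  proteins <- unique(proteins)
  have_track <- proteins %in% names(tracks)
  if (!all(have_track)) {
    warning(sum(!have_track),
            " tissue protein(s) without a score track; excluded from medians")
  }
  scored <- tracks[proteins[have_track]]
  disorder <- vapply(scored, protein_disorder_percent, numeric(1),
                     threshold = threshold)
  tissue_ints <- restrict_to_tissue(interactions, proteins)
  deg <- degree_stats(tissue_ints, proteins)
  btracks <- binding_tracks[intersect(proteins, names(binding_tracks))]
  sites <- if (length(btracks) > 0) {
    summarize_binding_sites(btracks, threshold, min_run, min_sep)$total_sites
  } else 0L
  tibble::tibble(
    n_proteins = length(proteins),
    median_disorder_percent =
      if (length(disorder) > 0) median(disorder) else NA_real_,
    median_partners = median(deg$degrees$degree),
    total_ppis = deg$total_interactions,
    total_binding_sites = as.integer(sites),
    as_fraction = if (is.null(as_flags)) NA_real_ else
      tissue_as_fraction(proteins, as_flags),
    median_disorder_alt = if (is.null(alt_tracks)) NA_real_ else {
      alt <- alt_tracks[intersect(proteins, names(alt_tracks))]
      if (length(alt) == 0) NA_real_ else
        median(vapply(alt, protein_disorder_percent, numeric(1),
                      threshold = threshold))
    })
}

#' Summarize a panel of tissues
#'
#' @param tissues Tibble with columns `tissue`, `complexity`.
#' @param annotation Tibble mapping `protein_id` to `tissue` (one row per
#'   pair).
#' @inheritParams summarize_tissue
#' @param min_proteins Tissues with fewer proteins are excluded with a logged
#'   reason (default 2).
#' @return Tibble: one row per retained tissue with `tissue`, `complexity`
#'   and the [summarize_tissue()] columns.
#' @export
summarize_tissue_panel <- function(tissues, annotation, tracks, interactions,
                                   as_flags = NULL, alt_tracks = NULL,
                                   binding_tracks = tracks,
                                   threshold = 0.5, min_run = 3, min_sep = 3,
                                   min_proteins = 2) {
  stopifnot(all(c("tissue", "complexity") %in% names(tissues)),
            all(c("protein_id", "tissue") %in% names(annotation)))
  rows <- lapply(seq_len(nrow(tissues)), function(i) {
    tt <- tissues$tissue[i]
    prot <- annotation$protein_id[annotation$tissue == tt]
    if (length(prot) < min_proteins) {
      message("tissue '", tt, "' excluded: only ", length(prot),
              " annotated protein(s)")
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(tissue = tt, complexity = tissues$complexity[i]),
      summarize_tissue(prot, tracks, interactions, as_flags, alt_tracks,
                       binding_tracks, threshold, min_run, min_sep))
  })
  dplyr::bind_rows(rows)
}

#' Correlate tissue metrics with complexity and fit the sites-PPI scaling
#'
#' Runs, across tissues: Spearman correlations of complexity against each
#' summary metric; power-law fits of the binding-site and PPI totals against
#' complexity; and the scaling between the two totals themselves, reported in
#' both orientations (PPIs as a function of sites and sites as a function of
#' PPIs) because the two regressions answer different questions and their
#' exponents are not reciprocal under noise.
#'
#' @param summaries Tibble from [summarize_tissue_panel()] (needs
#'   `complexity` plus the metric columns); at least 4 tissues.
#' @return List with `correlations` (tibble: metric, r, p, n, note) and
#'   `fits` (named list of [fit_power_law()] results:
#'   `ppis_vs_sites`, `sites_vs_ppis`, `sites_vs_complexity`,
#'   `ppis_vs_complexity`).
#' @export
correlate_tissue_metrics <- function(summaries) {
  if (nrow(summaries) < 4) stop("need at least 4 tissues")
  metrics <- c("median_disorder_percent", "median_partners", "total_ppis",
               "total_binding_sites", "as_fraction", "median_disorder_alt")
  metrics <- intersect(metrics, names(summaries))
  cors <- lapply(metrics, function(m) {
    v <- summaries[[m]]
    keep <- !is.na(v)
    if (sum(keep) < 3 || length(unique(v[keep])) == 1 ||
        length(unique(summaries$complexity[keep])) == 1) {
      message("correlation skipped for constant/short metric '", m, "'")
      return(tibble::tibble(metric = m, r = NA_real_, p = NA_real_,
                            n = sum(keep), note = "skipped"))
    }
    ct <- cor_spearman(summaries$complexity[keep], v[keep])
    tibble::tibble(metric = m, r = ct$r, p = ct$p_two_tailed, n = ct$n,
                   note = ct$note %||% "")
  })
  fit_or_null <- function(x, y) {
    keep <- !is.na(x) & !is.na(y) & x > 0 & y > 0
    if (sum(keep) < 3) return(NULL)
    fit_power_law(x[keep], y[keep])
  }
  list(correlations = dplyr::bind_rows(cors),
       fits = list(
         ppis_vs_sites = fit_or_null(summaries$total_binding_sites,
                                     summaries$total_ppis),
         sites_vs_ppis = fit_or_null(summaries$total_ppis,
                                     summaries$total_binding_sites),
         sites_vs_complexity = fit_or_null(summaries$complexity,
                                           summaries$total_binding_sites),
         ppis_vs_complexity = fit_or_null(summaries$complexity,
                                          summaries$total_ppis)))
}
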
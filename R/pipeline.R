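#' Default pipeline configuration
#'
#' All thresholds default to the conventional printed cut-offs: disorder and
#' binding threshold 0.5, minimum site run 3, minimum separator run 3,
#' domain identity 50 (strict), interaction confidence 900 (inclusive),
#' superfamily expansion boundaries 0.8 / 0.2 (inclusive). Every value can
#' be overridden; the configuration in force is echoed into every report.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(disorder_threshold = 0.5, min_run = 3, min_sep = 3,
              min_identity = 50, min_confidence = 900,
              expansion_hi = 0.8, expansion_lo = 0.2,
              exclude_plants = TRUE, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

#' Generate a complete synthetic dataset directory
#'
#' Writes, under `out_dir`, everything the analysis stages read: a species
#' table with per-species FASTA files, score tracks and splicing tables and
#' interaction tables, a tissue panel (tissue table, protein annotation,
#' disorder and binding tracks, interactions, AS flags), a ground-truth JSON
#' and a config echo. Identical seeds produce identical directories.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_species,n_bacteria,n_plants Species panel composition (defaults
#'   12 eukaryotes + 4 bacteria + 2 plants: a desk-scale panel).
#' @param n_tissues Tissue panel size (default 12).
#' @param config [pipeline_config()] list.
#' @param ... Passed on to [simulate_species_panel()] /
#'   [simulate_tissue_panel()] (e.g. `k_true`, `prefactor_true`).
#' @param seed Integer seed (mandatory; sub-seeds for each generator derive
#'   from it).
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, n_species = 12, n_bacteria = 4,
                         n_plants = 2, n_tissues = 12,
                         config = pipeline_config(), seed, ...) {
  stopifnot(!missing(seed))
  dots <- list(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp_args <- c(list(n_species = n_species, n_bacteria = n_bacteria,
                    n_plants = n_plants, sequences = TRUE,
                    dir = file.path(out_dir, "fasta"), seed = seed),
               dots[intersect(names(dots),
                              names(formals(simulate_species_panel)))])
  panel <- do.call(simulate_species_panel, sp_args)
  species <- panel$species
  readr::write_tsv(species[c("species_id", "clade", "complexity")],
                   file.path(out_dir, "species.tsv"))

  dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "splicing"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "interactions"), showWarnings = FALSE)
  for (i in seq_len(nrow(species))) {
    sid <- species$species_id[i]
    iso <- panel$isoforms[[sid]]
    main <- iso[iso$is_main, ]
    lens <- setNames(main$length, main$protein_id)
    tr <- simulate_score_tracks(lens, species$disorder_target[i],
                                seed = seed + 1000L + i)
    write_score_tracks(tr$tracks, file.path(out_dir, "tracks",
                                            paste0(sid, ".tsv")))
    spl <- simulate_splicing_table(
      n_genes = gene_count(iso),
      as_event_rate = 0.1 + 0.9 * species$disorder_target[i],
      seed = seed + 2000L + i)
    readr::write_tsv(spl$genes, file.path(out_dir, "splicing",
                                          paste0(sid, ".tsv")))
    net <- simulate_interactome(main$protein_id, mean_degree = 4,
                                seed = seed + 3000L + i)
    write_interactions(net$interactions,
                       file.path(out_dir, "interactions",
                                 paste0(sid, ".tsv")))
  }

  ts_args <- c(list(n_tissues = n_tissues, seed = seed + 9000L),
               dots[intersect(names(dots),
                              names(formals(simulate_tissue_panel)))])
  tp <- do.call(simulate_tissue_panel, ts_args)
  tdir <- file.path(out_dir, "tissue")
  dir.create(tdir, showWarnings = FALSE)
  readr::write_tsv(tp$tissues, file.path(tdir, "tissues.tsv"))
  readr::write_tsv(tp$annotation, file.path(tdir, "annotation.tsv"))
  write_score_tracks(tp$tracks, file.path(tdir, "tracks.tsv"))
  write_score_tracks(tp$binding_tracks, file.path(tdir,
                                                  "binding_tracks.tsv"))
  write_interactions(tp$interactions, file.path(tdir, "interactions.tsv"))
  readr::write_tsv(tibble::tibble(protein_id = names(tp$as_flags),
                                  has_alt_isoform = unname(tp$as_flags)),
                   file.path(tdir, "as_flags.tsv"))

  truth <- list(species = species, tissue = tp$truth,
                species_config = panel$config, tissue_config = tp$config)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(config, seed = seed),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  message("synthetic dataset written to ", out_dir)
  invisible(out_dir)
}

#' Species-level analysis report
#'
#' Reads a dataset directory (layout of [run_simulate()]; real data can
#' replace any piece in the same formats), computes per-species metrics
#' (gene count, PIC in both complements, mean disorder, binding-site
#' statistics, interaction statistics, splicing summaries), and runs the
#' statistical layer three ways where clade structure permits: all species,
#' eukaryotes only, and eukaryotes excluding plants, plus a clade ANOVA on
#' PIC (plants excluded) when at least two clades have n >= 2.
#'
#' @param dir Dataset directory.
#' @param config [pipeline_config()] list.
#' @return List of class `species_report`: `metrics` (per-species tibble),
#'   `stats` (nested list of fits/correlations/ANOVA), `config`. Also
#'   writes `species_metrics.tsv` and `species_statistics.json` under
#'   `dir/reports/`.
#' @export
run_species_analysis <- function(dir, config = pipeline_config()) {
  species <- readr::read_tsv(file.path(dir, "species.tsv"),
                             col_types = "cci")
  bad_clade <- setdiff(unique(species$clade), CLADES)
  if (length(bad_clade) > 0) {
    stop("unknown clade(s): ", paste(bad_clade, collapse = ", "))
  }
  keep <- !is.na(species$complexity)
  if (!all(keep)) {
    message("excluded ", sum(!keep), " species without complexity")
    species <- species[keep, ]
  }
  rows <- lapply(seq_len(nrow(species)), function(i) {
    sid <- species$species_id[i]
    iso <- group_isoforms(read_proteome_fasta(
      file.path(dir, "fasta", paste0(sid, ".fa"))))
    tracks <- read_score_tracks(file.path(dir, "tracks",
                                          paste0(sid, ".tsv")))
    bs <- summarize_binding_sites(tracks, config$disorder_threshold,
                                  config$min_run, config$min_sep)
    spl_path <- file.path(dir, "splicing", paste0(sid, ".tsv"))
    int_path <- file.path(dir, "interactions", paste0(sid, ".tsv"))
    ints <- if (file.exists(int_path)) {
      filter_confidence(read_interactions(int_path), config$min_confidence)
    } else NULL
    deg <- if (!is.null(ints)) degree_stats(ints, iso$protein_id[iso$is_main])
    spl <- if (file.exists(spl_path)) read_splicing_table(spl_path)
    tibble::tibble(
      species_id = sid, clade = species$clade[i],
      complexity = species$complexity[i],
      n_genes = gene_count(iso),
      pic_main = compute_pic(iso, "main"),
      pic_all = compute_pic(iso, "all"),
      mean_disorder = proteome_mean_disorder(tracks,
                                             config$disorder_threshold),
      mean_sites_per_protein = bs$mean_sites_per_protein,
      total_sites = bs$total_sites,
      percent_binding_residues = bs$percent_binding_residues,
      total_ppis = if (is.null(deg)) NA_integer_ else
        deg$total_interactions,
      ppis_per_protein = if (is.null(deg)) NA_real_ else
        deg$interactions_per_protein,
      percent_multiexon_as = if (is.null(spl)) NA_real_ else
        percent_multiexon_as(spl),
      mean_as_events = if (is.null(spl)) NA_real_ else
        mean_as_events_per_gene(spl))
  })
  metrics <- dplyr::bind_rows(rows)
  stats <- species_statistics(metrics, config)
  rep_dir <- file.path(dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  readr::write_tsv(metrics, file.path(rep_dir, "species_metrics.tsv"))
  jsonlite::write_json(
    c(list(config = config), serialize_stats(stats)),
    file.path(rep_dir, "species_statistics.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  out <- list(metrics = metrics, stats = stats, config = config)
  class(out) <- "species_report"
  out
}

species_statistics <- function(metrics, config) {
  subsets <- list(all_species = metrics,
                  eukaryotes = metrics[metrics$clade != "bacteria", ],
                  eukaryotes_no_plants =
                    metrics[!metrics$clade %in% c("bacteria", "plants"), ])
  # degenerate inputs (constant metric, too few species) yield NULL entries
  # rather than aborting the whole report
  safe <- function(fn, x, y) {
    tryCatch(fn(x, y), error = function(e) {
      message("statistic skipped: ", conditionMessage(e))
      NULL
    })
  }
  per_subset <- lapply(subsets, function(m) {
    if (nrow(m) < 3 || length(unique(m$complexity)) < 2) return(NULL)
    res <- list(
      fit_pic_main = safe(fit_power_law, m$complexity, m$pic_main),
      pearson_log_pic_main = safe(cor_pearson, log10(m$complexity),
                                  log10(m$pic_main)),
      spearman_disorder = safe(cor_spearman, m$complexity, m$mean_disorder),
      spearman_mean_sites = safe(cor_spearman, m$complexity,
                                 m$mean_sites_per_protein),
      spearman_total_sites = safe(cor_spearman, m$complexity,
                                  m$total_sites))
    if (!anyNA(m$pic_all)) {
      res$fit_pic_all <- safe(fit_power_law, m$complexity, m$pic_all)
    }
    if (!anyNA(m$percent_multiexon_as)) {
      res$spearman_percent_multiexon_as <-
        safe(cor_spearman, m$complexity, m$percent_multiexon_as)
      res$spearman_mean_as_events <-
        safe(cor_spearman, m$complexity, m$mean_as_events)
    }
    res
  })
  anova_m <- metrics[metrics$clade != "plants", ]
  sizes <- table(anova_m$clade)
  per_subset$clade_anova_pic <- if (sum(sizes >= 2) >= 2) {
    ok <- anova_m$clade %in% names(sizes)[sizes >= 2]
    one_way_anova_bonferroni(anova_m$pic_main[ok], anova_m$clade[ok])
  } else {
    message("clade ANOVA skipped: fewer than two clades with n >= 2")
    NULL
  }
  per_subset
}

# flatten S3 stat objects for JSON
serialize_stats <- function(x) {
  if (inherits(x, c("power_fit", "correlation_result", "anova_result",
                    "subsample_sd"))) {
    return(lapply(unclass(x), function(v) {
      if (is.null(v)) NULL else v
    }))
  }
  if (is.list(x)) return(lapply(x, serialize_stats))
  x
}

#' @export
print.species_report <- function(x, ...) {
  cat("<species_report>", nrow(x$metrics), "species\n")
  f <- x$stats$eukaryotes_no_plants$fit_pic_main %||%
    x$stats$all_species$fit_pic_main
  if (!is.null(f)) {
    cat("  PIC ~ complexity (eukaryotes minus plants): ")
    print(f)
  }
  invisible(x)
}

#' Tissue-level analysis report
#'
#' Reads the tissue tables of a dataset directory, filters interactions to
#' high confidence, summarizes each tissue ([summarize_tissue_panel()]) and
#' runs the complexity correlations and the sites-interactions scaling fits
#' ([correlate_tissue_metrics()]). A missing AS-flag file degrades
#' gracefully: the `as_fraction` column is reported as missing and the rest
#' is computed.
#'
#' @param dir Dataset directory (uses `dir/tissue/`).
#' @param config [pipeline_config()] list.
#' @return List of class `tissue_report`: `summaries`, `stats`, `config`.
#'   Also writes `tissue_summary.tsv` and `tissue_statistics.json` under
#'   `dir/reports/`.
#' @export
run_tissue_analysis <- function(dir, config = pipeline_config()) {
  tdir <- file.path(dir, "tissue")
  tissues <- readr::read_tsv(file.path(tdir, "tissues.tsv"),
                             col_types = "ci")
  annotation <- readr::read_tsv(file.path(tdir, "annotation.tsv"),
                                col_types = "cc")
  tracks <- read_score_tracks(file.path(tdir, "tracks.tsv"))
  bt_path <- file.path(tdir, "binding_tracks.tsv")
  binding_tracks <- if (file.exists(bt_path)) read_score_tracks(bt_path)
    else tracks
  interactions <- filter_confidence(
    read_interactions(file.path(tdir, "interactions.tsv")),
    config$min_confidence)
  as_path <- file.path(tdir, "as_flags.tsv")
  as_flags <- if (file.exists(as_path)) {
    tbl <- readr::read_tsv(as_path, col_types = "cl")
    setNames(tbl$has_alt_isoform, tbl$protein_id)
  } else {
    message("no AS flags file; as_fraction omitted")
    NULL
  }
  summaries <- summarize_tissue_panel(
    tissues, annotation, tracks, interactions, as_flags,
    binding_tracks = binding_tracks,
    threshold = config$disorder_threshold,
    min_run = config$min_run, min_sep = config$min_sep)
  stats <- correlate_tissue_metrics(summaries)
  rep_dir <- file.path(dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  readr::write_tsv(summaries, file.path(rep_dir, "tissue_summary.tsv"))
  jsonlite::write_json(
    list(config = config,
         correlations = stats$correlations,
         fits = serialize_stats(stats$fits)),
    file.path(rep_dir, "tissue_statistics.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  out <- list(summaries = summaries, stats = stats, config = config)
  class(out) <- "tissue_report"
  out
}

#' @export
print.tissue_report <- function(x, ...) {
  cat("<tissue_report>", nrow(x$summaries), "tissues\n")
  if (!is.null(x$stats$fits$ppis_vs_sites)) {
    cat("  PPIs ~ binding sites: ")
    print(x$stats$fits$ppis_vs_sites)
  }
  invisible(x)
}
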
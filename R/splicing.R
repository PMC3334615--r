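#' Read a gene-level splicing table
#'
#' Columns: `gene_id`, `n_exons` (>= 1), `n_isoforms` (>= 1), `n_as_events`
#' (>= 0, the number of alternative-splicing events recorded for the gene).
#'
#' @param path TSV path.
#' @return Tibble with the four columns, validated.
#' @export
read_splicing_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    n_exons = readr::col_integer(),
    n_isoforms = readr::col_integer(),
    n_as_events = readr::col_integer()))
  validate_splicing_table(tbl)
  tbl
}

validate_splicing_table <- function(tbl) {
  stopifnot(all(c("gene_id", "n_exons", "n_isoforms", "n_as_events")
                %in% names(tbl)))
  if (any(tbl$n_exons < 1) || any(tbl$n_isoforms < 1) ||
      any(tbl$n_as_events < 0)) {
    stop("splicing table out of range: need n_exons >= 1, n_isoforms >= 1, ",
         "n_as_events >= 0")
  }
  invisible(TRUE)
}

#' Percent of multi-exon genes with alternative splice forms
#'
#' Single-exon genes cannot be alternatively spliced by exon choice, so both
#' numerator and denominator are restricted to genes with at least two exons.
#'
#' @param genes Gene-splicing table (see [read_splicing_table()]).
#' @return Percentage in \[0, 100\].
#' @export
percent_multiexon_as <- function(genes) {
  validate_splicing_table(genes)
  multi <- genes$n_exons >= 2
  if (!any(multi)) stop("no multi-exon genes in table")
  100 * sum(multi & genes$n_as_events >= 1) / sum(multi)
}

#' Mean number of alternative-splicing events per gene
#'
#' @param genes Gene-splicing table.
#' @param multiexon_only When `TRUE`, restrict the denominator (and
#'   numerator) to multi-exon genes; the default uses every gene in the
#'   table.
#' @return Mean events per gene.
#' @export
mean_as_events_per_gene <- function(genes, multiexon_only = FALSE) {
  validate_splicing_table(genes)
  if (multiexon_only) genes <- genes[genes$n_exons >= 2, ]
  if (nrow(genes) == 0) stop("empty splicing table")
  mean(genes$n_as_events)
}

#' Fraction of a tissue's proteins that are alternatively spliced
#'
#' @param proteins Character vector of the tissue's protein ids (non-empty).
#' @param as_flags Named logical vector mapping protein id to
#'   has-alternative-isoform. Proteins missing from the map count as not
#'   alternatively spliced, with a logged warning.
#' @return Fraction in \[0, 1\].
#' @export
tissue_as_fraction <- function(proteins, as_flags) {
  if (length(proteins) == 0) stop("empty tissue protein set")
  missing <- setdiff(proteins, names(as_flags))
  if (length(missing) > 0) {
    warning(length(missing),
            " tissue protein(s) missing from AS flags; counted as not-AS")
  }
  flags <- as_flags[proteins]
  flags[is.na(flags)] <- FALSE
  mean(flags)
}
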
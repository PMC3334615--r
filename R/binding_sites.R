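#' Segment a binding-propensity track into disordered binding sites
#'
#' Implements the run-and-merge calling rule for disordered binding regions:
#' a site requires at least `min_run` consecutive residues with score strictly
#' above `threshold`, and two adjacent sites are independent only when
#' separated by at least `min_sep` residues with scores strictly below
#' `threshold`. Residues exactly at the threshold are neither site residues
#' nor separators.
#'
#' The rule is applied in a fixed order:
#' \enumerate{
#'   \item find maximal runs of residues with score > `threshold`;
#'   \item candidate sites are the runs of length >= `min_run` (shorter runs
#'     never seed a site);
#'   \item consecutive candidates merge, transitively left to right, whenever
#'     fewer than `min_sep` residues strictly below `threshold` lie between
#'     them; a merged site spans from the first candidate's start to the
#'     last's end, absorbing everything between (including sub-`min_run`
#'     runs);
#'   \item `n_above` counts every above-threshold residue inside the final
#'     span.
#' }
#'
#' @param scores Numeric per-residue scores in \[0, 1\].
#' @param threshold Score threshold (default 0.5).
#' @param min_run Minimum run of above-threshold residues to seed a site
#'   (default 3).
#' @param min_sep Minimum count of below-threshold residues separating
#'   independent sites (default 3).
#' @return Tibble with 0-based half-open intervals: columns `start`, `end`,
#'   `n_above`; sites disjoint and sorted by `start`. Use
#'   [write_binding_sites()] for the 1-based inclusive file representation.
#' @examples
#' segment_binding_sites(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.9, 0.9, 0.9))
#' # one merged site [0, 8): only 2 below-threshold separators
#' @export
segment_binding_sites <- function(scores, threshold = 0.5, min_run = 3,
                                  min_sep = 3) {
  validate_scores(scores)
  stopifnot(min_run >= 1, min_sep >= 0)
  above <- scores > threshold
  below <- scores < threshold
  # low-overhead constructor: this function runs once per protein over
  # whole proteomes and in exhaustive property sweeps
  site_tbl <- function(start, end, n_above) {
    tibble::new_tibble(list(start = start, end = end, n_above = n_above),
                       nrow = length(start))
  }
  empty <- site_tbl(integer(), integer(), integer())
  if (!any(above)) return(empty)

  r <- rle(above)
  run_end <- cumsum(r$lengths)                 # 1-based inclusive
  run_start <- run_end - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_run)
  if (length(cand) == 0) return(empty)
  cs <- run_start[cand]
  ce <- run_end[cand]

  # transitive left-to-right merge on the below-threshold separator count
  below_cum <- cumsum(c(0L, below))
  starts <- cs[1]
  ends <- ce[1]
  for (i in seq_along(cand)[-1]) {
    gap_below <- below_cum[cs[i]] - below_cum[ends[length(ends)] + 1L]
    if (gap_below < min_sep) {
      ends[length(ends)] <- ce[i]
    } else {
      starts <- c(starts, cs[i])
      ends <- c(ends, ce[i])
    }
  }
  above_cum <- cumsum(c(0L, above))
  site_tbl(starts - 1L, as.integer(ends),
           as.integer(above_cum[ends + 1L] - above_cum[starts]))
}

#' Aggregate binding-site statistics over a proteome
#'
#' @param tracks Named list of binding-propensity score vectors.
#' @param threshold,min_run,min_sep Passed to [segment_binding_sites()].
#' @param residue_mode How `percent_binding_residues` counts residues:
#'   `"span"` (default) counts every residue inside a final site span;
#'   `"above"` counts only above-threshold residues inside spans.
#' @return A list of class `binding_summary`: `total_sites`,
#'   `mean_sites_per_protein`, `percent_binding_residues`, `n_proteins`, and
#'   `per_protein` (tibble with `protein_id`, `n_sites`, `site_residues`,
#'   `length`).
#' @export
summarize_binding_sites <- function(tracks, threshold = 0.5, min_run = 3,
                                    min_sep = 3,
                                    residue_mode = c("span", "above")) {
  residue_mode <- match.arg(residue_mode)
  if (length(tracks) == 0) stop("no score tracks supplied")
  per <- dplyr::bind_rows(lapply(names(tracks), function(id) {
    sites <- segment_binding_sites(tracks[[id]], threshold, min_run, min_sep)
    res <- if (residue_mode == "span") {
      sum(sites$end - sites$start)
    } else {
      sum(sites$n_above)
    }
    tibble::tibble(protein_id = id, n_sites = nrow(sites),
                   site_residues = as.integer(res),
                   length = length(tracks[[id]]))
  }))
  out <- list(total_sites = sum(per$n_sites),
              mean_sites_per_protein = sum(per$n_sites) / nrow(per),
              percent_binding_residues =
                100 * sum(per$site_residues) / sum(per$length),
              n_proteins = nrow(per),
              per_protein = per)
  class(out) <- "binding_summary"
  out
}

#' @export
print.binding_summary <- function(x, ...) {
  cat("<binding_summary>", x$n_proteins, "proteins\n",
      " total sites:", x$total_sites,
      " mean/protein:", signif(x$mean_sites_per_protein, 4),
      " %binding residues:", signif(x$percent_binding_residues, 4), "\n")
  invisible(x)
}

#' Call binding sites for every track
#' @param tracks Named list of score vectors.
#' @inheritParams segment_binding_sites
#' @return Tibble with `protein_id`, `start`, `end` (0-based half-open),
#'   `n_above`.
#' @export
call_binding_sites <- function(tracks, threshold = 0.5, min_run = 3,
                               min_sep = 3) {
  dplyr::bind_rows(lapply(names(tracks), function(id) {
    s <- segment_binding_sites(tracks[[id]], threshold, min_run, min_sep)
    if (nrow(s) == 0) return(NULL)
    dplyr::mutate(s, protein_id = id, .before = 1)
  }))
}

#' Write called binding sites as TSV (1-based inclusive coordinates)
#' @param sites Tibble from [call_binding_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_sites <- function(sites, path) {
  out <- tibble::tibble(protein_id = sites$protein_id,
                        start = sites$start + 1L,
                        end = sites$end,
                        n_above = sites$n_above)
  readr::write_tsv(out, path)
  invisible(path)
}
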
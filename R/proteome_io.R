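#' Read a proteome FASTA file into an isoform table
#'
#' Parses a multi-sequence amino-acid FASTA file (Ensembl/NCBI-style headers)
#' into one row per isoform. The protein identifier is the first whitespace-
#' delimited token of the header; the gene identifier is extracted from the
#' header with `gene_pattern` (first capture group). Headers without a gene
#' token fall back to `gene_id = protein_id`, so single-isoform proteomes
#' work without annotation.
#'
#' @param path Path to a FASTA file.
#' @param gene_pattern Regular expression with one capture group applied to the
#'   full header line to extract the gene identifier. The default matches an
#'   Ensembl-style `gene:<ID>` token.
#' @return A tibble with columns `protein_id`, `gene_id`, `sequence`, `length`,
#'   one row per FASTA entry in file order. Residues are uppercased; the 20
#'   standard letters plus ambiguity codes (X, B, Z, U, O, J) are accepted.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1 gene:G1", "MKV", ">P2 gene:G1", "MKVLAA"), fa)
#' read_proteome_fasta(fa)
#' @export
read_proteome_fasta <- function(path, gene_pattern = "gene:(\\S+)") {
  stopifnot(length(path) == 1, file.exists(path))
  # cheap pre-scan so malformed files fail with a line number rather than an
  # opaque parser error
  first <- scan_first_content_line(path)
  if (is.na(first$line)) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(protein_id = character(), gene_id = character(),
                          sequence = character(), length = integer()))
  }
  if (!startsWith(first$text, ">")) {
    stop("malformed FASTA (sequence before first header) at line ",
         first$line, " of ", path)
  }
  # Biostrings drops letters outside its amino-acid alphabet with a warning;
  # the contract here is a hard error naming the problem
  seqs <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("unknown residue code(s) in ", path)
      }
      invokeRestart("muffleWarning")
    })
  headers <- names(seqs)
  protein_id <- sub("\\s.*$", "", headers)
  gene_match <- regmatches(headers, regexec(gene_pattern, headers))
  gene_id <- vapply(seq_along(headers), function(i) {
    m <- gene_match[[i]]
    if (length(m) >= 2) m[2] else protein_id[i]
  }, character(1))
  sequence <- toupper(as.character(seqs))
  validate_aa_sequences(sequence, protein_id)
  if (anyDuplicated(protein_id)) {
    stop("duplicated protein_id in ", path, ": ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  }
  tibble::tibble(protein_id = unname(protein_id), gene_id = unname(gene_id),
                 sequence = unname(sequence), length = nchar(sequence))
}

scan_first_content_line <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  i <- 0L
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0) return(list(line = NA_integer_, text = NA_character_))
    i <- i + 1L
    if (nzchar(trimws(ln))) return(list(line = i, text = trimws(ln)))
  }
}

validate_aa_sequences <- function(sequence, protein_id) {
  letters_seen <- unique(strsplit(paste(sequence, collapse = ""), "")[[1]])
  bad <- setdiff(letters_seen, AA_ALPHABET)
  if (length(bad) > 0) {
    offender <- protein_id[grepl(paste0("[", paste(bad, collapse = ""), "]"),
                                 sequence)][1]
    stop("unknown residue code(s) ", paste(bad, collapse = ", "),
         " (first offending protein: ", offender, ")")
  }
  if (any(nchar(sequence) < 1)) {
    stop("zero-length sequence for protein ",
         protein_id[nchar(sequence) < 1][1])
  }
  invisible(TRUE)
}

#' Group isoforms by gene and flag the main (longest) isoform
#'
#' One gene's main isoform is its longest; ties are broken by first occurrence
#' in the input, so the result is stable under re-reading the same file.
#'
#' @param isoforms Isoform table as returned by [read_proteome_fasta()]
#'   (columns `protein_id`, `gene_id`, `length`; `sequence` optional).
#' @return The input tibble with a logical `is_main` column (exactly one
#'   `TRUE` per gene), rows in original order.
#' @export
group_isoforms <- function(isoforms) {
  stopifnot(all(c("protein_id", "gene_id", "length") %in% names(isoforms)))
  if (nrow(isoforms) == 0) {
    return(dplyr::mutate(isoforms, is_main = logical(0)))
  }
  isoforms |>
    dplyr::mutate(.input_order = dplyr::row_number()) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(is_main = dplyr::row_number(
      dplyr::desc(.data$length * 1e9 - .data$.input_order)) == 1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".input_order")
}

#' Proteome information content (PIC)
#'
#' PIC is the total number of amino acids in a proteome. In `"main"` mode only
#' the longest isoform of each gene is counted (the main-isoform complement);
#' in `"all"` mode every known splice variant contributes (the alternative
#' complement). Ambiguity codes count as ordinary residues.
#'
#' @param isoforms Isoform table (with or without an `is_main` column; it is
#'   computed when absent).
#' @param mode `"main"` or `"all"`.
#' @return Integer amino-acid count.
#' @examples
#' iso <- tibble::tibble(protein_id = c("P1", "P2", "P3"),
#'                       gene_id = c("G1", "G1", "G2"),
#'                       length = c(150L, 100L, 80L))
#' compute_pic(iso, "main")  # 230
#' compute_pic(iso, "all")   # 330
#' @export
compute_pic <- function(isoforms, mode = c("main", "all")) {
  mode <- match.arg(mode)
  if (nrow(isoforms) == 0) stop("empty proteome")
  if (mode == "all") return(as.integer(sum(isoforms$length)))
  if (!"is_main" %in% names(isoforms)) isoforms <- group_isoforms(isoforms)
  as.integer(sum(isoforms$length[isoforms$is_main]))
}

#' Number of distinct genes in an isoform table
#' @param isoforms Isoform table.
#' @return Integer gene count (0 for an empty table).
#' @export
gene_count <- function(isoforms) {
  length(unique(isoforms$gene_id))
}

#' Construct a proteome record
#'
#' Bundles a species' isoform table with its organismal complexity (cell-type
#' count) and phylogenetic clade. Bacteria are unicellular and must have
#' complexity exactly 1.
#'
#' @param species_id Species identifier.
#' @param clade One of `"bacteria"`, `"protozoa"`, `"fungi"`, `"plants"`,
#'   `"protostomes"`, `"deuterostomes"`.
#' @param complexity Integer cell-type count, at least 1.
#' @param isoforms Isoform table; `is_main` is added if missing.
#' @return An object of class `proteome`.
#' @export
proteome <- function(species_id, clade, complexity, isoforms) {
  clade <- match.arg(clade, CLADES)
  complexity <- as.integer(complexity)
  stopifnot(length(complexity) == 1, !is.na(complexity), complexity >= 1)
  if (clade == "bacteria" && complexity != 1L) {
    stop("bacteria have complexity exactly 1 (got ", complexity, ")")
  }
  if (nrow(isoforms) == 0) stop("empty proteome for species ", species_id)
  if (anyDuplicated(isoforms$protein_id)) stop("duplicated protein_id")
  if (!"is_main" %in% names(isoforms)) isoforms <- group_isoforms(isoforms)
  structure(list(species_id = species_id, clade = clade,
                 complexity = complexity, isoforms = isoforms),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("<proteome>", x$species_id, "\n",
      " clade:", x$clade, " complexity:", x$complexity, "\n",
      " genes:", gene_count(x$isoforms),
      " isoforms:", nrow(x$isoforms),
      " PIC(main):", compute_pic(x$isoforms, "main"),
      " PIC(all):", compute_pic(x$isoforms, "all"), "\n")
  invisible(x)
}

#' Per-species summary table
#'
#' @param proteomes A list of [proteome()] objects.
#' @return A tibble with columns `species_id`, `clade`, `complexity`,
#'   `n_genes`, `pic_main`, `pic_all`.
#' @export
species_summary <- function(proteomes) {
  dplyr::bind_rows(lapply(proteomes, function(p) {
    tibble::tibble(species_id = p$species_id, clade = p$clade,
                   complexity = p$complexity,
                   n_genes = gene_count(p$isoforms),
                   pic_main = compute_pic(p$isoforms, "main"),
                   pic_all = compute_pic(p$isoforms, "all"))
  }))
}
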
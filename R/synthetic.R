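#' Simulate a species panel with power-law PIC scaling
#'
#' Generates a panel of species whose proteome information content follows
#' `PIC = a * C^k * 10^eps` with `eps ~ Normal(0, log_noise_sd)` and
#' complexity `C` drawn log-uniformly over `complexity_range` (bacteria, when
#' requested, are pinned at complexity 1). Eukaryote clades are assigned by
#' complexity rank (protozoa, fungi, protostomes, deuterostomes from low to
#' high); optional plant species receive an inflated prefactor
#' (`plant_pic_multiplier`) at low complexity, emulating their relatively
#' large proteomes. Each species also carries a disorder target that rises
#' log-linearly with complexity over `disorder_range`, so downstream
#' disorder-complexity correlations have a known positive ground truth.
#'
#' With `sequences = TRUE`, proteins are sampled (truncated-normal lengths)
#' until the cumulative length reaches the species' PIC, so the realized
#' main-isoform PIC matches the target to within one protein length; a
#' fraction `isoform_rate` of genes gains one shorter alternative isoform,
#' and FASTA files with `gene:<ID>` headers are written under `dir`.
#'
#' @param n_species Number of eukaryote species.
#' @param k_true True scaling exponent (default 0.25).
#' @param prefactor_true True prefactor `a` (default 2e4, which keeps
#'   synthetic proteomes small enough to analyse in seconds).
#' @param log_noise_sd SD of the log10-normal noise (default 0.15).
#' @param complexity_range Integer range for eukaryote cell-type counts.
#' @param n_bacteria Number of bacteria (complexity 1) to add.
#' @param n_plants Number of plants among the eukaryotes.
#' @param plant_pic_multiplier Prefactor multiplier for plants (default 3).
#' @param disorder_range Range of per-species disorder targets (fractions).
#' @param protein_length_mean,protein_length_sd Protein length distribution
#'   (residues; truncated below at 50).
#' @param isoform_rate Fraction of genes with one extra splice variant.
#' @param sequences Generate sequences/FASTA files (default FALSE: table
#'   only, used for fast fit-recovery experiments).
#' @param dir Output directory for FASTA files (required when
#'   `sequences = TRUE`).
#' @param seed Integer seed (mandatory).
#' @return List with `species` (tibble: `species_id`, `clade`, `complexity`,
#'   `pic_true`, `disorder_target`, and with sequences `n_genes`,
#'   `pic_main`, `pic_all`, `fasta`), `isoforms` (named list of isoform
#'   tibbles when `sequences = TRUE`), and `config` (the generating
#'   parameters).
#' @export
simulate_species_panel <- function(n_species = 53, k_true = 0.25,
                                   prefactor_true = 2e4, log_noise_sd = 0.15,
                                   complexity_range = c(2, 200),
                                   n_bacteria = 0, n_plants = 0,
                                   plant_pic_multiplier = 3,
                                   disorder_range = c(0.05, 0.30),
                                   protein_length_mean = 350,
                                   protein_length_sd = 100,
                                   isoform_rate = 0.15,
                                   sequences = FALSE, dir = NULL,
                                   seed) {
  stopifnot(n_species >= 3, !missing(seed), n_plants <= n_species)
  if (sequences && is.null(dir)) stop("dir is required when sequences = TRUE")
  config <- list(n_species = n_species, k_true = k_true,
                 prefactor_true = prefactor_true,
                 log_noise_sd = log_noise_sd,
                 complexity_range = complexity_range,
                 n_bacteria = n_bacteria, n_plants = n_plants,
                 plant_pic_multiplier = plant_pic_multiplier,
                 disorder_range = disorder_range,
                 protein_length_mean = protein_length_mean,
                 protein_length_sd = protein_length_sd,
                 isoform_rate = isoform_rate, seed = seed)
  withr::with_seed(seed, {
    lo <- log10(complexity_range[1]); hi <- log10(complexity_range[2])
    complexity <- pmax(complexity_range[1],
                       round(10^runif(n_species, lo, hi)))
    ord <- order(complexity)
    clade <- character(n_species)
    # clades by complexity rank; plants drawn from the lower half
    clade[ord] <- c("protozoa", "fungi", "protostomes",
                    "deuterostomes")[cut(seq_len(n_species), 4,
                                         labels = FALSE)]
    if (n_plants > 0) {
      low_half <- ord[seq_len(ceiling(n_species / 2))]
      plant_idx <- sample(low_half, n_plants)
      clade[plant_idx] <- "plants"
    }
    prefac <- ifelse(clade == "plants",
                     prefactor_true * plant_pic_multiplier, prefactor_true)
    eps <- rnorm(n_species, 0, log_noise_sd)
    pic_true <- prefac * complexity^k_true * 10^eps
    if (n_bacteria > 0) {
      complexity <- c(complexity, rep(1L, n_bacteria))
      clade <- c(clade, rep("bacteria", n_bacteria))
      eps_b <- rnorm(n_bacteria, 0, log_noise_sd)
      pic_true <- c(pic_true, prefactor_true * 10^eps_b)
    }
    n_total <- length(complexity)
    dmin <- disorder_range[1]; dmax <- disorder_range[2]
    rel <- (log10(complexity) - 0) / (hi - 0)  # C = 1 maps to dmin
    disorder_target <- pmin(dmax, pmax(dmin, dmin + (dmax - dmin) * rel +
                                         rnorm(n_total, 0, 0.01)))
    species <- tibble::tibble(
      species_id = sprintf("SP%03d", seq_len(n_total)),
      clade = clade, complexity = as.integer(complexity),
      pic_true = pic_true, disorder_target = disorder_target)
    isoforms <- NULL
    if (sequences) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      gen <- lapply(seq_len(n_total), function(i) {
        simulate_proteome_sequences(species$species_id[i], pic_true[i],
                                    protein_length_mean, protein_length_sd,
                                    isoform_rate)
      })
      isoforms <- lapply(gen, `[[`, "isoforms")
      names(isoforms) <- species$species_id
      species$n_genes <- vapply(isoforms, gene_count, integer(1))
      species$pic_main <- vapply(isoforms, compute_pic, integer(1), "main")
      species$pic_all <- vapply(isoforms, compute_pic, integer(1), "all")
      species$fasta <- file.path(dir, paste0(species$species_id, ".fa"))
      for (i in seq_len(n_total)) {
        write_isoform_fasta(isoforms[[i]], species$fasta[i])
      }
    }
    list(species = species, isoforms = isoforms, config = config)
  })
}

# sample one species' isoform table; total main-isoform length reaches
# pic_target within one protein length
simulate_proteome_sequences <- function(species_id, pic_target, len_mean,
                                        len_sd, isoform_rate) {
  lens <- integer(0)
  total <- 0
  while (total < pic_target) {
    l <- max(50L, round(rnorm(1, len_mean, len_sd)))
    lens <- c(lens, l)
    total <- total + l
  }
  n_genes <- length(lens)
  gene_id <- sprintf("%s_G%05d", species_id, seq_len(n_genes))
  main <- tibble::tibble(
    protein_id = sprintf("%s_P%05d.1", species_id, seq_len(n_genes)),
    gene_id = gene_id,
    sequence = vapply(lens, random_aa_sequence, character(1)),
    length = lens)
  extra_idx <- which(runif(n_genes) < isoform_rate)
  if (length(extra_idx) > 0) {
    alt_len <- pmax(50L, round(0.7 * lens[extra_idx]))
    alt <- tibble::tibble(
      protein_id = sprintf("%s_P%05d.2", species_id, extra_idx),
      gene_id = gene_id[extra_idx],
      sequence = vapply(alt_len, random_aa_sequence, character(1)),
      length = alt_len)
    main <- dplyr::bind_rows(main, alt)
  }
  list(isoforms = group_isoforms(main))
}

random_aa_sequence <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

#' Write an isoform table as FASTA with gene-annotated headers
#' @param isoforms Isoform table with `protein_id`, `gene_id`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_isoform_fasta <- function(isoforms, path) {
  seqs <- Biostrings::AAStringSet(isoforms$sequence)
  names(seqs) <- paste0(isoforms$protein_id, " gene:", isoforms$gene_id)
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Simulate two-state disorder score tracks
#'
#' For each protein, exactly `round(target * length)` residues are disordered
#' (so the realized per-protein disorder fraction matches the target to
#' within rounding), arranged as alternating segments with geometric lengths
#' of mean `segment_length_mean`. Disordered residues score
#' Uniform(0.55, 1.0) and ordered residues Uniform(0.0, 0.45); the band
#' \[0.45, 0.55\] around the classification threshold is deliberately avoided
#' so threshold-boundary behaviour is exercised only by dedicated fixtures.
#'
#' @param lengths Named integer vector of protein lengths.
#' @param disorder_target Fraction in \[0, 1\], recycled over proteins.
#' @param segment_length_mean Mean segment length in residues (default 40).
#' @param seed Optional integer seed.
#' @return List with `tracks` (named list of score vectors) and
#'   `true_fraction` (named numeric: realized disordered fraction per
#'   protein).
#' @export
simulate_score_tracks <- function(lengths, disorder_target = 0.3,
                                  segment_length_mean = 40, seed = NULL) {
  stopifnot(length(lengths) >= 1, !is.null(names(lengths)),
            all(disorder_target >= 0 & disorder_target <= 1))
  target <- rep_len(disorder_target, length(lengths))
  gen <- function() {
    tracks <- lapply(seq_along(lengths), function(i) {
      simulate_one_track(lengths[i], target[i], segment_length_mean)
    })
    names(tracks) <- names(lengths)
    tracks
  }
  tracks <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  frac <- vapply(tracks, function(s) mean(s > 0.5), numeric(1))
  list(tracks = tracks, true_fraction = frac)
}

simulate_one_track <- function(len, target, seg_mean) {
  n_dis <- round(target * len)
  n_ord <- len - n_dis
  state <- logical(len)  # TRUE = disordered
  if (n_dis == len) {
    state[] <- TRUE
  } else if (n_dis > 0) {
    seg_lengths <- function(total) {
      out <- integer(0)
      while (sum(out) < total) {
        out <- c(out, 1L + rgeom(1, 1 / seg_mean))
      }
      over <- sum(out) - total
      out[length(out)] <- out[length(out)] - over
      out[out > 0]
    }
    dis <- seg_lengths(n_dis)
    ord <- seg_lengths(n_ord)
    start_dis <- runif(1) < 0.5
    segs <- integer(0); states <- logical(0)
    di <- 1L; oi <- 1L; cur <- start_dis
    while (di <= length(dis) || oi <= length(ord)) {
      if (cur && di <= length(dis)) {
        segs <- c(segs, dis[di]); states <- c(states, TRUE); di <- di + 1L
      } else if (!cur && oi <= length(ord)) {
        segs <- c(segs, ord[oi]); states <- c(states, FALSE); oi <- oi + 1L
      }
      cur <- !cur
    }
    state <- rep(states, segs)
  }
  scores <- numeric(len)
  scores[state] <- runif(sum(state), 0.55, 1.0)
  scores[!state] <- runif(sum(!state), 0.0, 0.45)
  scores
}

#' Plant binding sites into a score track
#'
#' Overwrites a track so that segmentation recovers a known site list
#' exactly: `n_sites` runs of `site_length` scores in (0.55, 1.0), each pair
#' of consecutive sites separated by at least `separation` residues, and
#' every background residue strictly below 0.5 (Uniform(0, 0.45)). Leftover
#' space beyond the minimum layout is distributed randomly between the
#' sites. A separation below 3 would merge adjacent plants under the default
#' segmentation rule, so the generator refuses it unless `allow_merge` is
#' set.
#'
#' @param track Numeric score vector to modify (its length defines the
#'   layout space).
#' @param n_sites Number of sites to plant (>= 0).
#' @param site_length Length of each site (>= 3 to be callable).
#' @param separation Minimum residues between consecutive sites.
#' @param allow_merge Permit `separation < 3` (default FALSE).
#' @param seed Optional integer seed.
#' @return List with `scores` (the modified track) and `sites` (tibble
#'   `start`, `end` 0-based half-open, `n_above`).
#' @export
plant_binding_sites <- function(track, n_sites, site_length, separation = 4,
                                allow_merge = FALSE, seed = NULL) {
  len <- length(track)
  stopifnot(n_sites >= 0, site_length >= 1, separation >= 0)
  if (n_sites > 1 && separation < 3 && !allow_merge) {
    stop("separation < 3 would merge adjacent sites; ",
         "set allow_merge = TRUE if that is intended")
  }
  required <- n_sites * site_length + max(0, n_sites - 1) * separation
  if (required > len) {
    stop("site plan needs ", required, " residues but track has ", len)
  }
  gen <- function() {
    scores <- runif(len, 0.0, 0.45)
    if (n_sites == 0) {
      return(list(scores = scores,
                  sites = tibble::tibble(start = integer(), end = integer(),
                                         n_above = integer())))
    }
    slack <- len - required
    # distribute slack over n_sites + 1 gaps (before, between, after)
    extra <- if (slack > 0) {
      tabulate(sample.int(n_sites + 1L, slack, replace = TRUE),
               nbins = n_sites + 1L)
    } else rep(0L, n_sites + 1L)
    gaps <- as.integer(
      c(extra[1], separation + extra[seq_len(max(0, n_sites - 1)) + 1L]))
    site_length <- as.integer(site_length)
    starts <- integer(n_sites)
    pos <- 0L
    for (i in seq_len(n_sites)) {
      pos <- pos + gaps[i]
      starts[i] <- pos            # 0-based
      pos <- pos + site_length
    }
    for (s in starts) {
      scores[(s + 1):(s + site_length)] <- runif(site_length, 0.55, 1.0)
    }
    list(scores = scores,
         sites = tibble::tibble(start = starts,
                                end = starts + as.integer(site_length),
                                n_above = as.integer(site_length)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a random interactome
#'
#' Erdos-Renyi graph over the given proteins with edge probability
#' `mean_degree / (n - 1)`, so the expected mean degree equals
#' `mean_degree`. Confidences are drawn so that a fraction
#' `high_conf_fraction` of edges scores in \[900, 1000\] and the rest in
#' \[150, 899\].
#'
#' @param protein_ids Character vector of proteins (n >= 2 for any edges).
#' @param mean_degree Expected mean degree (0 gives an empty edge list).
#' @param high_conf_fraction Fraction of edges at score >= 900 (default
#'   0.5).
#' @param seed Integer seed (mandatory).
#' @return List with `interactions` (canonical tibble `protein_a`,
#'   `protein_b`, `confidence`) and `true_degrees` (named integer vector
#'   over all proteins).
#' @export
simulate_interactome <- function(protein_ids, mean_degree = 6,
                                 high_conf_fraction = 0.5, seed) {
  stopifnot(!missing(seed), mean_degree >= 0,
            high_conf_fraction >= 0, high_conf_fraction <= 1)
  n <- length(protein_ids)
  withr::with_seed(seed, {
    edges <- if (n < 2 || mean_degree == 0) {
      integer(0)
    } else {
      n_pairs <- n * (n - 1) / 2
      p <- min(1, mean_degree / (n - 1))
      m <- rbinom(1, n_pairs, p)
      sort(sample.int(n_pairs, m))
    }
    if (length(edges) == 0) {
      ints <- tibble::tibble(protein_a = character(),
                             protein_b = character(),
                             confidence = integer())
    } else {
      ij <- pair_index_decode(edges, n)
      conf <- ifelse(runif(length(edges)) < high_conf_fraction,
                     sample(900:1000, length(edges), replace = TRUE),
                     sample(150:899, length(edges), replace = TRUE))
      ints <- canonicalize_interactions(tibble::tibble(
        protein_a = protein_ids[ij$i], protein_b = protein_ids[ij$j],
        confidence = as.integer(conf)))
    }
    deg <- table(factor(c(ints$protein_a, ints$protein_b),
                        levels = protein_ids))
    list(interactions = ints,
         true_degrees = setNames(as.integer(deg), protein_ids))
  })
}

# decode 1-based pair index k over pairs (i < j) ordered by i, then j
pair_index_decode <- function(k, n) {
  cum <- cumsum((n - 1):1)
  i <- findInterval(k - 0.5, c(0, cum))
  j <- i + (k - c(0, cum)[i])
  list(i = i, j = j)
}

#' Simulate a gene-level splicing table
#'
#' Exon counts are 1 + Poisson(`exon_mean` - 1); multi-exon genes receive
#' Poisson(`as_event_rate`) alternative-splicing events, single-exon genes
#' none; `n_isoforms = n_as_events + 1`.
#'
#' @param n_genes Number of genes.
#' @param as_event_rate Poisson mean of AS events per multi-exon gene.
#' @param exon_mean Mean exon count (default 8).
#' @param seed Integer seed (mandatory).
#' @return List with `genes` (splicing tibble) and `truth`
#'   (`as_event_rate`, `exon_mean`).
#' @export
simulate_splicing_table <- function(n_genes, as_event_rate = 0.5,
                                    exon_mean = 8, seed) {
  stopifnot(!missing(seed), n_genes >= 1, as_event_rate >= 0, exon_mean >= 1)
  withr::with_seed(seed, {
    n_exons <- 1L + rpois(n_genes, exon_mean - 1)
    n_as <- ifelse(n_exons >= 2, rpois(n_genes, as_event_rate), 0L)
    genes <- tibble::tibble(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      n_exons = as.integer(n_exons),
      n_isoforms = as.integer(n_as + 1L),
      n_as_events = as.integer(n_as))
    list(genes = genes,
         truth = list(as_event_rate = as_event_rate, exon_mean = exon_mean))
  })
}

#' Simulate a tissue panel with configurable couplings
#'
#' Builds `n_tissues` tissues with log-uniform cell-type counts and, per
#' tissue, a disjoint set of proteins with:
#' \itemize{
#'   \item disorder tracks whose target fraction rises log-linearly with
#'     complexity over `disorder_range`;
#'   \item binding tracks with exactly
#'     `round(sites_prefactor * C^sites_exponent * 10^eps)` planted sites
#'     distributed over the tissue's proteins;
#'   \item exactly `round(ppi_prefactor * S^ppi_vs_sites_exponent * 10^eps)`
#'     high-confidence intra-tissue interactions (plus low-confidence
#'     distractor edges that the >= 900 filter must remove), where `S` is the
#'     tissue's planted site total;
#'   \item an alternatively-spliced fraction rising log-linearly with
#'     complexity over `as_range`.
#' }
#' All noise terms are log10-normal with SD `log_noise_sd`
#' (default log10(1.1), i.e. about 10% multiplicative noise).
#'
#' @param n_tissues Number of tissues (default 12).
#' @param proteins_per_tissue Proteins annotated to each tissue (default
#'   60).
#' @param complexity_range Cell-type count range (default c(4, 60)).
#' @param track_length Residues per protein track (default 400).
#' @param disorder_range Disorder-target range over complexity.
#' @param sites_prefactor,sites_exponent Site total `S = sites_prefactor *
#'   C^sites_exponent` before noise (defaults 20 and 1).
#' @param ppi_prefactor,ppi_vs_sites_exponent PPI total `P = ppi_prefactor *
#'   S^ppi_vs_sites_exponent` before noise (defaults 0.001 and 2: the
#'   quadratic sites-to-interactions coupling).
#' @param as_range Alternatively-spliced fraction range over complexity.
#' @param log_noise_sd SD of the log10 noise on site and PPI totals
#'   (default `log10(1.1)`); 0 gives exact couplings.
#' @param low_conf_edges Distractor edges per tissue at confidence < 900
#'   (default 30).
#' @param seed Integer seed (mandatory).
#' @return List with `tissues` (tibble `tissue`, `complexity`),
#'   `annotation` (`protein_id`, `tissue`), `tracks` (disorder),
#'   `binding_tracks`, `interactions` (canonical, mixed confidence),
#'   `as_flags` (named logical), `truth` (tibble of per-tissue planted
#'   values: `disorder_target`, `total_sites`, `total_ppis_highconf`,
#'   `as_fraction`), and `config`.
#' @export
simulate_tissue_panel <- function(n_tissues = 12, proteins_per_tissue = 60,
                                  complexity_range = c(4, 60),
                                  track_length = 400,
                                  disorder_range = c(0.08, 0.30),
                                  sites_prefactor = 20, sites_exponent = 1,
                                  ppi_prefactor = 6e-4,
                                  ppi_vs_sites_exponent = 2,
                                  as_range = c(0.2, 0.8),
                                  log_noise_sd = log10(1.1),
                                  low_conf_edges = 30, seed) {
  stopifnot(!missing(seed), n_tissues >= 4, proteins_per_tissue >= 2)
  config <- as.list(environment())
  withr::with_seed(seed, {
    lo <- log10(complexity_range[1]); hi <- log10(complexity_range[2])
    complexity <- pmax(complexity_range[1],
                       round(10^seq(lo, hi, length.out = n_tissues)))
    tissue <- sprintf("tissue_%02d", seq_len(n_tissues))
    rel <- (log10(complexity) - lo) / (hi - lo)
    disorder_target <- disorder_range[1] +
      (disorder_range[2] - disorder_range[1]) * rel
    as_target <- as_range[1] + (as_range[2] - as_range[1]) * rel
    # capacity: 5-residue sites with 4-residue separators per track
    site_cap <- floor((track_length + 4) / (5 + 4))
    sites_target <- pmin(proteins_per_tissue * site_cap, pmax(1,
      round(sites_prefactor * complexity^sites_exponent *
              10^rnorm(n_tissues, 0, log_noise_sd))))
    max_pairs <- proteins_per_tissue * (proteins_per_tissue - 1) / 2
    ppi_target <- pmin(max_pairs, pmax(1,
      round(ppi_prefactor * sites_target^ppi_vs_sites_exponent *
              10^rnorm(n_tissues, 0, log_noise_sd))))

    annotation <- NULL
    tracks <- list(); binding_tracks <- list()
    ints <- list(); as_flags <- logical(0)
    for (t in seq_len(n_tissues)) {
      ids <- sprintf("%s_PR%03d", tissue[t], seq_len(proteins_per_tissue))
      annotation <- dplyr::bind_rows(
        annotation, tibble::tibble(protein_id = ids, tissue = tissue[t]))
      lens <- setNames(rep(track_length, proteins_per_tissue), ids)
      tracks <- c(tracks,
                  simulate_score_tracks(lens, disorder_target[t],
                                        segment_length_mean = 30)$tracks)
      # spread the tissue's site total over its proteins, then plant
      per_prot <- tabulate(sample.int(proteins_per_tissue, sites_target[t],
                                      replace = TRUE),
                           nbins = proteins_per_tissue)
      while (any(per_prot > site_cap)) {  # total <= capacity by clipping
        over <- which(per_prot > site_cap)[1]
        room <- which(per_prot < site_cap)[1]
        per_prot[over] <- per_prot[over] - 1L
        per_prot[room] <- per_prot[room] + 1L
      }
      bt <- lapply(seq_len(proteins_per_tissue), function(i) {
        plant_binding_sites(numeric(track_length), per_prot[i],
                            site_length = 5, separation = 4)$scores
      })
      names(bt) <- ids
      binding_tracks <- c(binding_tracks, bt)
      # exact count of high-confidence intra-tissue edges + distractors
      hi_idx <- sample.int(max_pairs, ppi_target[t])
      ij <- pair_index_decode(sort(hi_idx), proteins_per_tissue)
      e_hi <- tibble::tibble(protein_a = ids[ij$i], protein_b = ids[ij$j],
                             confidence = sample(900:1000, ppi_target[t],
                                                 replace = TRUE))
      lo_pool <- setdiff(seq_len(max_pairs), hi_idx)
      n_lo <- min(low_conf_edges, length(lo_pool))
      e_lo <- if (n_lo > 0) {
        lj <- pair_index_decode(sort(sample(lo_pool, n_lo)),
                                proteins_per_tissue)
        tibble::tibble(protein_a = ids[lj$i], protein_b = ids[lj$j],
                       confidence = sample(150:899, n_lo, replace = TRUE))
      } else NULL
      ints[[t]] <- dplyr::bind_rows(e_hi, e_lo)
      n_as <- round(as_target[t] * proteins_per_tissue)
      flagged <- sample(ids, n_as)
      as_flags <- c(as_flags,
                    setNames(ids %in% flagged, ids))
    }
    interactions <- canonicalize_interactions(dplyr::bind_rows(ints))
    truth <- tibble::tibble(
      tissue = tissue, complexity = as.integer(complexity),
      disorder_target = disorder_target,
      total_sites = as.integer(sites_target),
      total_ppis_highconf = as.integer(ppi_target),
      as_fraction = round(as_target * proteins_per_tissue) /
        proteins_per_tissue)
    list(tissues = tibble::tibble(tissue = tissue,
                                  complexity = as.integer(complexity)),
         annotation = annotation, tracks = tracks,
         binding_tracks = binding_tracks, interactions = interactions,
         as_flags = as_flags, truth = truth, config = config)
  })
}
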
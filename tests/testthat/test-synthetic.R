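test_that("species panel is seed-stable and hits its PIC targets", {
  d1 <- file.path(tempdir(), "panelA"); d2 <- file.path(tempdir(), "panelB")
  p1 <- simulate_species_panel(n_species = 6, sequences = TRUE, dir = d1,
                               seed = 42, prefactor_true = 5000)
  p2 <- simulate_species_panel(n_species = 6, sequences = TRUE, dir = d2,
                               seed = 42, prefactor_true = 5000)
  # same seed: identical tables and byte-identical FASTA files
  expect_equal(p1$species[setdiff(names(p1$species), "fasta")],
               p2$species[setdiff(names(p2$species), "fasta")])
  for (i in seq_len(nrow(p1$species))) {
    expect_identical(readLines(p1$species$fasta[i]),
                     readLines(p2$species$fasta[i]))
  }
  # realized main-isoform PIC within one protein length of the target
  max_len <- max(unlist(lapply(p1$isoforms, function(x) x$length)))
  expect_true(all(p1$species$pic_main - p1$species$pic_true >= 0))
  expect_true(all(p1$species$pic_main - p1$species$pic_true <= max_len))
  # FASTA files pass the same validators as real inputs
  iso <- read_proteome_fasta(p1$species$fasta[1])
  expect_gt(nrow(iso), 0)
  expect_equal(sort(iso$protein_id),
               sort(p1$isoforms[[p1$species$species_id[1]]]$protein_id))
})

test_that("noiseless panels return the exact configured exponent", {
  p <- simulate_species_panel(n_species = 20, k_true = 0.3,
                              log_noise_sd = 0, seed = 7)
  f <- fit_power_law(p$species$complexity, p$species$pic_true)
  expect_equal(f$exponent, 0.3, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("score-track generator hits targets and avoids the threshold band", {
  lens <- setNames(rep(500L, 40), sprintf("p%02d", 1:40))
  tr <- simulate_score_tracks(lens, disorder_target = 0.3, seed = 9)
  # per-protein realized fraction within rounding of the target
  expect_true(all(abs(tr$true_fraction - 0.3) < 0.002))
  expect_equal(proteome_mean_disorder(tr$tracks), 30, tolerance = 1)
  # the threshold-adjacent band is avoided by construction
  all_scores <- unlist(tr$tracks)
  expect_false(any(all_scores > 0.45 & all_scores < 0.55))
  # edge targets
  t0 <- simulate_score_tracks(lens[1:3], 0, seed = 1)
  expect_equal(unname(t0$true_fraction), c(0, 0, 0))
  t1 <- simulate_score_tracks(lens[1:3], 1, seed = 1)
  expect_equal(unname(t1$true_fraction), c(1, 1, 1))
})

test_that("planted binding sites are recovered exactly by segmentation", {
  set.seed(33)
  for (i in 1:100) {
    n_sites <- sample(0:5, 1)
    site_len <- sample(3:10, 1)
    sep <- sample(3:8, 1)
    p <- plant_binding_sites(numeric(300), n_sites, site_len, sep)
    got <- segment_binding_sites(p$scores)
    expect_equal(site_key(got), site_key(p$sites))
  }
  # refusal cases
  expect_error(plant_binding_sites(numeric(10), 2, 5, 4), "plan needs")
  expect_error(plant_binding_sites(numeric(300), 2, 5, 2), "would merge")
  expect_s3_class(
    plant_binding_sites(numeric(300), 2, 5, 2, allow_merge = TRUE)$sites,
    "tbl_df")
})

test_that("simulated interactomes match configured degree structure", {
  ids <- sprintf("q%04d", 1:1000)
  sim <- simulate_interactome(ids, mean_degree = 6, seed = 19)
  d <- degree_stats(sim$interactions, ids)
  expect_equal(mean(d$degrees$degree), 6, tolerance = 0.05 * 6)
  expect_equal(setNames(d$degrees$degree, d$degrees$protein_id),
               sim$true_degrees)
  # edge cases
  expect_equal(nrow(simulate_interactome(ids[1:10], 0,
                                         seed = 1)$interactions), 0L)
  full <- simulate_interactome(ids[1:5], mean_degree = 4, seed = 1)
  expect_equal(nrow(full$interactions), 10L)  # complete graph on 5
})

test_that("splicing generator matches its Poisson ground truth", {
  sim <- simulate_splicing_table(4000, as_event_rate = 1.3, seed = 27)
  expect_equal(mean_as_events_per_gene(sim$genes), 1.3, tolerance = 0.1)
  zero <- simulate_splicing_table(200, as_event_rate = 0, seed = 3)
  expect_equal(percent_multiexon_as(zero$genes), 0)
  expect_true(all(zero$genes$n_isoforms == 1L))
})

test_that("tissue generator writes files that pass the input validators", {
  tp <- simulate_tissue_panel(n_tissues = 5, proteins_per_tissue = 20,
                              seed = 77)
  td <- tempdir()
  write_score_tracks(tp$tracks, file.path(td, "tt.tsv"))
  back <- read_score_tracks(file.path(td, "tt.tsv"))
  expect_equal(length(back), length(tp$tracks))
  write_interactions(tp$interactions, file.path(td, "ti.tsv"))
  ints <- read_interactions(file.path(td, "ti.tsv"))
  expect_equal(nrow(ints), nrow(tp$interactions))
  # degrees within each tissue respect the handshake lemma
  for (t in tp$tissues$tissue[1:2]) {
    prot <- tp$annotation$protein_id[tp$annotation$tissue == t]
    sub <- restrict_to_tissue(tp$interactions, prot)
    d <- degree_stats(sub, prot)
    expect_equal(sum(d$degrees$degree), 2L * d$total_interactions)
  }
})
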
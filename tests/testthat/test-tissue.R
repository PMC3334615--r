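test_that("tissue complexity counts distinct, case-normalized cell types", {
  tbl <- tibble::tibble(
    tissue = c("liver", "liver", "liver", "brain", "brain", "brain"),
    cell_type = c("Hepatocyte", "hepatocyte ", "Kupffer cell",
                  "neuron", "astrocyte", "microglia"))
  tc <- tissue_complexity(tbl)
  got <- setNames(tc$complexity, tc$tissue)
  expect_equal(got[["liver"]], 2L)   # duplicate counted once
  expect_equal(got[["brain"]], 3L)
  expect_error(tissue_complexity(
    tibble::tibble(tissue = "x", cell_type = "")), "empty cell-type")
})

test_that("tissue summary medians and totals match hand computation", {
  tracks <- list(
    p1 = c(rep(0.9, 1), rep(0.1, 9)),    # 10% disordered, no site
    p2 = c(rep(0.9, 2), rep(0.1, 8)),    # 20%
    p3 = c(rep(0.9, 9), rep(0.1, 1)))    # 90%, one site
  ints <- tibble::tibble(protein_a = "p1", protein_b = "p2",
                         confidence = 950L)
  s <- summarize_tissue(c("p1", "p2", "p3"), tracks, ints)
  expect_equal(s$median_disorder_percent, 20)
  expect_equal(s$total_ppis, 1L)
  expect_equal(s$median_partners, 1)       # degrees 1, 1, 0
  expect_equal(s$total_binding_sites, 1L)  # only p3 has a run >= 3
})

test_that("tissue summary counts sites only for qualifying runs", {
  tracks <- list(
    p1 = rep(0.2, 10),
    p2 = c(rep(0.9, 2), rep(0.1, 8)),
    p3 = c(rep(0.9, 9), rep(0.1, 1)))
  ints <- tibble::tibble(protein_a = character(), protein_b = character(),
                         confidence = integer())
  s <- summarize_tissue(c("p1", "p2", "p3"), tracks, ints)
  expect_equal(s$total_binding_sites, 1L)
  expect_equal(s$median_partners, 0)
  expect_equal(s$total_ppis, 0L)
})

test_that("proteins without tracks are excluded from medians with warning", {
  tracks <- list(p1 = c(0.9, 0.9), p2 = c(0.1, 0.1))
  ints <- tibble::tibble(protein_a = character(), protein_b = character(),
                         confidence = integer())
  expect_warning(
    s <- summarize_tissue(c("p1", "p2", "p9"), tracks, ints),
    "without a score track")
  expect_equal(s$median_disorder_percent, 50)
  expect_equal(s$n_proteins, 3L)
})

test_that("medians ignore proteins outside the tissue set", {
  tracks <- list(in1 = rep(0.9, 10), in2 = rep(0.1, 10),
                 out = rep(0.9, 10))
  ints <- tibble::tibble(protein_a = "in1", protein_b = "out",
                         confidence = 950L)
  s <- summarize_tissue(c("in1", "in2"), tracks, ints)
  expect_equal(s$median_disorder_percent, 50)
  expect_equal(s$total_ppis, 0L)  # partner outside the tissue
})

test_that("panel summary and correlations recover planted couplings", {
  tp <- simulate_tissue_panel(n_tissues = 8, proteins_per_tissue = 40,
                              seed = 123)
  ints_hi <- filter_confidence(tp$interactions)
  summaries <- summarize_tissue_panel(tp$tissues, tp$annotation, tp$tracks,
                                      ints_hi, tp$as_flags,
                                      binding_tracks = tp$binding_tracks)
  expect_equal(nrow(summaries), 8L)
  # planted per-tissue ground truth is recovered exactly where exact by
  # construction
  expect_equal(summaries$total_binding_sites, tp$truth$total_sites)
  expect_equal(summaries$total_ppis, tp$truth$total_ppis_highconf)
  expect_equal(summaries$as_fraction, tp$truth$as_fraction)
  st <- suppressMessages(correlate_tissue_metrics(summaries))
  cors <- setNames(st$correlations$r, st$correlations$metric)
  for (m in c("median_disorder_percent", "total_ppis",
              "total_binding_sites", "as_fraction")) {
    expect_gt(cors[[m]], 0)
  }
  expect_equal(st$fits$ppis_vs_sites$exponent, 2, tolerance = 0.15)
})

test_that("degenerate tissue inputs are handled", {
  expect_error(correlate_tissue_metrics(
    tibble::tibble(complexity = 1:3, total_ppis = 1:3,
                   total_binding_sites = 1:3)), "at least 4")
  # constant metric is skipped with a notice, not an error
  sm <- tibble::tibble(complexity = c(2, 4, 8, 16),
                       median_disorder_percent = c(1, 2, 3, 4),
                       median_partners = rep(5, 4),
                       total_ppis = c(10, 20, 40, 80),
                       total_binding_sites = c(3, 6, 12, 24),
                       as_fraction = c(.1, .2, .3, .4),
                       median_disorder_alt = rep(NA_real_, 4))
  expect_message(st <- correlate_tissue_metrics(sm), "skipped")
  expect_true(is.na(
    st$correlations$r[st$correlations$metric == "median_partners"]))
  expect_equal(st$fits$ppis_vs_sites$exponent, 1, tolerance = 1e-10)
  # both orientations reported, reciprocal on noiseless data
  expect_equal(st$fits$sites_vs_ppis$exponent, 1, tolerance = 1e-10)
})
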
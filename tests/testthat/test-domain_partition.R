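sf_table <- tibble::tibble(
  superfamily_id = c("sf.exp", "sf.non", "sf.mid", "sf.hi", "sf.lo"),
  expansion_r = c(0.9, 0.1, 0.5, 0.8, 0.2))

test_that("superfamily classification uses inclusive boundaries", {
  cls <- classify_superfamilies(sf_table)
  got <- setNames(cls$class, cls$superfamily_id)
  expect_equal(got[["sf.hi"]], "expanding")      # R = 0.8 inclusive
  expect_equal(got[["sf.lo"]], "non_expanding")  # R = 0.2 inclusive
  expect_equal(got[["sf.mid"]], "neither")
  expect_error(classify_superfamilies(
    tibble::tibble(superfamily_id = "x", expansion_r = 1.2)), "\\[-1, 1\\]")
})

test_that("protein partition applies the strict identity cut-off", {
  hits <- tibble::tibble(
    protein_id = c("p50", "p80", "pboth", "pboth", "pnon"),
    domain_id = paste0("d", 1:5),
    superfamily_id = c("sf.exp", "sf.exp", "sf.exp", "sf.non", "sf.non"),
    percent_identity = c(50, 80, 70, 90, 60))
  part <- partition_proteins(hits, classify_superfamilies(sf_table))
  expect_false("p50" %in% part$any_domain)  # 50.0% is not above 50
  expect_setequal(part$expanding, c("p80", "pboth"))
  expect_setequal(part$non_expanding, c("pboth", "pnon"))
  expect_setequal(part$any_domain, c("p80", "pboth", "pnon"))
  # set algebra: classed sets are subsets of any_domain; pboth in both,
  # counted once in any_domain
  expect_true(all(part$expanding %in% part$any_domain))
  expect_true(all(part$non_expanding %in% part$any_domain))
  expect_equal(sum(part$any_domain == "pboth"), 1L)
})

test_that("unknown superfamilies are warned about and treated as neither", {
  hits <- tibble::tibble(protein_id = "p1", domain_id = "d1",
                         superfamily_id = "sf.unknown",
                         percent_identity = 90)
  expect_warning(part <- partition_proteins(
    hits, classify_superfamilies(sf_table)), "unknown superfamilies")
  expect_equal(part$any_domain, "p1")
  expect_length(part$expanding, 0)
})

test_that("raising min_identity never grows any set", {
  set.seed(81)
  hits <- tibble::tibble(
    protein_id = sample(sprintf("p%02d", 1:30), 120, replace = TRUE),
    domain_id = sprintf("d%03d", 1:120),
    superfamily_id = sample(sf_table$superfamily_id, 120, replace = TRUE),
    percent_identity = runif(120, 0, 100))
  cls <- classify_superfamilies(sf_table)
  prev <- partition_proteins(hits, cls, min_identity = 30)
  for (cut in c(50, 70, 90)) {
    cur <- partition_proteins(hits, cls, min_identity = cut)
    expect_true(all(cur$expanding %in% prev$expanding))
    expect_true(all(cur$non_expanding %in% prev$non_expanding))
    expect_true(all(cur$any_domain %in% prev$any_domain))
    prev <- cur
  }
})

test_that("blast-tabular hit tables round through the reader", {
  hit_path <- tempfile(fileext = ".tsv")
  writeLines(c("d1\tp1\t75.5\t100\t5\t0\t1\t100\t1\t100\t1e-30\t200",
               "d2\tp2\t45.0\t80\t9\t1\t1\t80\t21\t100\t1e-10\t90"),
             hit_path)
  map <- tibble::tibble(domain_id = c("d1", "d2"),
                        superfamily_id = c("sf.exp", "sf.non"))
  hits <- read_domain_hits(hit_path, map)
  expect_equal(hits$protein_id, c("p1", "p2"))
  expect_equal(hits$percent_identity, c(75.5, 45.0))
  expect_equal(hits$superfamily_id, c("sf.exp", "sf.non"))
})

test_that("shipped synthetic fixture tables drive the full partition path", {
  ext <- function(f) system.file("extdata", f, package = "proteoscale")
  exp_tbl <- readr::read_tsv(ext("superfamily_expansion_synthetic.tsv"),
                             col_types = "cd")
  cls <- classify_superfamilies(exp_tbl)
  expect_setequal(unique(cls$class),
                  c("expanding", "non_expanding", "neither"))
  hits <- read_domain_hits(ext("domain_hits_synthetic.tsv"),
                           ext("domain_superfamily_map_synthetic.tsv"))
  part <- partition_proteins(hits, cls)
  expect_true(all(part$expanding %in% part$any_domain))
  expect_true(all(part$non_expanding %in% part$any_domain))
  # strict identity cut: every member has at least one hit above 50%
  qual <- hits[hits$percent_identity > 50, ]
  expect_setequal(part$any_domain, unique(qual$protein_id))
})

test_that("group disorder comparison recovers a planted difference", {
  set.seed(91)
  n <- 120
  mk_tracks <- function(ids, frac) {
    setNames(lapply(seq_along(ids), function(i) {
      ifelse(runif(200) < frac, runif(200, 0.55, 1), runif(200, 0, 0.45))
    }), ids)
  }
  exp_ids <- sprintf("e%03d", 1:n); non_ids <- sprintf("n%03d", 1:n)
  tracks <- c(mk_tracks(exp_ids, 0.35), mk_tracks(non_ids, 0.25))
  part <- structure(list(expanding = exp_ids, non_expanding = non_ids,
                         any_domain = c(exp_ids, non_ids)),
                    class = "protein_partition")
  res <- compare_group_disorder(part, tracks)
  ms <- setNames(res$group_summary$mean_disorder, res$group_summary$group)
  expect_gt(ms[["expanding"]], ms[["non_expanding"]])
  expect_lt(res$test$p_two_tailed, 0.05)
  # identical groups: U at its null midpoint
  same <- structure(list(expanding = exp_ids, non_expanding = exp_ids,
                         any_domain = exp_ids), class = "protein_partition")
  res2 <- compare_group_disorder(same, tracks)
  expect_equal(res2$test$U, n * n / 2)
})
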
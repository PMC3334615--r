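# Independent oracles, deliberately written with different structure from the
# package implementations they check.

# Literal reading of the binding-site rule: explicit scan for runs, explicit
# left-to-right merge walking the scores between candidates.
oracle_segment <- function(scores, threshold = 0.5, min_run = 3,
                           min_sep = 3) {
  n <- length(scores)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (scores[i] > threshold) {
      j <- i
      while (j < n && scores[j + 1L] > threshold) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cand <- Filter(function(r) r[2] - r[1] + 1L >= min_run, runs)
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      n_above = integer()))
  }
  merged <- list(cand[[1]])
  for (k in seq_along(cand)[-1]) {
    prev <- merged[[length(merged)]]
    n_below <- 0L
    if (cand[[k]][1] - prev[2] >= 2L) {
      for (p in (prev[2] + 1L):(cand[[k]][1] - 1L)) {
        if (scores[p] < threshold) n_below <- n_below + 1L
      }
    }
    if (n_below < min_sep) {
      merged[[length(merged)]] <- c(prev[1], cand[[k]][2])
    } else {
      merged[[length(merged) + 1L]] <- cand[[k]]
    }
  }
  data.frame(
    start = vapply(merged, function(m) m[1] - 1L, integer(1)),
    end = vapply(merged, function(m) m[2], integer(1)),
    n_above = vapply(merged, function(m) {
      sum(scores[m[1]:m[2]] > threshold)
    }, integer(1)))
}

# compact string form of a site table, for bulk equality checks
site_key <- function(sites) {
  paste(sites$start, sites$end, sites$n_above, sep = ":", collapse = ";")
}

# Exact two-tailed Mann-Whitney p by rank-sum enumeration (rank-sum W rather
# than U; the two statistics are linearly related so tail sets coincide).
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  splits <- combn(n1 + n2, n1)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]))
  e_w <- n1 * (n1 + n2 + 1) / 2
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# small FASTA fixture writer
write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}
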
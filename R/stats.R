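#' Fit a power law y = a * x^k by log-log least squares
#'
#' Ordinary least squares of log10(y) on log10(x); the exponent is the slope,
#' the prefactor is 10^intercept, and r-squared and the two-tailed p-value are
#' those of the linear fit in log space. This is the conventional fitting
#' choice for cross-species scaling relationships; a nonlinear least-squares
#' fit in raw space would weight the largest proteomes disproportionately.
#'
#' @param x,y Positive numeric vectors of equal length, n >= 3.
#' @return Object of class `power_fit`: `exponent`, `prefactor`, `r2`,
#'   `p_value`, `n`.
#' @examples
#' f <- fit_power_law(c(1, 4, 9, 16, 25), 2 * c(1, 4, 9, 16, 25)^0.5)
#' f$exponent  # 0.5
#' @export
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("power-law fit needs n >= 3")
  bad <- which(x <= 0 | y <= 0)
  if (length(bad) > 0) {
    stop("power-law fit requires positive values; offending indices: ",
         paste(head(bad, 5), collapse = ", "))
  }
  lx <- log10(x); ly <- log10(y)
  if (var(ly) == 0) {
    out <- list(exponent = 0, prefactor = y[1], r2 = 0, p_value = 1,
                n = length(x))
    class(out) <- "power_fit"
    return(out)
  }
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" chatter on exact data
  out <- list(exponent = unname(stats::coef(fit)[2]),
              prefactor = 10^unname(stats::coef(fit)[1]),
              r2 = sm$r.squared,
              p_value = unname(sm$coefficients[2, 4]),
              n = length(x))
  class(out) <- "power_fit"
  out
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> y = %.4g * x^%.4g  (r2 = %.4f, p = %.3g, n = %d)\n",
              x$prefactor, x$exponent, x$r2, x$p_value, x$n))
  invisible(x)
}

new_correlation <- function(method, r, p, n, note = NULL) {
  out <- list(method = method, r = unname(r), p_two_tailed = unname(p),
              n = n, note = note)
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s r = %.4f, two-tailed p = %.4g, n = %d%s\n",
              x$method, x$r, x$p_two_tailed, x$n,
              if (is.null(x$note)) "" else paste0(" [", x$note, "]")))
  invisible(x)
}

#' Pearson product-moment correlation with two-tailed p-value
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance. The p-value comes from the t distribution with n - 2 degrees
#'   of freedom (via [stats::cor.test()]).
#' @return Object of class `correlation_result`.
#' @export
cor_pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("correlation needs n >= 3")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  new_correlation("pearson", ct$estimate, ct$p.value, length(x))
}

#' Spearman rank correlation with two-tailed p-value
#'
#' The coefficient is exactly the Pearson correlation of the average ranks
#' (ties receive mean ranks). For n > 8 the p-value uses the t approximation
#' with n - 2 degrees of freedom, the convention of most desktop statistics
#' software; the result is flagged `"approximate"` for n < 10. For n <= 8 an
#' exact permutation p-value is computed by full enumeration of all n!
#' orderings instead.
#'
#' @inheritParams cor_pearson
#' @return Object of class `correlation_result`.
#' @export
cor_spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("correlation needs n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) stop("zero rank variance in input")
  r <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations_of(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # null distribution: cor(rx[perm], ry) over every ordering
    r_null <- (matrix(rxc[perms], nrow = nrow(perms)) %*% ryc)[, 1] / denom
    p <- mean(abs(r_null) >= abs(r) - 1e-12)
    return(new_correlation("spearman", r, p, n, note = "exact permutation"))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  if (is.nan(p)) p <- 0  # |r| = 1
  new_correlation("spearman", r, min(p, 1), n,
                  note = if (n < 10) "approximate" else NULL)
}

# all permutations of ry as a matrix of permuted values (rows = permutations)
permutations_of <- function(n) {
  perm_idx <- function(n) {
    if (n == 1) return(matrix(1L))
    sub <- perm_idx(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, matrix(c(seq_len(n))[-i][sub], nrow = nrow(sub)))
    }))
  }
  perm_idx(n)
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' Classical one-way fixed-effects ANOVA across k groups, followed by all
#' pairwise two-sample pooled-variance t-tests whose two-tailed p-values are
#' multiplied by the number of pairs (Bonferroni) and clipped at 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; at least 2 groups,
#'   each with n >= 2.
#' @return List of class `anova_result`: `f_stat`, `p_value`, `group_means`
#'   (named), `pairwise_p_bonferroni` (named by `"a vs b"`), `n_groups`.
#' @export
one_way_anova_bonferroni <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("every group needs n >= 2 (too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  }
  g <- factor(groups)
  fit <- aov(values ~ g)
  tab <- anova(fit)
  pairs <- combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  pw <- apply(pairs, 2, function(pr) {
    tt <- t.test(values[groups == pr[1]], values[groups == pr[2]],
                 var.equal = TRUE)
    min(1, tt$p.value * n_pairs)
  })
  names(pw) <- apply(pairs, 2, paste, collapse = " vs ")
  out <- list(f_stat = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
              group_means = tapply(values, groups, mean),
              pairwise_p_bonferroni = pw, n_groups = length(sizes))
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova> F = %.4g, p = %.4g over %d groups\n",
              x$f_stat, x$p_value, x$n_groups))
  invisible(x)
}

#' Mann-Whitney U test (two-tailed)
#'
#' U is computed for the first sample: the number of (a, b) pairs with
#' a > b, counting ties as 1/2. For small samples (n1 + n2 <= 12) the
#' two-tailed p-value is exact, by enumeration of all choose(n1 + n2, n1)
#' assignments of the pooled values (ties handled naturally by the
#' enumeration); extremeness is measured as distance of U from its null mean
#' n1*n2/2. For larger samples the tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `U`, `p_two_tailed`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1, !anyNA(a), !anyNA(b))
  n1 <- length(a); n2 <- length(b)
  u_stat <- function(ai, bi) {
    sum(vapply(ai, function(v) sum(v > bi) + 0.5 * sum(v == bi), numeric(1)))
  }
  U <- u_stat(a, b)
  if (n1 + n2 <= 12) {
    pooled <- c(a, b)
    idx <- combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    u_all <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    r <- rank(c(a, b))
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma2 <- n1 * n2 / 12 * (nt + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all values tied
    } else {
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_two_tailed = p, n1 = n1, n2 = n2, method = method)
}

#' Standard deviation of a statistic over random subsamples
#'
#' Repeatedly draws subsets of size `subset_size` without replacement,
#' computes the chosen statistic on each, and reports the mean and standard
#' deviation of the repeated statistic. This is the resampling procedure used
#' to attach an SD to proteome-level medians/means when the underlying
#' per-protein values are available.
#'
#' @param values Numeric population.
#' @param subset_size Size of each subsample (<= length of `values`).
#' @param n_repeats Number of subsamples (>= 2).
#' @param statistic `"mean"` or `"median"`.
#' @param seed Optional integer seed; when supplied, results are reproducible
#'   and the caller's RNG state is left untouched.
#' @return List of class `subsample_sd`: `mean_of_stats`, `sd_of_stats`,
#'   `subset_size`, `n_repeats`, `statistic`, `seed`.
#' @export
subsample_sd <- function(values, subset_size, n_repeats = 1000,
                         statistic = c("mean", "median"), seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_repeats >= 2)
  if (subset_size > length(values)) {
    stop("subset_size (", subset_size, ") exceeds population size (",
         length(values), ")")
  }
  fn <- if (statistic == "mean") mean else median
  draw <- function() {
    vapply(seq_len(n_repeats),
           function(i) fn(values[sample.int(length(values), subset_size)]),
           numeric(1))
  }
  stats_vec <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- list(mean_of_stats = mean(stats_vec), sd_of_stats = sd(stats_vec),
              subset_size = subset_size, n_repeats = n_repeats,
              statistic = statistic, seed = seed)
  class(out) <- "subsample_sd"
  out
}

#' @export
print.subsample_sd <- function(x, ...) {
  cat(sprintf("<subsample_sd> %s over %d draws of %d: %.4g (sd %.4g)\n",
              x$statistic, x$n_repeats, x$subset_size,
              x$mean_of_stats, x$sd_of_stats))
  invisible(x)
}
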
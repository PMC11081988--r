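# Nonparametric statistics engine. All tests are rank-based with midranks
# for ties, carry an exact-enumeration branch for small samples (verifiable
# against brute-force oracles) and a tie-corrected normal/chi-square
# approximation otherwise. Two-sided p-values throughout.

#' Significance codes for (adjusted) p-values
#'
#' Maps p-values to the study's significance scheme:
#' `ns` > 0.05, `*` < 0.05, `**` < 0.01, `***` < 0.001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes (`NA` preserved).
#' @export
significance_code <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01, "**",
             ifelse(p[ok] < 0.05, "*", "ns")))
  out
}

# exact null distribution of 2*W+ over all 2^n sign patterns, via
# shift-convolution on doubled (integer) midranks; counts are exact in
# double precision for n <= 25
.pm_signrank_counts <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests whether paired differences `x - y` are symmetric about zero. Zero
#' differences are discarded (classic Wilcoxon convention; switch to
#' `zero_method = "pratt"` to keep them in the ranking), absolute
#' differences are ranked with midranks for ties, and the statistic is
#' `W = min(W+, W-)`. The two-sided p-value is exact (full enumeration of
#' all sign patterns) when the number of nonzero differences is at most
#' `exact_max_n`, otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param exact_max_n Largest n for the exact branch (default 25).
#' @param zero_method `"discard"` (default) or `"pratt"`.
#' @param correct Apply continuity correction in the normal branch.
#' @return List with `statistic` (W), `w_plus`, `w_minus`, `n_used`,
#'   `p_value`, `method` and `degenerate`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 5, 9), c(1, 1, 1, 1))
wilcoxon_signed_rank <- function(x, y, exact_max_n = 25L,
                                 zero_method = c("discard", "pratt"),
                                 correct = TRUE) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- complete.cases(x, y)
  d <- x[keep] - y[keep]
  if (length(d) < 1L) stop("no complete pairs", call. = FALSE)
  if (zero_method == "discard") d <- d[d != 0]
  n <- length(d)
  if (n == 0L || all(d == 0)) {
    return(list(statistic = 0, w_plus = 0, w_minus = 0, n_used = n,
                p_value = 1, method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  if (zero_method == "pratt") {
    nz <- d != 0
    w_plus <- sum(r[nz & d > 0])
    w_minus <- sum(r[nz & d < 0])
    r <- r[nz]
  } else {
    w_plus <- sum(r[d > 0])
    w_minus <- sum(r[d < 0])
  }
  w <- min(w_plus, w_minus)
  if (length(r) <= exact_max_n) {
    ranks2 <- as.integer(round(2 * r))
    counts <- .pm_signrank_counts(ranks2)
    total2 <- sum(ranks2)
    w2 <- as.integer(round(2 * w))
    lo <- sum(counts[seq_len(w2 + 1L)])
    hi <- sum(counts[(total2 - w2 + 1L):(total2 + 1L)])
    p <- min(1, (lo + hi) / 2^length(r))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    if (sigma == 0) {
      return(list(statistic = w, w_plus = w_plus, w_minus = w_minus,
                  n_used = n, p_value = 1, method = "degenerate",
                  degenerate = TRUE))
    }
    dev <- w_plus - mu
    cc <- if (correct) 0.5 * sign(dev) else 0
    z <- (dev - cc) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, w_plus = w_plus, w_minus = w_minus, n_used = n,
       p_value = p, method = method, degenerate = FALSE)
}

#' Mann-Whitney (Wilcoxon rank-sum) test for two independent groups
#'
#' Two-sided test based on `U = min(U_a, U_b)` with midranks for ties. The
#' p-value is exact (enumeration of all group assignments of the pooled
#' values) when `length(a) + length(b) <= exact_max_n`, otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_max_n Largest pooled n for the exact branch (default 12).
#' @param correct Apply continuity correction in the normal branch.
#' @return List with `statistic` (U), `u_a`, `u_b`, `n_used`, `p_value`,
#'   `method`, `degenerate` and `direction` (sign of median(a) - median(b)).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney <- function(a, b, exact_max_n = 12L, correct = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  u <- min(u_a, u_b)
  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    return(list(statistic = u, u_a = u_a, u_b = u_b, n_used = N,
                p_value = 1, method = "degenerate", degenerate = TRUE,
                direction = 0))
  }
  if (N <= exact_max_n) {
    idx <- combn(N, na)
    rank_sums <- colSums(matrix(r[idx], nrow = na))
    u_perm <- rank_sums - na * (na + 1) / 2
    eps <- 1e-9
    p <- (sum(u_perm <= u + eps) + sum(u_perm >= na * nb - u - eps)) /
      ncol(idx)
    p <- min(1, p)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      return(list(statistic = u, u_a = u_a, u_b = u_b, n_used = N,
                  p_value = 1, method = "degenerate", degenerate = TRUE,
                  direction = 0))
    }
    dev <- u_a - na * nb / 2
    cc <- if (correct) 0.5 * sign(dev) else 0
    z <- (dev - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = u, u_a = u_a, u_b = u_b, n_used = N, p_value = p,
       method = method, degenerate = FALSE,
       direction = sign(median(a) - median(b)))
}

# all distinct assignments of N pooled ranks into groups of the given sizes;
# calls `fun(list_of_rank_vectors)` for each and returns the results
.pm_enumerate_partitions <- function(r, sizes, fun) {
  out <- numeric(0)
  recurse <- function(remaining_idx, k, acc) {
    if (k > length(sizes)) {
      out[[length(out) + 1L]] <<- fun(acc)
      return(invisible())
    }
    if (k == length(sizes)) {
      recurse(integer(0), k + 1L, c(acc, list(r[remaining_idx])))
      return(invisible())
    }
    picks <- combn(length(remaining_idx), sizes[k])
    for (j in seq_len(ncol(picks))) {
      sel <- remaining_idx[picks[, j]]
      recurse(setdiff(remaining_idx, sel), k + 1L, c(acc, list(r[sel])))
    }
    invisible()
  }
  recurse(seq_along(r), 1L, list())
  unlist(out)
}

# Kruskal-Wallis H for a list of rank vectors (ranks over the pooled sample)
.pm_kw_h <- function(rank_groups, N, tie_corr) {
  rbar <- vapply(rank_groups, mean, numeric(1))
  ni <- lengths(rank_groups)
  h <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  h / tie_corr
}

#' Kruskal-Wallis rank test for several independent groups
#'
#' Tie-corrected H statistic referred to the chi-square distribution with
#' k - 1 degrees of freedom, or to the exact permutation distribution
#' (enumeration of all distinct group assignments) when `exact = TRUE`.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @param exact Use the exact permutation distribution (intended for small
#'   pooled n; the enumeration grows multinomially).
#' @return List with `statistic` (H), `df`, `n_used`, `p_value`, `method`
#'   and `degenerate`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
kruskal_wallis <- function(groups, exact = FALSE) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  k <- length(groups)
  tie_tab <- table(pooled)
  tie_corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (tie_corr <= 0) {
    return(list(statistic = 0, df = k - 1L, n_used = N, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(pooled)
  idx <- split(seq_len(N), rep(seq_len(k), lengths(groups)))
  h <- .pm_kw_h(lapply(idx, function(i) r[i]), N, tie_corr)
  if (exact) {
    h_perm <- .pm_enumerate_partitions(
      r, lengths(groups),
      function(gs) .pm_kw_h(gs, N, tie_corr)
    )
    p <- mean(h_perm >= h - 1e-9)
    method <- "exact"
  } else {
    p <- pchisq(h, df = k - 1, lower.tail = FALSE)
    method <- "chisq"
  }
  list(statistic = h, df = k - 1L, n_used = N, p_value = p, method = method,
       degenerate = FALSE)
}

#' Dunn's post-hoc test for all pairwise group comparisons
#'
#' Rank-based z statistics on the pooled Kruskal-Wallis ranks with tie
#' correction, for every pair of groups:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3-t)/(12(N-1))) *
#' (1/n_i + 1/n_j))`, two-sided normal p-values, optionally Holm-adjusted
#' across the pairs.
#'
#' @param groups Named (or unnamed) list of two or more non-empty numeric
#'   vectors.
#' @param p_adjust `"holm"` (default) or `"none"`.
#' @return A tibble with one row per pair: `group_i`, `group_j`, `z`,
#'   `p_raw`, `p_adj`.
#' @export
dunns_test <- function(groups, p_adjust = c("holm", "none")) {
  p_adjust <- match.arg(p_adjust)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- split(seq_len(N), rep(seq_along(groups), lengths(groups)))
  rbar <- vapply(idx, function(i) mean(r[i]), numeric(1))
  ni <- lengths(groups)
  tie_tab <- table(pooled)
  s2 <- N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- combn(length(groups), 2L)
  z <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1L, m]; j <- pairs[2L, m]
    se <- sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
    z[m] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
  }
  p_raw <- pmin(1, 2 * pnorm(-abs(z)))
  p_adj <- if (p_adjust == "holm") holm_adjust(p_raw) else p_raw
  tibble(
    group_i = labels[pairs[1L, ]],
    group_j = labels[pairs[2L, ]],
    z = z,
    p_raw = p_raw,
    p_adj = p_adj
  )
}

#' Holm step-down adjustment for multiple testing
#'
#' Thin validated wrapper around `stats::p.adjust(method = "holm")`,
#' controlling the family-wise error rate. (The source study labels this an
#' FDR correction; Holm in fact controls FWER and is implemented as named.)
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03, 0.06, 0.06
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "holm")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Equal-length numeric vectors, n >= 3 after removing
#'   incomplete pairs.
#' @return List with `rho`, `rho_sq`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_rank(1:5, c(2, 1, 4, 3, 5))  # rho = 0.8
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("degenerate input: zero rank variance", call. = FALSE)
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, rho_sq = rho^2, p_value = p, n = n)
}

#' Distribution-free confidence interval for the median
#'
#' Order-statistic interval from the binomial(n, 1/2) distribution: the
#' endpoints are observed values chosen so that the coverage is at least
#' `level`. For n < 6 a proper two-sided 95% interval does not exist and the
#' interval degenerates to the sample range (flagged).
#'
#' @param values Numeric vector.
#' @param level Confidence level (default 0.95).
#' @return List with `median`, `ci_low`, `ci_high`, `level`, `degenerate`.
#' @export
median_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("no data", call. = FALSE)
  s <- sort(values)
  med <- median(values)
  alpha <- 1 - level
  l <- qbinom(alpha / 2, n, 0.5)
  if (n < 6L || l < 1L) {
    return(list(median = med, ci_low = s[1L], ci_high = s[n],
                level = level, degenerate = TRUE))
  }
  u <- n + 1L - l
  list(median = med, ci_low = s[l], ci_high = s[u], level = level,
       degenerate = FALSE)
}
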
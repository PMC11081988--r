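# Brute-force oracles, independent of the package's computation paths.

# two-sided exact signed-rank p by enumerating all 2^n sign patterns
oracle_signrank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  total <- sum(r)
  w_obs <- min(w_plus, total - w_plus)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  min(1, (sum(w_all <= w_obs + 1e-9) +
            sum(w_all >= total - w_obs - 1e-9)) / length(w_all))
}

# all permutations of 1..n (n <= 8)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# two-sided exact Mann-Whitney p by full permutation of the pooled sample
oracle_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  stopifnot(N <= 8)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx_a) sum(r[idx_a]) - na * (na + 1) / 2
  u_a <- u_of(seq_len(na))
  u_obs <- min(u_a, na * nb - u_a)
  perms <- oracle_perms(N)
  u_all <- apply(perms, 1L, function(p) u_of(p[seq_len(na)]))
  min(1, (sum(u_all <= u_obs + 1e-9) +
            sum(u_all >= na * nb - u_obs - 1e-9)) / length(u_all))
}

# tie-corrected Kruskal-Wallis H computed straight from the formula
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- split(seq_len(N), rep(seq_along(groups), lengths(groups)))
  rbar <- vapply(idx, function(i) mean(r[i]), numeric(1))
  ni <- lengths(groups)
  h <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  tie <- table(pooled)
  h / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# exact Kruskal-Wallis p by full permutation of the pooled sample
oracle_kw_p <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  stopifnot(N <= 8)
  sizes <- lengths(groups)
  h_obs <- oracle_kw_h(groups)
  perms <- oracle_perms(N)
  grp <- rep(seq_along(sizes), sizes)
  h_all <- apply(perms, 1L, function(p) {
    oracle_kw_h(split(pooled[p], grp))
  })
  mean(h_all >= h_obs - 1e-9)
}

# Dunn z for one pair, straight from the formula
oracle_dunn_z <- function(groups, i, j) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- split(seq_len(N), rep(seq_along(groups), lengths(groups)))
  rbar <- vapply(idx, function(ii) mean(r[ii]), numeric(1))
  tie <- table(pooled)
  s2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  unname((rbar[i] - rbar[j]) /
           sqrt(s2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]]))))
}
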
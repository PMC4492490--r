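# Independent oracles and small fixture builders shared across tests.

# literal double-loop version of the covariate-set score statistic:
# S = sum_j (x_j' ytilde)^2 / (m * sigma2hat), columns centred/scaled
oracle_global_stat <- function(y, X, scale = TRUE) {
  n <- length(y)
  m <- ncol(X)
  yt <- y - mean(y)
  sig2 <- sum(yt^2) / n
  total <- 0
  for (j in seq_len(m)) {
    x <- X[, j] - mean(X[, j])
    if (scale && sd(x) > 0) x <- x / sd(x)
    dot <- 0
    for (i in seq_len(n)) dot <- dot + x[i] * yt[i]
    total <- total + dot^2
  }
  total / (m * sig2)
}

# literal min-over-tail BH definition: q_(i) = min_{j >= i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# exact two-sided Mann-Whitney p by enumerating all C(nA+nB, nA) group
# assignments of the pooled (untied) values
oracle_mw_p <- function(a, b) {
  pool <- c(a, b)
  nA <- length(a)
  ranks <- rank(pool)
  u_of <- function(idx) sum(ranks[idx]) - nA * (nA + 1) / 2
  u_obs <- u_of(seq_len(nA))
  mu <- nA * length(b) / 2
  combos <- utils::combn(length(pool), nA)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exhaustive n! permutation p for the global test (independent of the
# package's enumeration path)
oracle_exhaustive_p <- function(y, X, scale = TRUE) {
  perms <- all_perms(length(y))
  s_obs <- oracle_global_stat(y, X, scale = scale)
  s_all <- apply(perms, 1, function(ix) oracle_global_stat(y[ix], X, scale = scale))
  mean(s_all >= s_obs - 1e-9 * max(1, s_obs))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# --- tiny fixtures -------------------------------------------------------

toy_genome <- function() c(chrA = 10e6, chrB = 5e6)

toy_segments_file <- function(path, df) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_expr_file <- function(path, mat) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small cohort settings used where full 125-sample runs are not needed
fast_scenario <- function(seed, ...) {
  scenario_config(n_samples = 60L, n_genes = 400L, seed = seed, ...)
}

fast_config <- function(seed, ...) {
  analysis_config(permutations = 999L, seed = seed, ...)
}
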
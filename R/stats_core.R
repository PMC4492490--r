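# Covariate-set score test (global test), BH-FDR, Mann-Whitney and
# association signs. The global test asks whether a *set* of covariates
# (copy-number window positions, or consensus target genes) is jointly
# associated with one response (a miRNA's expression), returning a single
# p-value per response.

# run `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  code <- substitute(code)
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  eval(code, envir = parent.frame())
}

# all n! permutations of v, one per row (recursion depth n <= ~8)
permutations_all <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  blocks <- lapply(seq_len(n), function(k) cbind(v[k], permutations_all(v[-k])))
  do.call(rbind, blocks)
}

# center (and optionally unit-variance scale) covariate columns
prepare_covariates <- function(X, scale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("covariates must be finite")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  if (scale) {
    sds <- apply(Xc, 2L, stats::sd)
    keep <- sds > 0
    Xc[, keep] <- sweep(Xc[, keep, drop = FALSE], 2L, sds[keep], "/")
  }
  Xc
}

check_gt_inputs <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (length(y) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(y))) stop("response must be finite")
  if (nrow(X) != length(y)) stop("covariate rows must match response length")
  if (ncol(X) < 1L) stop("need at least one covariate")
  if (stats::sd(y) == 0) stop("degenerate response: y is constant")
  y
}

#' Global-test score statistic
#'
#' Computes the covariate-set score statistic
#' \deqn{S = \tilde y^\top X X^\top \tilde y / (m \hat\sigma^2)}
#' with \eqn{\tilde y = y - \bar y}, \eqn{\hat\sigma^2 = \tilde y^\top
#' \tilde y / n}, and covariate columns centred (and, by default, scaled to
#' unit variance so each contributes comparably). The statistic is
#' invariant to adding a constant to `y` and to the column order of `X`.
#'
#' @param y Numeric response vector (one miRNA's expression), length n >= 3,
#'   not constant.
#' @param X Numeric n x m covariate matrix (m >= 1).
#' @param scale Scale covariate columns to unit variance (default TRUE).
#' @return The nonnegative statistic. All-constant covariates give 0 with a
#'   warning.
#' @export
global_test_statistic <- function(y, X, scale = TRUE) {
  y <- check_gt_inputs(y, X)
  Xc <- prepare_covariates(X, scale = scale)
  if (all(Xc == 0)) {
    warning("all covariates constant; statistic is 0")
    return(0)
  }
  yt <- y - mean(y)
  sig2 <- sum(yt^2) / length(y)
  sum(crossprod(Xc, yt)^2) / (ncol(Xc) * sig2)
}

#' Global test with permutation, exact-enumeration or asymptotic null
#'
#' The permutation null permutes the entries of `y` with a seeded
#' generator: \eqn{p = (1 + \#\{S_{perm} \ge S_{obs}\})/(B+1)}. When
#' \eqn{n! \le} `exact_cap` (default 5040, n <= 7) all n! permutations are
#' enumerated instead and the p-value is the exact tail fraction. The
#' asymptotic option fits a moment-matched (Satterthwaite) scaled
#' chi-square to the eigenvalues of the centred covariate kernel; it is
#' provided for speed, the permutation null remains the reference.
#'
#' @inheritParams global_test_statistic
#' @param B Number of Monte-Carlo permutations (>= 99).
#' @param seed Integer seed for the permutation draw; NULL uses the current
#'   RNG state.
#' @param method `"auto"` (exact enumeration when feasible, else Monte
#'   Carlo), `"permutation"`, `"exact"`, or `"asymptotic"`.
#' @param exact_cap Largest n! enumerated exhaustively under `"auto"`.
#' @return A list of class `global_test_result`: `statistic`, `p_value`,
#'   `method` (one of permutation / exact_enumeration / asymptotic),
#'   `n_permutations` (NA for exact/asymptotic).
#' @export
global_test <- function(y, X, B = 9999L, seed = NULL,
                        method = c("auto", "permutation", "exact", "asymptotic"),
                        scale = TRUE, exact_cap = 5040L) {
  method <- match.arg(method)
  y <- check_gt_inputs(y, X)
  n <- length(y)
  if (B < 99L) stop("B must be >= 99")
  Xc <- prepare_covariates(X, scale = scale)
  yt <- y - mean(y)
  sig2 <- sum(yt^2) / n
  m <- ncol(Xc)
  if (all(Xc == 0)) {
    warning("all covariates constant; statistic is 0, p = 1")
    return(structure(list(statistic = 0, p_value = 1, method = "degenerate",
                          n_permutations = NA_integer_),
                     class = "global_test_result"))
  }
  s_obs <- sum(crossprod(Xc, yt)^2) / (m * sig2)
  tol <- 1e-12 * max(1, s_obs)

  if (method == "auto")
    method <- if (factorial(n) <= exact_cap) "exact" else "permutation"

  if (method == "asymptotic") {
    lam <- eigen(tcrossprod(Xc) / m, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-12 * max(lam)]
    a <- sum(lam^2) / sum(lam)
    nu <- sum(lam)^2 / sum(lam^2)
    # sigma-hat uses /n; rescale so the null mean matches sum(lam)
    p <- stats::pchisq(s_obs * (n - 1) / n / a, df = nu, lower.tail = FALSE)
    return(structure(list(statistic = s_obs, p_value = max(p, .Machine$double.xmin),
                          method = "asymptotic", n_permutations = NA_integer_),
                     class = "global_test_result"))
  }

  if (method == "exact") {
    perm <- permutations_all(seq_len(n))
    Yp <- matrix(yt[perm], nrow = nrow(perm))
    s_perm <- rowSums((Yp %*% Xc)^2) / (m * sig2)
    p <- mean(s_perm >= s_obs - tol)
    return(structure(list(statistic = s_obs, p_value = p,
                          method = "exact_enumeration", n_permutations = NA_integer_),
                     class = "global_test_result"))
  }

  idx <- with_seed(seed, {
    vapply(seq_len(B), function(i) sample.int(n), integer(n))
  })
  Yp <- matrix(yt[idx], nrow = n)                       # n x B
  s_perm <- rowSums((t(Yp) %*% Xc)^2) / (m * sig2)
  p <- (1 + sum(s_perm >= s_obs - tol)) / (B + 1)
  structure(list(statistic = s_obs, p_value = p, method = "permutation",
                 n_permutations = as.integer(B)),
            class = "global_test_result")
}

#' @export
print.global_test_result <- function(x, ...) {
  cat(sprintf("global test: S = %.4g, p = %.4g (%s%s)\n", x$statistic, x$p_value,
              x$method,
              if (!is.na(x$n_permutations)) paste0(", B = ", x$n_permutations) else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjustment, returned in the input order:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, clipped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (no NA).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. The null distribution is
#' enumerated exactly when nA + nB <= 12 and the data carry no ties;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return List with `U` (statistic for group `a`), `p` (two-sided),
#'   `method`, and group sizes `nA`, `nB`.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("group values must be finite")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact_enumeration" else "normal_approximation",
       nA = length(a), nB = length(b))
}

#' Sign of a miRNA-target association
#'
#' Sign of the Pearson correlation between a miRNA's expression and a
#' single target's expression. A correlation of exactly zero is reported
#' as positive by convention (with a message).
#'
#' @param y miRNA expression vector (length >= 3, non-constant).
#' @param t Target expression vector (same length, non-constant).
#' @return `"positive"` or `"negative"`.
#' @export
association_sign <- function(y, t) {
  y <- as.numeric(y); t <- as.numeric(t)
  if (length(y) != length(t) || length(y) < 3L) stop("vectors must share length >= 3")
  if (stats::sd(y) == 0 || stats::sd(t) == 0) stop("constant vector")
  r <- stats::cor(y, t)
  if (r == 0) message("zero correlation; sign reported positive by convention")
  if (r < 0) "negative" else "positive"
}
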
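#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall rank correlation: `tau_b = S / sqrt((n0 - n1)
#' (n0 - n2))` where `S` is the concordant-minus-discordant pair count,
#' `n0 = n (n - 1) / 2` and `n1`, `n2` are the tie corrections of `x` and
#' `y`. The two-sided p-value uses the normal approximation of `S` with
#' tie-corrected variance. Pairs with a missing value in either vector are
#' deleted. Rank statistics are invariant under strictly increasing
#' transforms (log, square root), so rates may be supplied on any
#' monotone scale.
#'
#' @param x,y Numeric vectors of equal length (`n >= 2` after deletion).
#' @return A `cor_result` with `estimate` (tau), `statistic` (z),
#'   `p_value`, `n` and a `note` flag (e.g. `"zero_variance"`).
#' @examples
#' kendall_tau_b(c(1, 2, 2, 3), c(1, 2, 3, 3))$estimate # 0.8
#' @export
kendall_tau_b <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 2) stop("kendall_tau_b needs >= 2 complete pairs")
  n0 <- n * (n - 1) / 2
  # tie groups by exact value (table() would coerce doubles to strings)
  tx <- tabulate(match(x, x)); tx <- tx[tx > 0]
  ty <- tabulate(match(y, y)); ty <- ty[ty > 0]
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  note <- character(0)
  if (n1 == n0 || n2 == n0) {
    return(new_cor_result(NA_real_, NA_real_, NA_real_, n,
                          method = "Kendall tau-b",
                          note = "zero_variance"))
  }
  S <- concordance_s(x, y)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  # tie-corrected null variance of S (the classical Kendall formula)
  tvec <- tx; uvec <- ty
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tvec * (tvec - 1) * (2 * tvec + 5))
  vu <- sum(uvec * (uvec - 1) * (2 * uvec + 5))
  v1 <- sum(tvec * (tvec - 1)) * sum(uvec * (uvec - 1)) /
    (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tvec * (tvec - 1) * (tvec - 2)) *
      sum(uvec * (uvec - 1) * (uvec - 2)) / (9 * n * (n - 1) * (n - 2))
  } else 0
  vS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (vS > 0) S / sqrt(vS) else NA_real_
  p <- if (n >= 3 && is.finite(z)) 2 * stats::pnorm(-abs(z)) else NA_real_
  new_cor_result(tau, z, p, n, method = "Kendall tau-b", note = note)
}

# S = sum over pairs i<j of sign(x_i - x_j) * sign(y_i - y_j),
# computed in row blocks to bound memory at large n.
concordance_s <- function(x, y, block = 512L) {
  n <- length(x)
  total <- 0
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    dx <- sign(outer(x[i0:i1], x, "-"))
    dy <- sign(outer(y[i0:i1], y, "-"))
    total <- total + sum(dx * dy)
  }
  total / 2   # each unordered pair counted twice
}

new_cor_result <- function(estimate, statistic, p_value, n,
                           method, note = character(0),
                           conditioned_on = character(0)) {
  structure(list(estimate = estimate, statistic = statistic,
                 p_value = p_value, n = n, method = method,
                 note = note, conditioned_on = conditioned_on),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(x$method, ": tau = ", signif(x$estimate, 4),
      ", p = ", signif(x$p_value, 4), ", n = ", x$n, "\n", sep = "")
  if (length(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation/test result
#' @param x A `cor_result`.
#' @param ... Unused.
#' @method tidy cor_result
#' @export
tidy.cor_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$statistic,
                 p_value = x$p_value, n = x$n, method = x$method,
                 note = if (length(x$note)) x$note else NA_character_)
}

#' Partial Kendall correlation matrix
#'
#' Computes the pairwise Kendall tau-b matrix `T` over the numeric
#' columns, then partials each pair on all remaining variables through the
#' inverse-matrix route: with `O = solve(T)`, `partial_ij = -O_ij /
#' sqrt(O_ii O_jj)`. Two-sided p-values use `z = partial *
#' sqrt(9 m (m - 1) / (2 (2 m + 5)))` with `m = n - (k - 2)` effective
#' observations. Rows with any missing value are deleted listwise.
#'
#' @param data Data frame of `k >= 3` numeric columns.
#' @param vars Optional column subset.
#' @return A `partial_kendall` object with `tau`, `partial` and `p`
#'   matrices; see [tidy.partial_kendall()].
#' @export
partial_kendall <- function(data, vars = NULL) {
  d <- tibble::as_tibble(data)
  if (!is.null(vars)) d <- d[vars]
  d <- d[vapply(d, is.numeric, logical(1))]
  k <- ncol(d)
  if (k < 3) stop("partial_kendall needs >= 3 variables")
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n <= k) stop("needs more complete rows than variables (n = ", n, ")")
  vn <- names(d)
  T <- diag(1, k); dimnames(T) <- list(vn, vn)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    T[i, j] <- T[j, i] <- kendall_tau_b(d[[i]], d[[j]])$estimate
  }
  if (anyNA(T)) {
    bad <- which(is.na(T), arr.ind = TRUE)[1, ]
    stop("zero-variance pair: ", vn[bad[1]], " ~ ", vn[bad[2]])
  }
  O <- tryCatch(solve(T), error = function(e) NULL)
  if (is.null(O) || !all(is.finite(O))) {
    off <- abs(T); diag(off) <- 0
    bad <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("collinear variables (singular tau matrix), strongest pair: ",
         vn[bad[1]], " ~ ", vn[bad[2]])
  }
  P <- -O / sqrt(diag(O) %o% diag(O))
  diag(P) <- 1
  m <- n - (k - 2)
  z <- P * sqrt(9 * m * (m - 1) / (2 * (2 * m + 5)))
  pv <- 2 * stats::pnorm(-abs(z))
  diag(pv) <- NA
  structure(list(tau = T, partial = P, p = pv, n = n, vars = vn),
            class = "partial_kendall")
}

#' @export
print.partial_kendall <- function(x, ...) {
  cat("Partial Kendall correlations (n =", x$n, ")\n")
  print(round(x$partial, 3))
  invisible(x)
}

#' Tidy a partial Kendall matrix into long form
#'
#' @param x A `partial_kendall` object.
#' @param correction Multiplicity correction for the p column
#'   (`"holm"`, `"bh"` or `"none"`).
#' @param ... Unused.
#' @return Long tibble: `var1`, `var2`, `tau`, `partial`, `p_value`,
#'   `p_adjusted`, `n`, `conditioned_on`.
#' @method tidy partial_kendall
#' @export
tidy.partial_kendall <- function(x, correction = "holm", ...) {
  k <- length(x$vars)
  idx <- which(upper.tri(x$partial), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = x$vars[idx[, 1]], var2 = x$vars[idx[, 2]],
    tau = x$tau[idx], partial = x$partial[idx], p_value = x$p[idx],
    n = x$n,
    conditioned_on = vapply(seq_len(nrow(idx)), function(i) {
      paste(setdiff(x$vars, x$vars[idx[i, ]]), collapse = ",")
    }, character(1)))
  out$p_adjusted <- holm_adjust(out$p_value, method = correction)
  out
}

#' Glance at a partial Kendall matrix
#' @param x A `partial_kendall` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `k`, `n_pairs`, `min_p`.
#' @method glance partial_kendall
#' @export
glance.partial_kendall <- function(x, ...) {
  k <- length(x$vars)
  tibble::tibble(n = x$n, k = k, n_pairs = k * (k - 1) / 2,
                 min_p = min(x$p, na.rm = TRUE))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Unpaired two-sample rank-sum test with midranks for ties. The p-value
#' is exact (full enumeration of group labelings, valid under ties) when
#' `n_a + n_b <= exact_max`, otherwise a normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Total sample size up to which the exact permutation
#'   distribution is enumerated (default 12).
#' @param correction Multiplicity correction recorded on the result
#'   (applied by callers testing several groups; for a single test the
#'   adjusted p equals the raw p).
#' @return A `rank_test` list: `statistic` (U for sample `a`), `p_value`,
#'   `p_adjusted`, `n_a`, `n_b`, `exact`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12,
                              correction = c("none", "holm", "bh")) {
  correction <- match.arg(correction)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[1:na]) - na * (na + 1) / 2
  if (n <= exact_max) {
    combs <- utils::combn(n, na)
    us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    exact <- TRUE
  } else {
    mu <- na * nb / 2
    ties <- tabulate(match(r, r)); ties <- ties[ties > 0]
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  structure(list(statistic = u, p_value = p,
                 p_adjusted = holm_adjust(p, method = correction),
                 n_a = na, n_b = nb, exact = exact,
                 method = "Wilcoxon rank-sum"),
            class = "rank_test")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric samples with `n >= 2` each and non-degenerate
#'   variance in at least one sample.
#' @return A `rank_test`-style list: `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("welch_t needs n >= 2 per sample")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance")
  }
  ht <- stats::t.test(a, b)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, n_a = length(a), n_b = length(b),
                 method = "Welch two-sample t"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a rank test
#' @param x A `rank_test`.
#' @param ... Unused.
#' @method tidy rank_test
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method)
}

#' Multiplicity adjustment of p-values
#'
#' Step-down Holm by default; Benjamini-Hochberg (`"bh"`) and `"none"`
#' are available.
#'
#' @param p Numeric p-values in [0, 1] (`NA` allowed).
#' @param method `"holm"`, `"bh"` or `"none"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' holm_adjust(c(0.01, 0.04)) # 0.02 0.04
#' @export
holm_adjust <- function(p, method = c("holm", "bh", "none")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  switch(method,
         holm = stats::p.adjust(p, method = "holm"),
         bh = stats::p.adjust(p, method = "BH"),
         none = p)
}
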
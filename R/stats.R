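new_assoc <- function(statistic, p_value, method, n, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(statistic = statistic, p_value = min(p_value, 1), method = method,
         n = n, ...),
    class = "ssep_assoc"
  )
}

#' @export
print.ssep_assoc <- function(x, ...) {
  cat(sprintf("<ssep_assoc> %s: statistic = %.6g, p = %.4g, n = %d\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' @rdname tidy
#' @param x A `ssep_assoc` result.
#' @param ... Unused.
#' @method tidy ssep_assoc
#' @export
tidy.ssep_assoc <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 method = x$method, n = x$n)
}

#' Tidy / glance at a test result
#'
#' One-row tibble summaries of the package's association test results, in
#' the broom convention.
#'
#' @name tidy
NULL

#' @rdname tidy
#' @method glance ssep_assoc
#' @export
glance.ssep_assoc <- function(x, ...) tidy(x)

as_2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
    x
  } else {
    stopifnot(is.numeric(x), length(x) == 4L)
    matrix(x, nrow = 2, byrow = TRUE)
  }
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test with the probability-mass two-sided rule: with all
#' margins fixed, the p-value is the sum of hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed table
#' (a relative tolerance of 1e-7 guards the comparison against floating
#' error). A zero margin leaves no alternative tables and returns p = 1.
#'
#' @param x A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `(a, b, c, d)` filling the table by rows.
#' @return A `ssep_assoc` with the sample odds ratio as statistic.
#' @examples
#' fisher_exact_2x2(matrix(c(27, 4, 0, 4), nrow = 2, byrow = TRUE))$p_value
#' @export
fisher_exact_2x2 <- function(x) {
  tab <- as_2x2(x)
  if (any(tab < 0) || any(tab != round(tab)) || !all(is.finite(tab))) {
    abort("counts must be non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  if (n < 1) {
    abort("table must contain at least one observation")
  }
  r1 <- a + b; c1 <- a + c
  odds <- (a * d) / (b * c)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    return(new_assoc(odds, 1, "Fisher exact test (two-sided)", n,
                     table = tab))
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  if (abs(sum(probs) - 1) > 1e-9) {
    abort("internal error: hypergeometric probabilities do not normalise")
  }
  p_obs <- dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_assoc(odds, p, "Fisher exact test (two-sided)", n, table = tab)
}

tie_counts <- function(v) {
  t <- table(v)
  as.numeric(t[t > 1])
}

# number-of-inversions distribution for untied rankings (Kendall exact null):
# iterated convolution with a length-m boxcar
inversion_counts <- function(n) {
  w <- 1
  for (m in 2:n) {
    nw <- numeric(length(w) + m - 1)
    for (j in 0:(m - 1)) {
      idx <- seq_along(w) + j
      nw[idx] <- nw[idx] + w
    }
    w <- nw
  }
  w # length n(n-1)/2 + 1, counts of permutations by inversion number
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected rank correlation
#' `tau_b = (C - D) / sqrt((n0 - Tx)(n0 - Ty))`, with a two-tailed p-value
#' from the tie-adjusted normal approximation of `C - D`, or from the exact
#' inversion-number null distribution for small untied samples.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param p_method `"auto"` (exact when `n <= 10` and untied, otherwise
#'   normal), `"normal"`, or `"exact"`.
#' @return A `ssep_assoc` with `statistic = tau_b`.
#' @examples
#' kendall_tau_b(1:5, c(2, 1, 4, 3, 5))
#' @export
kendall_tau_b <- function(x, y, p_method = c("auto", "normal", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 2) {
    abort("need at least two observations")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("inputs must not contain NA")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("tau_b is undefined when x or y is constant")
  }
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  s <- sum(dx * dy * upper.tri(dx))
  n0 <- n * (n - 1) / 2
  tx <- tie_counts(x); ty <- tie_counts(y)
  Tx <- sum(tx * (tx - 1) / 2); Ty <- sum(ty * (ty - 1) / 2)
  tau <- s / sqrt((n0 - Tx) * (n0 - Ty))

  untied <- length(tx) == 0 && length(ty) == 0
  use_exact <- (p_method == "exact") ||
    (p_method == "auto" && n <= 10 && untied)
  if (use_exact && !untied) {
    abort("exact p-value requires untied data")
  }
  if (use_exact) {
    w <- inversion_counts(n)
    k <- seq_along(w) - 1 # inversion numbers; S = n0 - 2k
    p <- sum(w[abs(n0 - 2 * k) >= abs(s)]) / sum(w)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- if (n > 2) {
      sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
        (9 * n * (n - 1) * (n - 2))
    } else 0
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- s / sqrt(var_s)
    p <- 2 * pnorm(-abs(z))
  }
  new_assoc(tau, min(p, 1), "Kendall tau-b", n, cd = s)
}

#' Kruskal-Wallis H test
#'
#' Rank-based comparison of three or more independent samples:
#' `H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2`, with mid-ranks for ties
#' and the usual tie-correction divisor; p-value from the chi-square
#' distribution with `k - 1` degrees of freedom.
#'
#' @param groups List of non-empty numeric vectors (>= 2 groups).
#' @return A `ssep_assoc` with `statistic = H`.
#' @examples
#' kruskal_wallis_h(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis_h <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, function(g) is.numeric(g) && length(g) > 0, TRUE))) {
    abort("each group must be a non-empty numeric vector")
  }
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) {
    abort("inputs must not contain NA")
  }
  N <- length(pooled)
  if (length(unique(pooled)) == 1L) {
    abort("H is undefined when all observations are identical (tie factor 0)")
  }
  r <- rank(pooled)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  t <- tie_counts(pooled)
  correction <- 1 - sum(t^3 - t) / (N^3 - N)
  h <- h / correction
  p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  new_assoc(h, p, "Kruskal-Wallis H", N, df = length(groups) - 1)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with mid-ranks: `U_x = R_x - n_x(n_x+1)/2`; the
#' reported statistic is `min(U_x, U_y)`. The two-tailed p-value comes from
#' exact enumeration of all group assignments of the observed (possibly
#' tied) ranks when `n_x + n_y <= 12`, otherwise from the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A `ssep_assoc` with `statistic = min(U_x, U_y)` (also carries
#'   `u_x` and `u_y`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) > 0, length(y) > 0)
  if (anyNA(x) || anyNA(y)) {
    abort("inputs must not contain NA")
  }
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  u <- min(ux, uy)
  mu <- nx * ny / 2

  if (N <= 12) {
    combos <- combn(N, nx)
    us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(ux - mu) - 1e-9)
  } else {
    t <- tie_counts(r)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    if (sigma2 <= 0) {
      abort("U variance is zero: all observations identical")
    }
    z <- (ux - mu - sign(ux - mu) * 0.5) / sqrt(sigma2)
    if (ux == mu) z <- 0
    p <- 2 * pnorm(-abs(z))
  }
  new_assoc(u, min(p, 1), "Mann-Whitney U", N, u_x = ux, u_y = uy)
}
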
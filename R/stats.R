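#' Jonckheere trend test for ordered groups
#'
#' Tests for a monotone location trend across k ordered groups using the
#' Jonckheere statistic: the sum over ordered group pairs of between-group
#' concordances, with half credit for ties. The default inference uses the
#' normal approximation with a tie-corrected null variance; for small totals
#' an exact p-value is computed by full enumeration of group assignments.
#'
#' @param groups list of numeric vectors, in the hypothesized order.
#' @param alternative `"increasing"` or `"decreasing"` location trend.
#' @param method `"auto"` (exact when total n <= `exact_max`, otherwise
#'   normal), `"normal"`, or `"exact"`.
#' @param exact_max largest total sample size for which `"auto"` enumerates.
#' @return object of class `jonckheere_result`: list with `J` (statistic),
#'   `mean`, `variance` (tie-corrected), `z`, `p_value` (one-sided),
#'   `alternative` and `method`.
#' @export
jonckheere <- function(groups, alternative = c("increasing", "decreasing"),
                       method = c("auto", "normal", "exact"),
                       exact_max = 12L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least 2 numeric samples")
  if (length(groups) == 2L)
    warning("only 2 ordered groups supplied; the trend test reduces to a rank-sum comparison")
  if (any(vapply(groups, length, 1L) == 0L))
    stop("all groups must be non-empty")
  groups <- lapply(groups, as.numeric)
  if (any(!vapply(groups, function(g) all(is.finite(g)), TRUE)))
    stop("non-finite values in 'groups'")

  n_i <- vapply(groups, length, 1L)
  N <- sum(n_i)
  x <- unlist(groups, use.names = FALSE)
  if (alternative == "decreasing") {
    # reverse values so an increasing statistic measures the decreasing trend
    groups_j <- lapply(groups, function(g) -g)
  } else {
    groups_j <- groups
  }
  J <- .jonckheere_stat(groups_j)

  mu <- sum(outer(n_i, n_i)[upper.tri(diag(length(n_i)))]) / 2

  # tie-corrected variance (ties pooled across groups)
  t_u <- as.numeric(table(x))
  A <- N * (N - 1) * (2 * N + 5) -
    sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
    sum(t_u * (t_u - 1) * (2 * t_u + 5))
  B <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_u * (t_u - 1) * (t_u - 2))
  C <- sum(n_i * (n_i - 1)) * sum(t_u * (t_u - 1))
  V <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))

  if (method == "auto") method <- if (N <= exact_max) "exact" else "normal"

  if (method == "exact") {
    p <- .jonckheere_exact_p(groups_j, J)
    z <- if (V > 0) (J - mu) / sqrt(V) else 0
  } else {
    if (V <= 0) {
      z <- 0
      p <- 0.5
    } else {
      # continuity-corrected upper tail: P(J >= j) ~ 1 - Phi((j - 1/2 - mu)/sd)
      z <- (J - 0.5 - mu) / sqrt(V)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  structure(list(J = J, mean = mu, variance = V, z = z, p_value = p,
                 alternative = alternative, method = method),
            class = "jonckheere_result")
}

# J statistic for an increasing alternative
.jonckheere_stat <- function(groups) {
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1L)) {
    gi <- groups[[i]]
    for (j in (i + 1L):k) {
      gj <- groups[[j]]
      cmp <- outer(gi, gj, function(a, b) (b > a) + 0.5 * (b == a))
      J <- J + sum(cmp)
    }
  }
  J
}

# exact one-sided p by full enumeration of assignments of the pooled sample
# to groups of the observed sizes; P(J >= observed)
.jonckheere_exact_p <- function(groups, J_obs) {
  n_i <- vapply(groups, length, 1L)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  counts <- new.env()
  counts$ge <- 0
  counts$total <- 0
  recurse <- function(remaining_idx, g, assigned) {
    if (g > length(n_i)) {
      gl <- split(x[assigned], rep(seq_along(n_i), n_i))
      J <- .jonckheere_stat(gl)
      counts$total <- counts$total + 1
      if (J >= J_obs - 1e-9) counts$ge <- counts$ge + 1
      return(invisible())
    }
    picks <- utils::combn(remaining_idx, n_i[g], simplify = FALSE)
    for (p in picks) {
      recurse(setdiff(remaining_idx, p), g + 1L, c(assigned, p))
    }
  }
  recurse(seq_len(N), 1L, integer(0))
  counts$ge / counts$total
}

#' Fisher's exact test for a 2x2 table with conditional-MLE odds ratio
#'
#' Two-sided p-value by the point-probability rule (sum of hypergeometric
#' probabilities of all tables at least as extreme as, i.e. no more probable
#' than, the observed table) and the conditional maximum-likelihood estimate
#' of the odds ratio under Fisher's noncentral hypergeometric distribution,
#' obtained by solving the score equation E_psi[X] = x by root finding.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return object of class `fisher_result`: list with `table`,
#'   `p_two_sided`, `or_cmle`, `or_sample`, and `degenerate` flag (TRUE when
#'   a margin is zero; then p = 1 and the odds ratio is NaN).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("'table' must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("'table' must contain non-negative integers")
  x <- table[1, 1]
  m1 <- sum(table[1, ])   # row 1 margin
  m2 <- sum(table[2, ])
  k <- sum(table[, 1])    # column 1 margin
  N <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == N) {
    return(structure(list(table = table, p_two_sided = 1,
                          or_cmle = NaN, or_sample = NaN, degenerate = TRUE),
                     class = "fisher_result"))
  }
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  support <- lo:hi
  dens <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(x, m1, m2, k)
  p_two <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  p_two <- min(1, p_two)

  or_sample <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])

  or_cmle <- .cmle_odds_ratio(x, support, m1, m2, k)

  structure(list(table = table, p_two_sided = p_two, or_cmle = or_cmle,
                 or_sample = or_sample, degenerate = FALSE),
            class = "fisher_result")
}

# conditional MLE: psi such that E_psi[X] = x on the noncentral
# hypergeometric support; boundary cases map to 0 / Inf
.cmle_odds_ratio <- function(x, support, m1, m2, k) {
  if (x == min(support)) return(0)
  if (x == max(support)) return(Inf)
  logdc <- stats::dhyper(support, m1, m2, k, log = TRUE)
  mean_x <- function(log_psi) {
    logw <- logdc + support * log_psi
    logw <- logw - max(logw)
    w <- exp(logw)
    sum(support * w) / sum(w)
  }
  f <- function(log_psi) mean_x(log_psi) - x
  lower <- -1
  while (f(lower) > 0) lower <- lower * 2
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  exp(stats::uniroot(f, c(lower, upper), tol = 1e-10)$root)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation on complete pairs, with the classical
#' t-transform p-value: t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df.
#'
#' @param x,y numeric vectors of equal length; pairs with missing values in
#'   either vector are dropped.
#' @return list with `r`, `p_value`, `n` (complete pairs).
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p_value = p, n = n)
}

#' Locally weighted scatterplot smoother
#'
#' Thin wrapper around [stats::lowess()] returning fitted values in the
#' order of the input points. Used for visualizing expression-dependence of
#' guide log-fold changes.
#'
#' @param x,y numeric vectors (at least 5 points).
#' @param frac smoother span in (0, 1]; default 2/3.
#' @return numeric vector of fitted values aligned with `x`.
#' @export
lowess_fit <- function(x, y, frac = 2 / 3) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 5L) stop("need at least 5 points")
  if (!is.numeric(frac) || frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
  fit <- stats::lowess(x, y, f = frac)
  # lowess returns values sorted by x; map fitted values back to input order,
  # averaging duplicates at identical x
  fitted_at <- stats::approx(fit$x, fit$y, xout = x, ties = mean, rule = 2)$y
  fitted_at
}

#' @export
print.jonckheere_result <- function(x, ...) {
  cat("Jonckheere trend test (", x$alternative, ", ", x$method, ")\n",
      "J = ", format(x$J), ", z = ", format(round(x$z, 4)),
      ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher exact 2x2: p =", format(x$p_two_sided),
      " OR (conditional MLE) =", format(x$or_cmle), "\n")
  invisible(x)
}
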
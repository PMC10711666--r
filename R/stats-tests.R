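# Container for a single hypothesis-test result.
new_test_result <- function(statistic, p_value, method, alternative = "two_sided") {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(
    list(statistic = statistic, p_value = p_value,
         method = method, alternative = alternative),
    class = "lb_test"
  )
}

#' @export
print.lb_test <- function(x, ...) {
  cat(sprintf("%s test (%s): statistic = %.6g, p = %.4g\n",
              x$method, x$alternative, x$statistic, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The p-value is computed by
#' exhaustive enumeration of all rank assignments whenever the number of
#' distinct assignments `choose(n + m, n)` does not exceed `exact_limit`
#' (ties are handled exactly through midranks); otherwise a normal
#' approximation with tie correction and, by default, a continuity correction
#' is used. The U statistic is reported for the first sample.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`; the
#'   directional alternatives refer to `x` tending larger (greater) or
#'   smaller (less) than `y`.
#' @param exact_limit Maximum number of enumerable rank assignments for which
#'   the exact distribution is used.
#' @param correct Apply the continuity correction in the normal approximation.
#' @return An `lb_test` with fields `statistic` (U for `x`), `p_value`,
#'   `method`, `alternative`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, alternative = c("two_sided", "greater", "less"),
                           exact_limit = 1e5, correct = TRUE) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("NA values are not supported")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  if (length(unique(pooled)) == 1L) {
    return(new_test_result(u_obs, 1, "mwu", alternative))
  }

  if (choose(n + m, n) <= exact_limit) {
    # Exact null distribution of U over all assignments of pooled midranks.
    combs <- utils::combn(n + m, n)
    u_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    p_le <- mean(u_all <= u_obs)
    p_ge <- mean(u_all >= u_obs)
    p <- switch(alternative,
      two_sided = min(1, 2 * min(p_le, p_ge)),
      greater   = p_ge,
      less      = p_le)
    return(new_test_result(u_obs, p, "mwu", alternative))
  }

  mu <- n * m / 2
  N <- n + m
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (n * m / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(new_test_result(u_obs, 1, "mwu", alternative))
  sigma <- sqrt(sigma2)
  cc <- if (correct) 0.5 else 0
  p <- switch(alternative,
    two_sided = {
      z <- (abs(u_obs - mu) - cc) / sigma
      min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    },
    greater = stats::pnorm((u_obs - mu - cc) / sigma, lower.tail = FALSE),
    less    = stats::pnorm((u_obs - mu + cc) / sigma))
  new_test_result(u_obs, p, "mwu", alternative)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction; p-value from the chi-square approximation
#' with k - 1 degrees of freedom. Identical values across all groups give
#' H = 0 and p = 1 by convention.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return An `lb_test` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) stop("NA values are not supported")
  N <- length(pooled)
  k <- length(groups)
  r <- rank(pooled)
  g <- rep.int(seq_len(k), sizes)
  rbar <- tapply(r, g, mean)
  h_raw <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- table(pooled)
  denom <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (denom <= 0) return(new_test_result(0, 1, "kruskal"))  # all values identical
  h <- h_raw / denom
  p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  if (h == 0) p <- 1
  new_test_result(h, p, "kruskal")
}

#' Conover-Iman post hoc test
#'
#' Pairwise rank comparisons after a Kruskal-Wallis test, using the t
#' statistic on pooled-rank variance with the (N - 1 - H) / (N - k)
#' correction. Returns a symmetric matrix of two-sided p-values, optionally
#' Bonferroni-adjusted (multiplied by the number of pairs, capped at 1).
#'
#' @param groups List of numeric vectors (each with at least one value).
#' @param p_adjust `"none"` or `"bonferroni"`.
#' @return Symmetric k x k matrix of p-values with 1 on the diagonal.
#' @export
conover_posthoc <- function(groups, p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group must contain at least one observation")
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep.int(seq_len(k), sizes)
  rbar <- tapply(r, g, mean)
  h <- kruskal_wallis(groups)$statistic
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  pm <- matrix(1, k, k, dimnames = list(nm, nm))
  if (s2 <= 0 || N == k) return(pm)  # zero rank variance: everything tied
  scale2 <- s2 * (N - 1 - h) / (N - k)
  scale2 <- max(scale2, 0)
  n_pairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(scale2 * (1 / sizes[i] + 1 / sizes[j]))
      p <- if (se == 0) 1 else {
        tstat <- (rbar[i] - rbar[j]) / se
        2 * stats::pt(abs(tstat), df = N - k, lower.tail = FALSE)
      }
      if (p_adjust == "bonferroni") p <- min(1, p * n_pairs)
      pm[i, j] <- pm[j, i] <- p
    }
  }
  pm
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and
#' values are capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= overlap) that a query of `query_size` genes
#' drawn from a universe of `background` genes overlaps a reference set of
#' `set_size` genes at least `overlap` times. Evaluated on the log scale via
#' the hypergeometric distribution.
#'
#' @param overlap Observed overlap (non-negative integer).
#' @param set_size,query_size,background Reference-set, query and universe
#'   sizes; `overlap <= min(set_size, query_size)` and both sizes must not
#'   exceed `background`.
#' @return Upper-tail p-value.
#' @export
hypergeom_overrep <- function(overlap, set_size, query_size, background) {
  vals <- c(overlap, set_size, query_size, background)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
    stop("all arguments must be non-negative integers")
  if (overlap > min(set_size, query_size))
    stop("overlap exceeds min(set_size, query_size)")
  if (set_size > background || query_size > background)
    stop("set and query sizes must not exceed the background")
  if (overlap == 0) return(1)
  exp(stats::phyper(overlap - 1, set_size, background - set_size, query_size,
                    lower.tail = FALSE, log.p = TRUE))
}
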
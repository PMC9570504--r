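# Self-contained rank-based group comparisons (and Student's t), implemented
# from first principles so group results carry no external statistical
# dependency.  Base R supplies only the reference distributions
# (pchisq/pnorm/pt).

as_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  if (any(lengths(groups) < 1)) stop("every group needs at least one value")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction; p-value from the chi-square distribution
#' with `k - 1` degrees of freedom.  If all values are identical the test is
#' uninformative and `p = 1` by convention.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups,
#'   total n >= 3).
#' @return List of class `"gj_htest"`: `statistic` (H), `df`, `p.value`,
#'   `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3) stop("total n must be >= 3")
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  ni <- lengths(groups)
  Ri <- tapply(r, g, sum)
  H <- 12 / (n * (n + 1)) * sum(Ri^2 / ni) - 3 * (n + 1)
  C <- 1 - tie_term(x) / (n^3 - n)
  if (C <= 0) {
    out <- list(statistic = 0, df = length(groups) - 1, p.value = 1, n = n,
                method = "Kruskal-Wallis rank test")
    return(structure(out, class = "gj_htest"))
  }
  H <- H / C
  structure(list(statistic = H, df = length(groups) - 1,
                 p.value = pchisq(H, length(groups) - 1, lower.tail = FALSE),
                 n = n, method = "Kruskal-Wallis rank test"),
            class = "gj_htest")
}

#' Dunn's post hoc test against a reference group
#'
#' Pairwise z statistics from the pooled ranks with tie correction,
#' restricted to comparisons of each group against the named reference
#' (the variant-versus-wild-type design).  P-values are two-sided normal,
#' Bonferroni-adjusted over the comparisons performed by default.
#'
#' @inheritParams kruskal_wallis
#' @param reference Name of the reference group.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return Data frame with one row per comparison: `group`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_posthoc <- function(groups, reference, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- as_groups(groups)
  if (!reference %in% names(groups))
    stop("reference group '", reference, "' not found")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  s2 <- n * (n + 1) / 12 - tie_term(x) / (12 * (n - 1))
  others <- setdiff(names(groups), reference)
  z <- vapply(others, function(k) {
    (rbar[[k]] - rbar[[reference]]) /
      sqrt(s2 * (1 / ni[[k]] + 1 / ni[[reference]]))
  }, 0)
  p <- 2 * pnorm(-abs(z))
  m <- length(others)
  p_adj <- if (adjust == "bonferroni") pmin(1, p * m) else p
  data.frame(group = others, z = z, p = p, p_adj = p_adj, row.names = NULL)
}

# Null counts of the Mann-Whitney U statistic by the classic recurrence
# f(i, j, u) = f(i-1, j, u-j) + f(i, j-1, u); doubles are exact here
# (counts stay far below 2^53 for m*n <= 400).
u_null_counts <- function(m, n) {
  dp <- rep(list(1), m + 1)          # j = 0: f(i, 0) = {1}
  for (j in seq_len(n)) {
    new <- vector("list", m + 1)
    new[[1]] <- 1
    for (i in seq_len(m)) {
      len <- i * j + 1
      a <- c(rep(0, j), new[[i]])                  # f(i-1, j, u - j)
      a <- c(a, rep(0, len - length(a)))
      b <- c(dp[[i + 1]], rep(0, len - length(dp[[i + 1]])))
      new[[i + 1]] <- a + b
    }
    dp <- new
  }
  dp[[m + 1]]
}

#' Mann-Whitney U test
#'
#' U counts the (a > b) pairs, with half credit for ties.  When there are no
#' ties and `n_a * n_b <= 400` the two-sided p-value is exact (full null
#' distribution of U); otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param a,b Numeric samples.
#' @return List of class `"gj_htest"`: `statistic` (U), `p.value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  m <- length(a); n <- length(b)
  if (m < 1 || n < 1) stop("both samples must be non-empty")
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && m * n <= 400) {
    cnt <- u_null_counts(m, n)
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(U + 1)]) / tot          # P(U <= u)
    hi <- sum(cnt[(U + 1):length(cnt)]) / tot     # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    N <- m + n
    mu <- m * n / 2
    sig2 <- m * n / 12 * ((N + 1) - tie_term(c(a, b)) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  structure(list(statistic = U, p.value = p,
                 method = paste("Mann-Whitney U test,", method)),
            class = "gj_htest")
}

#' Two-sided pooled-variance Student's t test
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return List of class `"gj_htest"`: `statistic` (t), `df`, `p.value`.
#'   If both samples have zero variance and equal means, `p = 1` by
#'   convention.
#' @export
student_t <- function(a, b) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  m <- length(a); n <- length(b)
  if (m < 2 || n < 2) stop("both samples need n >= 2 for the t test")
  sp2 <- ((m - 1) * stats::var(a) + (n - 1) * stats::var(b)) / (m + n - 2)
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    out <- list(statistic = if (d == 0) 0 else sign(d) * Inf, df = m + n - 2,
                p.value = if (d == 0) 1 else 0,
                method = "Student's t test (pooled variance)")
    return(structure(out, class = "gj_htest"))
  }
  t <- d / sqrt(sp2 * (1 / m + 1 / n))
  structure(list(statistic = t, df = m + n - 2,
                 p.value = 2 * pt(-abs(t), m + n - 2),
                 method = "Student's t test (pooled variance)"),
            class = "gj_htest")
}

#' @export
print.gj_htest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g%s, p = %.4g\n", x$statistic,
              if (!is.null(x$df)) sprintf(", df = %g", x$df) else "",
              x$p.value))
  invisible(x)
}
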
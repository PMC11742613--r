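#' Group-comparison test result
#'
#' Lightweight container for the rank-based and ANOVA comparisons used by
#' the census and depth pipelines.
#'
#' @param method Method name.
#' @param statistic Test statistic value (finite).
#' @param p_value P-value in `[0, 1]`.
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`.
#' @param tie_corrected Whether a tie correction entered the null variance.
#' @param n Integer vector of group sizes.
#' @param ... Further named fields (degrees of freedom, estimates, labels).
#' @return Object of class `trp_test`.
#' @export
test_result <- function(method, statistic, p_value,
                        alternative = "two.sided", tie_corrected = FALSE,
                        n = integer(), ...) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, alternative = alternative,
                   tie_corrected = tie_corrected, n = as.integer(n)),
              list(...)),
            class = "trp_test")
}

#' @export
print.trp_test <- function(x, ...) {
  cat("<trp_test>", x$method, "\n  statistic =",
      format(x$statistic, digits = 6), " p =", format(x$p_value, digits = 4),
      paste0("(", x$alternative, ")"), "\n  n =",
      paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Mann-Whitney U rank test
#'
#' U is computed from midranks. For small samples (`n1 + n2 <= 12`, or
#' when `exact = TRUE`) the p-value comes from exact enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the observed midranks
#' (conditional on ties); otherwise from the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y Nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` (x shifted left)
#'   or `"greater"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the enumeration path;
#'   `NULL` chooses by total sample size.
#' @return A [test_result()] with extra fields `U` and `exact`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- N <= 12L
  if (exact) {
    combos <- utils::combn(N, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- switch(alternative,
                less      = mean(us <= u + eps),
                greater   = mean(us >= u - eps),
                two.sided = mean(abs(us - mu) >= abs(u - mu) - eps))
    tie_corrected <- FALSE
  } else {
    tcount <- table(r)
    tie_term <- sum(tcount^3 - tcount)
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1))))
    if (sigma == 0) {
      p <- 1
    } else {
      p <- switch(alternative,
        less      = stats::pnorm((u - mu + 0.5) / sigma),
        greater   = stats::pnorm((u - mu - 0.5) / sigma,
                                 lower.tail = FALSE),
        two.sided = min(1, 2 * stats::pnorm(
          (abs(u - mu) - 0.5) / sigma, lower.tail = FALSE)))
    }
    tie_corrected <- has_ties
  }
  test_result("Mann-Whitney U", statistic = u, p_value = p,
              alternative = alternative, tie_corrected = tie_corrected,
              n = c(n1, n2), U = u, exact = exact)
}

#' One-way analysis of variance
#'
#' F = MSB / MSW on (k - 1, N - k) degrees of freedom, from sums of
#' squares. A zero within-group mean square is an error unless the group
#' means are also all equal (every observation identical), in which case
#' F = 0 and p = 1.
#'
#' @param groups List of >= 2 numeric samples, each with >= 2 observations.
#' @return A [test_result()] with extra fields `df1`, `df2`, `msw`,
#'   `means`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs >= 2 observations")
  k <- length(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  if (msw == 0) {
    if (isTRUE(all.equal(ssb, 0))) {
      return(test_result("one-way ANOVA", statistic = 0, p_value = 1,
                         n = sizes, df1 = k - 1L, df2 = N - k, msw = 0,
                         means = means))
    }
    stop("zero within-group variance with unequal means (MSW = 0)")
  }
  f <- msb / msw
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  test_result("one-way ANOVA", statistic = f, p_value = p, n = sizes,
              df1 = k - 1L, df2 = N - k, msw = msw, means = means)
}

#' Studentized-range distribution function
#'
#' P(Q <= q) for the range of `k` independent standard-normal means
#' studentized by an independent chi-based scale on `df` degrees of
#' freedom, evaluated by direct two-level numerical quadrature of
#'
#' \deqn{P(Q \le q) = \int_0^\infty f_{df}(s)\, k \int_{-\infty}^{\infty}
#'   \phi(z)\,[\Phi(z) - \Phi(z - q s)]^{k-1}\, dz\, ds,}
#'
#' where `f_df` is the density of `sqrt(chi^2_df / df)`. Quadrature
#' tolerances are set so the CDF is accurate to about 1e-6.
#'
#' @param q Quantile (scalar).
#' @param k Number of groups (>= 2).
#' @param df Within-group degrees of freedom (>= 1).
#' @return P(Q <= q).
#' @export
studentized_range_cdf <- function(q, k, df) {
  stopifnot(length(q) == 1L, k >= 2, df >= 1)
  if (!is.finite(q)) return(as.numeric(q > 0))
  if (q <= 0) return(0)
  inner <- function(x) {
    # P(range of k std normals <= x)
    val <- stats::integrate(function(z)
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - x))^(k - 1),
      -Inf, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
    min(1, k * val)
  }
  log_c <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2)
  outer_fun <- function(s) {
    vapply(s, function(si) {
      if (si <= 0) return(0)
      dens <- exp(log_c + (df - 1) * log(si) - df * si^2 / 2)
      if (dens == 0) return(0)
      dens * inner(q * si)
    }, numeric(1))
  }
  val <- stats::integrate(outer_fun, 0, Inf, rel.tol = 1e-7,
                          abs.tol = 1e-9)$value
  min(1, max(0, val))
}

#' Tukey honestly-significant-difference test
#'
#' All pairwise comparisons after a one-way ANOVA. For each pair,
#' `q = |mean_i - mean_j| / sqrt(MSW / n_h)` where `n_h` is the harmonic
#' mean of the two group sizes (the Tukey-Kramer variant; for equal n it
#' reduces to the classical statistic), and the p-value is the upper tail
#' of the studentized-range distribution with `k` groups and `N - k`
#' degrees of freedom, evaluated by [studentized_range_cdf()].
#'
#' @param groups List of >= 2 numeric samples, each with >= 2 observations.
#' @param labels Optional group labels (default `g1`, `g2`, ...).
#' @return List of [test_result()]s, one per unordered pair, each with
#'   extra fields `pair`, `q`, `diff`, `df`.
#' @export
tukey_hsd <- function(groups, labels = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs >= 2 observations")
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  stopifnot(length(labels) == length(groups))
  k <- length(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msw <- ssw / (N - k)
  if (msw == 0) stop("zero within-group variance (MSW = 0)")
  df <- N - k
  out <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      nh <- 2 / (1 / sizes[i] + 1 / sizes[j])
      q <- abs(means[i] - means[j]) / sqrt(msw / nh)
      p <- 1 - studentized_range_cdf(q, k, df)
      out[[length(out) + 1L]] <- test_result(
        "Tukey HSD", statistic = q, p_value = min(1, max(0, p)),
        n = c(sizes[i], sizes[j]),
        pair = c(labels[i], labels[j]), q = q,
        diff = means[i] - means[j], df = df)
    }
  }
  out
}
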
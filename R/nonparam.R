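#' Runs test about the median (Wald-Wolfowitz)
#'
#' Counts maximal runs of consecutive values above or below the sample
#' median; values tied with the median are discarded before counting. Too
#' few runs indicate serial dependence (a trend or a random walk), too
#' many indicate alternation. The exact run-count distribution
#' \deqn{P(R = 2k) = 2 \binom{n_1-1}{k-1}\binom{n_2-1}{k-1} /
#'   \binom{n}{n_1}}
#' (and the analogous odd-R form) is used when the retained count n_used
#' is at most `exact_max`; beyond that the normal approximation with
#' continuity correction takes over.
#'
#' `p_lower` = P(R <= observed) is the tail sensitive to trends and walks
#' (the use case here); `p_upper` and a two-sided p are also reported.
#'
#' @param ys numeric sequence.
#' @param exact_max largest n_used for which the exact distribution is
#'   enumerated (default 40).
#' @return list of class `runs_result`: `n_used`, `n_above`, `n_below`,
#'   `n_runs`, `p_lower`, `p_upper`, `p_two_sided`, `method`.
#' @export
runs_test <- function(ys, exact_max = 40L) {
  med <- stats::median(ys)
  s <- sign(ys - med)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0)
    stop("degenerate sequence: all retained values on one side of the median")
  n <- n1 + n2
  r_obs <- length(rle(s)$lengths)
  if (n <= exact_max) {
    probs <- runs_exact_pmf(n1, n2)
    p_lower <- sum(probs[seq_len(r_obs - 1L)])  # probs[r-1] = P(R = r)
    p_upper <- sum(probs[(r_obs - 1L):length(probs)])
    method <- "exact"
  } else {
    mu <- 2 * n1 * n2 / n + 1
    sg <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
    p_lower <- stats::pnorm(r_obs + 0.5, mu, sg)
    p_upper <- stats::pnorm(r_obs - 0.5, mu, sg, lower.tail = FALSE)
    method <- "normal_approx"
  }
  structure(list(n_used = n, n_above = n1, n_below = n2, n_runs = r_obs,
                 p_lower = min(1, p_lower), p_upper = min(1, p_upper),
                 p_two_sided = min(1, 2 * min(p_lower, p_upper)),
                 method = method),
            class = "runs_result")
}

# P(R = r) for r = 2..(n1+n2 when both sides interleave fully);
# returns a vector indexed by r - 1.
runs_exact_pmf <- function(n1, n2) {
  rmax <- 2L * min(n1, n2) + (n1 != n2)
  denom <- choose(n1 + n2, n1)
  p <- numeric(rmax - 1L)
  for (r in 2:rmax) {
    if (r %% 2 == 0) {
      k <- r / 2
      num <- 2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (r - 1) / 2
      num <- choose(n1 - 1, k - 1) * choose(n2 - 1, k) +
        choose(n1 - 1, k) * choose(n2 - 1, k - 1)
    }
    p[r - 1L] <- num / denom
  }
  p
}

#' @export
print.runs_result <- function(x, ...) {
  cat(sprintf(
    "Runs about the median: %d runs (%d above / %d below, n = %d), P(R <= obs) = %.4g [%s]\n",
    x$n_runs, x$n_above, x$n_below, x$n_used, x$p_lower, x$method))
  invisible(x)
}

#' Hodges-Lehmann location estimate with confidence interval
#'
#' The estimate is the median of all n(n+1)/2 Walsh averages
#' (x_i + x_j)/2, i <= j; the confidence interval takes the order
#' statistics of the sorted Walsh averages at the Wilcoxon signed-rank
#' critical positions (exact critical values for n <= 50, normal
#' approximation beyond).
#'
#' @param ys numeric sample, n >= 1.
#' @param conf confidence level.
#' @return list: `estimate`, `lower`, `upper`, `conf`, `n`.
#' @export
hl_median_ci <- function(ys, conf = 0.95) {
  n <- length(ys)
  if (!n) stop("empty sample")
  if (n == 1L)
    return(list(estimate = ys, lower = ys, upper = ys, conf = conf, n = 1L))
  alpha <- 1 - conf
  w <- outer(ys, ys, "+")[upper.tri(diag(n), diag = TRUE)] / 2
  w <- sort(w)
  m <- length(w)
  est <- stats::median(w)
  if (n <= 50L) {
    k <- stats::qsignrank(alpha / 2, n)
    if (stats::psignrank(k, n) > alpha / 2 && k > 0) k <- k - 1L
  } else {
    k <- floor(m / 2 - stats::qnorm(1 - alpha / 2) *
                 sqrt(n * (n + 1) * (2 * n + 1) / 24))
  }
  k <- max(0L, min(k, floor((m - 1) / 2)))
  list(estimate = est, lower = w[k + 1L], upper = w[m - k], conf = conf,
       n = n)
}

#' Theil nonparametric regression with Spearman correlation
#'
#' The slope is the median of all pairwise slopes
#' (y_j - y_i)/(x_j - x_i) over pairs with distinct x; its confidence
#' interval uses the rank positions of the sorted pairwise slopes given by
#' the normal approximation to Kendall's statistic. The intercept is the
#' median of y_i - beta * x_i, with a Hodges-Lehmann-style interval on
#' those residual intercepts. The tie-corrected Spearman coefficient
#' (Pearson correlation of mid-ranks) and its large-sample significance
#' are attached.
#'
#' @param xs,ys numeric vectors of equal length, n >= 3; xs not all equal.
#' @param conf confidence level for the slope and intercept intervals.
#' @return list of class `theil_fit`: `alpha`, `alpha_ci`, `beta`,
#'   `beta_ci`, `rho_s`, `p_rho`, `n`.
#' @export
theil_regression <- function(xs, ys, conf = 0.95) {
  n <- length(xs)
  stopifnot(length(ys) == n)
  if (n < 3) stop("need at least 3 pairs")
  if (length(unique(xs)) == 1L) stop("all x values identical")
  dx <- outer(xs, xs, "-")
  dy <- outer(ys, ys, "-")
  keep <- upper.tri(dx) & dx != 0
  slopes <- sort(dy[keep] / dx[keep])
  beta <- stats::median(slopes)
  M <- length(slopes)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  l <- max(1L, floor((M - C) / 2))
  u <- min(M, ceiling((M + C) / 2) + 1L)
  beta_ci <- c(slopes[l], slopes[u])
  resid <- ys - beta * xs
  hl <- hl_median_ci(resid, conf = conf)
  alpha <- stats::median(resid)
  rx <- rank(xs); ry <- rank(ys)          # mid-ranks: tie-corrected rho
  rho <- suppressWarnings(stats::cor(rx, ry))
  if (is.na(rho)) { rho <- 0; }            # a constant margin: no association
  p_rho <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  structure(list(alpha = alpha, alpha_ci = c(hl$lower, hl$upper),
                 beta = beta, beta_ci = beta_ci, rho_s = rho,
                 p_rho = p_rho, n = n),
            class = "theil_fit")
}

#' @export
print.theil_fit <- function(x, ...) {
  cat(sprintf(
    "Theil fit: alpha = %.4g (%.4g, %.4g), beta = %.4g (%.4g, %.4g), rho_S = %.3f (P = %.3g), n = %d\n",
    x$alpha, x$alpha_ci[1], x$alpha_ci[2], x$beta, x$beta_ci[1],
    x$beta_ci[2], x$rho_s, x$p_rho, x$n))
  invisible(x)
}

#' Jarque-Bera Gaussianity test
#'
#' JB = n/6 * (S^2 + (K - 3)^2 / 4) from the sample skewness S and
#' kurtosis K (population-moment definitions), referred to the chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param ys numeric sample, n >= 8, non-constant.
#' @return list: `statistic`, `p`, `skewness`, `kurtosis`, `n`.
#' @export
jarque_bera <- function(ys) {
  n <- length(ys)
  if (n < 8) stop("need at least 8 observations")
  m <- mean(ys)
  m2 <- mean((ys - m)^2)
  if (m2 == 0) stop("zero variance")
  S <- mean((ys - m)^3) / m2^1.5
  K <- mean((ys - m)^4) / m2^2
  JB <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = JB, p = stats::pchisq(JB, 2, lower.tail = FALSE),
       skewness = S, kurtosis = K, n = n)
}

#' Two-sample Smirnov test
#'
#' Maximum distance D between the empirical distribution functions of two
#' samples, with the two-sided p-value from the Kolmogorov asymptotic
#' distribution (ties handled by the underlying implementation).
#'
#' @param a,b numeric samples, both nonempty.
#' @return list: `D`, `p`.
#' @export
smirnov_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
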
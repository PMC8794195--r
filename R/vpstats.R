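#' Vysochanskij-Petunin tail bound
#'
#' For any unimodal distribution with mean mu and finite variance sigma^2,
#' P(|X - mu| >= lambda * sigma) <= 4 / (9 * lambda^2) whenever
#' lambda > sqrt(8/3). Below that threshold the theorem does not apply and
#' the probability is only bounded inside [1/6, 1] (the corollary regime).
#' The one-tailed bound halves the two-sided one by the symmetry
#' convention of the dimension-difference test.
#'
#' @param lam standardized deviation lambda > 0.
#' @param tails "two" (default) or "one".
#' @return a list: `lam`, `regime` ("theorem" or "corollary"), `bound`
#'   (a single probability in the theorem regime, the interval c(1/6, 1)
#'   in the corollary regime) and `tails`.
#' @export
vp_tail_bound <- function(lam, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (!is.finite(lam) || lam <= 0) stop("lambda must be positive")
  if (lam > vp_theorem_threshold()) {
    eps <- 4 / (9 * lam^2)
    list(lam = lam, regime = "theorem",
         bound = if (tails == "one") eps / 2 else eps, tails = tails)
  } else {
    list(lam = lam, regime = "corollary", bound = c(1 / 6, 1),
         tails = tails)
  }
}

#' @rdname vp_tail_bound
#' @details `vp_theorem_threshold()` returns sqrt(8/3) = 1.63299...,
#'   the lambda below which the theorem ceases to apply.
#' @export
vp_theorem_threshold <- function() sqrt(8 / 3)

#' Critical lambda of the Vysochanskij-Petunin test
#'
#' Inverts the tail bound at significance level alpha:
#' lambda = sqrt(4 / (9 * alpha)) for a two-tailed test
#' (sqrt(80/9) ~ 2.981 at alpha = 0.05) and
#' lambda = sqrt(2 / (9 * alpha)) for a one-tailed test
#' (sqrt(40/9) ~ 2.108 at alpha = 0.05).
#'
#' @param alpha significance level in (0, 0.5).
#' @param tails "one" (the default decision rule) or "two".
#' @return the critical lambda.
#' @export
vp_critical <- function(alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(alpha > 0, alpha < 0.5)
  if (tails == "one") sqrt(2 / (9 * alpha)) else sqrt(4 / (9 * alpha))
}

#' Distribution-free comparison of two Sevcik dimensions
#'
#' Tests whether two dimension estimates (ensemble means with total
#' variances, or single-series estimates with their within-trace
#' variances) differ, without assuming the sampling law of D_s:
#' lambda = |D1 - D2| / sqrt(var1 + var2) is referred to the
#' Vysochanskij-Petunin critical ratio. The default is the one-tailed rule
#' (lambda >= sqrt(2/(9 alpha))); in the corollary regime
#' (lambda <= sqrt(8/3)) the p-value is only bounded in [1/6, 1] and the
#' difference is never declared significant. The test is conservative:
#' a difference it declares significant is more significant than the bound
#' suggests.
#'
#' @param a,b each a list with elements `mean` and `var` (a
#'   `calibration_ensemble` or `sevcik_result` is accepted directly).
#' @param alpha significance level.
#' @param tails "one" (default) or "two".
#' @return list of class `vp_comparison`: `deltaD`, `s_delta`, `lam`,
#'   `regime`, `p_bound`, `critical`, `significant`, `alpha`, `tails`.
#' @export
compare_dimensions <- function(a, b, alpha = 0.05,
                               tails = c("one", "two")) {
  tails <- match.arg(tails)
  a <- as_dim_estimate(a)
  b <- as_dim_estimate(b)
  if (a$var <= 0 || b$var <= 0)
    stop("both dimension variances must be positive")
  deltaD <- a$mean - b$mean
  s_delta <- sqrt(a$var + b$var)
  lam <- abs(deltaD) / s_delta
  crit <- vp_critical(alpha, tails)
  if (lam > vp_theorem_threshold()) {
    regime <- "theorem"
    eps <- 4 / (9 * lam^2)
    p_bound <- if (tails == "one") eps / 2 else eps
  } else {
    regime <- "corollary"
    p_bound <- c(1 / 6, 1)
  }
  structure(list(deltaD = deltaD, s_delta = s_delta, lam = lam,
                 regime = regime, p_bound = p_bound, critical = crit,
                 significant = (regime == "theorem") && lam >= crit,
                 alpha = alpha, tails = tails),
            class = "vp_comparison")
}

as_dim_estimate <- function(x) {
  if (inherits(x, "calibration_ensemble"))
    return(list(mean = x$Dbar, var = x$var_total))
  if (inherits(x, "sevcik_result"))
    return(list(mean = x$Ds, var = x$varDs))
  stopifnot(is.list(x), !is.null(x$mean), !is.null(x$var))
  list(mean = x$mean, var = x$var)
}

#' @export
print.vp_comparison <- function(x, ...) {
  pb <- if (length(x$p_bound) == 2)
    sprintf("P in [%.3f, 1]", x$p_bound[1]) else sprintf("P <= %.4g", x$p_bound)
  cat(sprintf(
    "V-P comparison: dD = %.4g, s(dD) = %.4g, lambda = %.4g (%s regime), %s: %s\n",
    x$deltaD, x$s_delta, x$lam, x$regime, pb,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Cauchy density, distribution and quantile functions
#'
#' Closed forms for the heavy-tailed Cauchy law with location mu (its
#' median) and dispersion lambda > 0:
#' density c(x) = lambda / (pi * (lambda^2 + (x - mu)^2)), distribution
#' C(x) = arctan((x - mu)/lambda)/pi + 1/2, and the exact inverse of C.
#' The law has no moments: sample means and variances of Cauchy data do
#' not converge, which motivates the all-nonparametric toolbox. Its 95%
#' central interval is mu +- 12.706 * lambda.
#'
#' @param x numeric evaluation points.
#' @param q probabilities in (0, 1).
#' @param location median mu.
#' @param scale dispersion lambda > 0.
#' @return numeric vector.
#' @export
cauchy_pdf <- function(x, location = 0, scale = 1) {
  stopifnot(scale > 0)
  scale / (pi * (scale^2 + (x - location)^2))
}

#' @rdname cauchy_pdf
#' @export
cauchy_cdf <- function(x, location = 0, scale = 1) {
  stopifnot(scale > 0)
  atan((x - location) / scale) / pi + 0.5
}

#' @rdname cauchy_pdf
#' @export
cauchy_quantile <- function(q, location = 0, scale = 1) {
  stopifnot(scale > 0)
  if (any(q <= 0 | q >= 1)) stop("quantile probabilities must lie in (0, 1)")
  location + scale * tan(pi * (q - 0.5))
}
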
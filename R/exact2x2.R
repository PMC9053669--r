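#' Build a 2x2 carrier/non-carrier contingency table
#'
#' The four counts that drive every exact test in the package: carriers and
#' non-carriers of a qualifying CNV in the case (schizophrenia) and control
#' (non-psychotic) groups.
#'
#' @param a carriers in the case group.
#' @param b non-carriers in the case group.
#' @param c carriers in the control group.
#' @param d non-carriers in the control group.
#' @return An object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(69, 31, 58, 60)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("all four cells must be non-negative integers")
  structure(lapply(as.list(x), as.integer), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("CASE", "CONTROL"), c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

as_contingency_2x2 <- function(t) {
  if (inherits(t, "contingency_2x2")) return(t)
  if (is.numeric(t) && length(t) == 4L)
    return(contingency_2x2(t[[1]], t[[2]], t[[3]], t[[4]]))
  stop("expected a contingency_2x2 or a numeric vector (a, b, c, d)")
}

# Conditional model: with both margins fixed, the first cell a follows a
# noncentral hypergeometric distribution.  Parametrisation mirrors the
# classical one: x = a, m = a + c (first-column total), n = b + d,
# k = a + b (first-row total); support is [max(0, k - n), min(k, m)].
.cond_setup <- function(t) {
  m <- t$a + t$c
  n <- t$b + t$d
  k <- t$a + t$b
  lo <- max(0L, k - n)
  hi <- min(k, m)
  list(x = t$a, m = m, n = n, k = k, support = lo:hi, lo = lo, hi = hi)
}

# Noncentral hypergeometric pmf over the whole support at odds ratio psi.
.dnhyper <- function(s, psi) {
  logd <- stats::dhyper(s$support, s$m, s$n, s$k, log = TRUE)
  if (psi > 0) logd <- logd + s$support * log(psi) else logd[s$support > s$lo] <- -Inf
  d <- exp(logd - max(logd))
  d / sum(d)
}

.mnhyper <- function(s, psi) {
  if (psi == 0) return(s$lo)
  if (!is.finite(psi)) return(s$hi)
  sum(s$support * .dnhyper(s, psi))
}

.pnhyper <- function(s, q, psi, upper = FALSE) {
  d <- .dnhyper(s, psi)
  if (upper) sum(d[s$support >= q]) else sum(d[s$support <= q])
}

# Solve a monotone-in-log(psi) equation f(psi) = 0 by bisection on the log
# scale over [1e-12, 1e12]; the conditional expectation and both tail
# probabilities are strictly monotone in psi, so the root is unique.
.solve_psi <- function(f, tol = 1e-8) {
  lo <- log(1e-12); hi <- log(1e12)
  flo <- f(exp(lo)); fhi <- f(exp(hi))
  if (flo > 0 && fhi > 0) return(if (abs(flo) < abs(fhi)) 1e-12 else 1e12)
  if (flo < 0 && fhi < 0) return(if (abs(flo) < abs(fhi)) 1e-12 else 1e12)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(exp(mid))
    if (fm == 0) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if ((hi - lo) < tol * max(1, abs(mid))) break
  }
  exp((lo + hi) / 2)
}

#' Two-sided Fisher exact test p-value
#'
#' Sums, over all tables with the observed margins, the central hypergeometric
#' probabilities no larger than that of the observed table, with a relative
#' slack of `rel_eps` to absorb floating-point ties (the convention of the
#' standard R implementation).
#'
#' @param t a [contingency_2x2()] (or numeric `c(a, b, c, d)`).
#' @param rel_eps relative tie tolerance when comparing table probabilities.
#' @return The two-sided p-value.
#' @examples
#' fisher_two_sided(contingency_2x2(4, 96, 0, 118))  # 0.0428
#' @export
fisher_two_sided <- function(t, rel_eps = 1e-7) {
  t <- as_contingency_2x2(t)
  s <- .cond_setup(t)
  if (s$m == 0 || s$n == 0 || s$k == 0 || (t$c + t$d) == 0) {
    message("degenerate margin: p = 1 by convention")
    return(1)
  }
  d <- .dnhyper(s, 1)
  p <- sum(d[d <= d[s$x - s$lo + 1L] * (1 + rel_eps)])
  min(1, p)
}

#' Conditional maximum-likelihood odds ratio
#'
#' The odds ratio maximising the noncentral hypergeometric likelihood of the
#' observed table conditional on both margins — the estimate printed by the
#' standard exact-test implementation.  A zero first cell gives 0; a zero
#' fourth-cell side gives `Inf`.
#'
#' @inheritParams fisher_two_sided
#' @param tol relative root-finding tolerance.
#' @return The conditional-MLE odds ratio.
#' @examples
#' odds_ratio_cmle(contingency_2x2(69, 31, 58, 60))  # 2.29
#' @export
odds_ratio_cmle <- function(t, tol = 1e-8) {
  t <- as_contingency_2x2(t)
  s <- .cond_setup(t)
  if (s$lo == s$hi) {
    warning("degenerate margin: odds ratio undefined")
    return(NA_real_)
  }
  if (s$x == s$lo) return(0)
  if (s$x == s$hi) return(Inf)
  .solve_psi(function(psi) .mnhyper(s, psi) - s$x, tol = tol)
}

#' Exact confidence interval for the odds ratio
#'
#' Inverts the one-sided noncentral hypergeometric tail tests at `alpha/2`
#' per side.  A zero cell yields a one-sided interval (bound 0 or `Inf`).
#'
#' @inheritParams fisher_two_sided
#' @param alpha two-sided error level (default 0.05 for a 95% CI).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @examples
#' odds_ratio_ci_exact(contingency_2x2(69, 31, 58, 60))  # (1.27, 4.18)
#' @export
odds_ratio_ci_exact <- function(t, alpha = 0.05) {
  t <- as_contingency_2x2(t)
  stopifnot(alpha > 0, alpha < 1)
  s <- .cond_setup(t)
  if (s$lo == s$hi) return(c(0, Inf))
  lower <- if (s$x == s$lo) 0 else
    .solve_psi(function(psi) .pnhyper(s, s$x, psi, upper = TRUE) - alpha / 2)
  upper <- if (s$x == s$hi) Inf else
    .solve_psi(function(psi) .pnhyper(s, s$x, psi, upper = FALSE) - alpha / 2)
  c(ci_low = unname(lower), ci_high = unname(upper))
}

#' Full exact-test result for a 2x2 table
#'
#' Bundles the two-sided Fisher p-value, the conditional-MLE odds ratio and
#' the exact confidence interval into one result object.
#'
#' @inheritParams odds_ratio_ci_exact
#' @return An `exact_test_result` with elements `table`, `or`, `ci_low`,
#'   `ci_high`, `p`, `alpha`.
#' @examples
#' exact_test_2x2(contingency_2x2(11, 89, 4, 114))
#' @export
exact_test_2x2 <- function(t, alpha = 0.05) {
  t <- as_contingency_2x2(t)
  ci <- odds_ratio_ci_exact(t, alpha)
  structure(list(table = t,
                 or = odds_ratio_cmle(t),
                 ci_low = ci[[1]], ci_high = ci[[2]],
                 p = fisher_two_sided(t),
                 alpha = alpha),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat(sprintf("OR = %.2f [%d%% CI = %.2f-%.2f], p = %.4f\n",
              x$or, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Order-preserving step-up adjustment; applied within declared test families
#' throughout the package (gene-set categories, miRNA attribution sets).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
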
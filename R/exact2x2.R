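# Exact conditional inference for 2x2 allele-count tables.
#
# Conditioning on both margins of the table
#
#              minor  major
#   cases        a      b     | m = a + b
#   controls     c      d     | n = c + d
#                k = a + c
#
# leaves a one-dimensional family: the count in cell `a` follows a (central
# or noncentral) hypergeometric distribution whose noncentrality parameter is
# the odds ratio.  Everything in this file -- two-sided p-values, conditional
# MLE odds ratio, and confidence intervals by test inversion -- is computed by
# explicit enumeration of that conditional support, in log space so large
# cohort tables do not overflow.

# Relative tie tolerance used when summing outcomes "no more likely than
# observed" (minlike) or "no more acceptable" (Blaker).  This is the de facto
# convention for exact two-sided tests on discrete data.
.TIE_TOL <- 1 + 1e-7

# Maximum table total for which enumeration is attempted.
.MAX_TOTAL <- 1e6

#' Build a 2x2 allele-count table
#'
#' Assembles the case/control by minor/major allele contingency table from two
#' [allele_count()] objects: `a` = case minor alleles, `b` = case major
#' alleles, `c` = control minor alleles, `d` = control major alleles.
#'
#' @param case,control objects of class `allele_count` (see [allele_count()]).
#' @return An object of class `two_by_two`: a named integer vector
#'   `c(a, b, c, d)`.
#' @examples
#' build_table(allele_count(15, 612), allele_count(4, 740))
#' @export
build_table <- function(case, control) {
  case <- as_allele_count(case)
  control <- as_allele_count(control)
  tab <- c(a = case$minor, b = case$total - case$minor,
           c = control$minor, d = control$total - control$minor)
  structure(as.integer(tab), names = names(tab), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("case", "control"), c("minor", "major")))
  print(m)
  invisible(x)
}

# Accept a two_by_two or any numeric (a, b, c, d) of length 4.
as_table4 <- function(table) {
  x <- as.numeric(unclass(table))
  if (length(x) != 4L || anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop("table must be four non-negative integer cells (a, b, c, d)",
         call. = FALSE)
  if (sum(x) > .MAX_TOTAL)
    stop("table total exceeds ", format(.MAX_TOTAL, scientific = FALSE),
         "; enumeration refused", call. = FALSE)
  names(x) <- c("a", "b", "c", "d")
  x
}

# Conditional support and log pmf of cell `a` given margins, at odds ratio
# `or`.  Returns list(xs, logp) with logp normalised to sum to one.
cond_support <- function(tab, or = 1) {
  m <- tab[["a"]] + tab[["b"]]
  n <- tab[["c"]] + tab[["d"]]
  k <- tab[["a"]] + tab[["c"]]
  xs <- max(0, k - n):min(m, k)
  if (or < 0) stop("odds ratio must be non-negative", call. = FALSE)
  if (or == 0) {
    logp <- rep(-Inf, length(xs))
    logp[1L] <- 0
  } else if (is.infinite(or)) {
    logp <- rep(-Inf, length(xs))
    logp[length(xs)] <- 0
  } else {
    lg <- lchoose(m, xs) + lchoose(n, k - xs) + xs * log(or)
    lg <- lg - max(lg)
    logp <- lg - log(sum(exp(lg)))
  }
  list(xs = xs, logp = logp)
}

# Two-sided p-values on a precomputed support, vectorised over methods.
p_from_support <- function(sup, a, methods) {
  p <- exp(sup$logp)
  i <- match(a, sup$xs)
  lower <- cumsum(p)
  upper <- rev(cumsum(rev(p)))
  vapply(methods, function(method) {
    switch(method,
      minlike = min(1, sum(p[p <= p[i] * .TIE_TOL])),
      central = min(1, 2 * min(lower[i], upper[i])),
      blaker = {
        acc <- pmin(lower, upper)
        min(1, sum(p[acc <= acc[i] * .TIE_TOL]))
      },
      stop("unknown method: ", method, call. = FALSE))
  }, numeric(1))
}

check_margins <- function(tab, rows_only = FALSE) {
  if (tab[["a"]] + tab[["b"]] == 0 || tab[["c"]] + tab[["d"]] == 0)
    stop("both row margins of the table must be positive for exact inference",
         call. = FALSE)
  if (!rows_only &&
      (tab[["a"]] + tab[["c"]] == 0 || tab[["b"]] + tab[["d"]] == 0))
    stop("all four margins of the table must be positive for exact inference",
         call. = FALSE)
  invisible(tab)
}

#' Exact conditional two-sided p-value for a 2x2 table
#'
#' Computes the exact two-sided p-value for association in a 2x2 allele-count
#' table by enumerating the hypergeometric distribution of the `a` cell
#' conditional on both margins, under odds ratio `or` (default 1, the null of
#' no association).  Three standard two-sided constructions are available:
#'
#' * `"minlike"` -- sum of probabilities of all outcomes no more likely than
#'   the observed one (the classical Fisher two-sided rule);
#' * `"central"` -- twice the smaller conditional tail, capped at 1;
#' * `"blaker"` -- Blaker's acceptability method (sum over outcomes whose
#'   smaller tail is no larger than that of the observed outcome).
#'
#' @param table a `two_by_two` from [build_table()] or a numeric vector
#'   `c(a, b, c, d)` of cell counts.
#' @param method character vector of methods; if more than one is given a
#'   named vector of p-values is returned.
#' @param or odds-ratio value at which the conditional null is evaluated.
#' @return p-value(s) in `(0, 1]`, named by method when several are requested.
#' @examples
#' fisher_exact_p(c(15, 597, 4, 736))                     # 0.0041
#' fisher_exact_p(c(2, 8, 1, 9), c("minlike", "central", "blaker"))
#' @seealso [exact_or_ci()], [odds_ratio()]
#' @export
fisher_exact_p <- function(table, method = "minlike", or = 1) {
  tab <- as_table4(table)
  # a zero column margin leaves a one-point support: p = 1, still defined
  check_margins(tab, rows_only = TRUE)
  method <- match.arg(method, c("minlike", "central", "blaker"),
                      several.ok = TRUE)
  sup <- cond_support(tab, or = or)
  out <- p_from_support(sup, tab[["a"]], method)
  if (length(method) == 1L) unname(out) else out
}

#' Odds ratio of a 2x2 table
#'
#' @param table a `two_by_two` or numeric `c(a, b, c, d)`.
#' @param estimator `"sample"` for the cross-product ratio `ad / bc`, or
#'   `"cmle"` for the conditional maximum-likelihood estimate: the odds-ratio
#'   value under which the expected value of the noncentral hypergeometric
#'   distribution (conditional on the table margins) equals the observed `a`
#'   cell.  Zero cells give 0 or `Inf` for the sample estimator (flagged via
#'   the `"zero_cell"` attribute); for the CMLE the boundary outcomes of the
#'   conditional support give 0 or `Inf`.
#' @return A single numeric odds ratio.
#' @examples
#' odds_ratio(c(15, 597, 4, 736))            # 4.62
#' odds_ratio(c(15, 597, 48, 4358))          # 2.28
#' odds_ratio(c(15, 597, 4, 736), "cmle")
#' @export
odds_ratio <- function(table, estimator = c("sample", "cmle")) {
  tab <- as_table4(table)
  estimator <- match.arg(estimator)
  a <- tab[["a"]]; b <- tab[["b"]]; c <- tab[["c"]]; d <- tab[["d"]]
  if (estimator == "sample") {
    if (b * c == 0 && a * d == 0)
      return(structure(NaN, zero_cell = TRUE))
    if (b * c == 0) return(structure(Inf, zero_cell = TRUE))
    if (a * d == 0) return(structure(0, zero_cell = TRUE))
    return((a * d) / (b * c))
  }
  check_margins(tab)
  sup <- cond_support(tab)
  if (a == min(sup$xs)) return(0)
  if (a == max(sup$xs)) return(Inf)
  # E_theta[X] is strictly increasing in theta; solve E_theta[X] = a by
  # root-finding on log(theta).
  escore <- function(lth) {
    s <- cond_support(tab, exp(lth))
    sum(s$xs * exp(s$logp)) - a
  }
  bracket <- expand_bracket(escore, log(max((a * d) / (b * c), 1e-8)))
  r <- stats::uniroot(escore, bracket, tol = 1e-10)
  exp(r$root)
}

# Expand outwards from `center` (both directions) until f changes sign;
# works for monotone f of either orientation.
expand_bracket <- function(f, center, step = 1, max_width = 80) {
  f0 <- f(center)
  if (f0 == 0) return(c(center - 1e-12, center + 1e-12))
  last <- c(center, center)  # last probed point on each side
  for (w in seq(step, max_width, by = step)) {
    for (s in 1:2) {
      x <- center + c(1, -1)[s] * w
      if (sign(f(x)) != sign(f0)) return(sort(c(last[s], x)))
      last[s] <- x
    }
  }
  stop("root bracketing failed", call. = FALSE)
}

#' Exact odds-ratio confidence interval by test inversion
#'
#' Inverts the chosen two-sided exact test over the odds-ratio parameter of
#' the noncentral hypergeometric distribution: the interval is the outer hull
#' of odds-ratio values whose two-sided p-value exceeds `1 - level`.  For the
#' `"central"` method this is equivalent to inverting the two one-sided tail
#' tests at `(1 - level)/2` each (the interval reported by
#' [stats::fisher.test()]); `"minlike"` and `"blaker"` invert their matching
#' two-sided p-value functions and give intervals consistent with those
#' p-values.  When the observed `a` cell sits on the boundary of the
#' conditional support the corresponding limit is 0 or `Inf`.
#'
#' @inheritParams fisher_exact_p
#' @param level confidence level in (0, 1).
#' @param method one of `"minlike"`, `"central"`, `"blaker"`.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' exact_or_ci(c(15, 597, 4, 736))                 # 1.51 - 15.20
#' exact_or_ci(c(15, 597, 48, 4358))               # 1.26 - 4.10
#' exact_or_ci(c(15, 597, 4, 736), method = "central")
#' @export
exact_or_ci <- function(table, level = 0.95,
                        method = c("minlike", "central", "blaker")) {
  tab <- as_table4(table)
  check_margins(tab)
  method <- match.arg(method)
  stopifnot(is_fraction(level), level > 0, level < 1)
  alpha <- 1 - level
  a <- tab[["a"]]
  sup0 <- cond_support(tab)
  at_min <- a == min(sup0$xs)
  at_max <- a == max(sup0$xs)

  if (method == "central") {
    lower_tail <- function(lth)  # P(X >= a | theta) - alpha/2
      sum(exp(cond_support(tab, exp(lth))$logp)[sup0$xs >= a]) - alpha / 2
    upper_tail <- function(lth)  # P(X <= a | theta) - alpha/2
      sum(exp(cond_support(tab, exp(lth))$logp)[sup0$xs <= a]) - alpha / 2
    lower <- if (at_min) 0 else
      exp(stats::uniroot(lower_tail, expand_bracket(lower_tail, or_center(tab)),
                         tol = 1e-8)$root)
    upper <- if (at_max) Inf else
      exp(stats::uniroot(upper_tail, expand_bracket(upper_tail, or_center(tab)),
                         tol = 1e-8)$root)
    return(c(lower = lower, upper = upper))
  }

  # minlike / blaker: p(theta) is near-unimodal in theta but not monotone;
  # take the outermost crossings of p(theta) = alpha, scanning inwards from
  # far outside so the hull of the acceptance region is returned.
  pfun <- function(lth) p_from_support(cond_support(tab, exp(lth)), a, method)
  lower <- if (at_min) 0 else
    exp(outer_crossing(pfun, alpha, or_center(tab), side = "lower"))
  upper <- if (at_max) Inf else
    exp(outer_crossing(pfun, alpha, or_center(tab), side = "upper"))
  c(lower = lower, upper = upper)
}

# A log-odds-ratio value well inside the acceptance region.
or_center <- function(tab) {
  a <- tab[["a"]] + 0.5; b <- tab[["b"]] + 0.5
  c <- tab[["c"]] + 0.5; d <- tab[["d"]] + 0.5
  log((a * d) / (b * c))
}

# Outermost solution of p(log theta) = alpha on the given side of `center`.
# Scans outwards in unit steps until p < alpha, then walks back in and
# refines the first crossing encountered from outside.
outer_crossing <- function(pfun, alpha, center, side, step = 0.5,
                           max_width = 120) {
  dir <- if (side == "lower") -1 else 1
  prev <- center
  far <- NA_real_
  for (w in seq(step, max_width, by = step)) {
    x <- center + dir * w
    if (pfun(x) < alpha) { far <- x; break }
    prev <- x
  }
  if (is.na(far)) stop("confidence bound bracketing failed", call. = FALSE)
  # scan back inwards from `far` to find the outermost sub-interval where the
  # p-value function re-crosses alpha
  xs <- seq(far, prev, by = -dir * step / 4)
  hit <- NA_real_
  for (i in seq_along(xs)[-1L]) {
    if (pfun(xs[i]) >= alpha) { hit <- i; break }
  }
  if (is.na(hit)) { lo <- min(far, prev); hi <- max(far, prev) }
  else { lo <- min(xs[hit], xs[hit - 1L]); hi <- max(xs[hit], xs[hit - 1L]) }
  f <- function(x) pfun(x) - alpha
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Exact two-sided binomial test p-value
#'
#' Minimum-likelihood two-sided exact binomial p-value: the sum of
#' probabilities of all outcomes no more likely than the observed count under
#' `Binomial(n, p0)` (the construction used by [stats::binom.test()]).
#'
#' @param k observed count of successes.
#' @param n number of trials (must be positive).
#' @param p0 null success probability, strictly inside (0, 1).
#' @return p-value in `(0, 1]`.
#' @examples
#' binomial_two_sided(9, 10, 0.5)   # 22/1024
#' @export
binomial_two_sided <- function(k, n, p0) {
  stopifnot(is_count(k), is_count(n), is.numeric(p0), length(p0) == 1L)
  if (n == 0) stop("n must be positive", call. = FALSE)
  if (k > n) stop("k cannot exceed n", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly inside (0, 1)",
                               call. = FALSE)
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1L] * .TIE_TOL]))
}
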
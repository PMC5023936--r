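# Allele counting, LD, covariate comparison, logistic confounding check and
# subcohort homogeneity.

#' Allele counts
#'
#' `allele_count()` constructs an allele count directly; `allele_counts()`
#' tallies one from a vector of diploid genotype calls (alt-allele dosages
#' 0/1/2, `NA` for missing).  Missing calls are excluded from the
#' denominator, so `total = 2 * (number of non-missing subjects)`.
#'
#' @param minor minor-allele count.
#' @param total total allele count (2 per non-missing diploid subject).
#' @param calls vector of genotype calls in `{0, 1, 2, NA}`.
#' @return An object of class `allele_count`: `list(minor, total)`.
#' @examples
#' ac <- allele_counts(c(rep(1, 48), rep(0, 2155)))
#' maf(ac)  # 48 / 4406 = 0.0109
#' @export
allele_count <- function(minor, total) {
  stopifnot(is_count(minor), is_count(total), minor <= total)
  structure(list(minor = as.integer(minor), total = as.integer(total)),
            class = "allele_count")
}

#' @rdname allele_count
#' @export
allele_counts <- function(calls) {
  check_calls(calls)
  n_obs <- sum(!is.na(calls))
  if (n_obs == 0) stop("all genotype calls are missing", call. = FALSE)
  allele_count(sum(calls, na.rm = TRUE), 2L * n_obs)
}

as_allele_count <- function(x) {
  if (inherits(x, "allele_count")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(allele_count(x[[1]], x[[2]]))
  stop("expected an allele_count or numeric c(minor, total)", call. = FALSE)
}

#' @rdname allele_count
#' @param x an `allele_count`.
#' @export
maf <- function(x) {
  x <- as_allele_count(x)
  x$minor / x$total
}

#' @export
print.allele_count <- function(x, ...) {
  cat(sprintf("allele count: %d / %d (MAF = %.4g)\n",
              x$minor, x$total, maf(x)))
  invisible(x)
}

#' Exact association summary for a 2x2 table
#'
#' Bundles the default inference for one case/control (or case/background)
#' comparison: two-sided exact p-value, sample and conditional-MLE odds
#' ratios, and a test-inversion confidence interval.
#'
#' @inheritParams fisher_exact_p
#' @param level confidence level for the interval.
#' @param ci_method two-sided construction inverted for the interval.
#' @param method two-sided p-value construction.
#' @return An object of class `assoc_result` with fields `table`, `p_value`,
#'   `p_method`, `or_sample`, `or_cmle`, `ci`, `ci_level`, `ci_method`.
#' @examples
#' associate_table(c(15, 597, 4, 736))
#' @export
associate_table <- function(table, method = "minlike", ci_method = "minlike",
                            level = 0.95) {
  tab <- as_table4(table)
  structure(list(
    table = tab,
    p_value = fisher_exact_p(tab, method = method),
    p_method = method,
    or_sample = as.numeric(odds_ratio(tab, "sample")),
    or_cmle = odds_ratio(tab, "cmle"),
    ci = unname(exact_or_ci(tab, level = level, method = ci_method)),
    ci_level = level,
    ci_method = ci_method
  ), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf(
    "exact 2x2 association (a=%d b=%d c=%d d=%d)\n  P = %.4g (%s)\n  OR = %.3g (sample), %.3g (cmle)\n  %d%% CI: %.3g - %.3g (%s)\n",
    x$table[1], x$table[2], x$table[3], x$table[4], x$p_value, x$p_method,
    x$or_sample, x$or_cmle, round(100 * x$ci_level), x$ci[1], x$ci[2],
    x$ci_method))
  invisible(x)
}

#' Linkage-disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of alt-allele dosage vectors over subjects
#' with non-missing calls at both variants (the composite, genotype-based
#' r-squared computed on unphased data).
#'
#' @param calls_x,calls_y genotype call vectors (0/1/2/NA) of equal length.
#' @return list with `r_squared` and `n` (subjects used).
#' @examples
#' ld_r2(c(0, 0, 1, 1), c(1, 1, 0, 0))$r_squared  # 1
#' @export
ld_r2 <- function(calls_x, calls_y) {
  check_calls(calls_x); check_calls(calls_y)
  if (length(calls_x) != length(calls_y))
    stop("call vectors must have equal length", call. = FALSE)
  ok <- !is.na(calls_x) & !is.na(calls_y)
  if (sum(ok) < 2)
    stop("need at least 2 subjects with calls at both variants",
         call. = FALSE)
  x <- calls_x[ok]; y <- calls_y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined r-squared: variant monomorphic among complete pairs",
         call. = FALSE)
  structure(list(r_squared = stats::cor(x, y)^2, n = sum(ok)),
            class = "ld_result")
}

#' Logistic regression confounding check
#'
#' Fits case/control status on a predictor matrix by maximum likelihood
#' (iteratively reweighted least squares via [stats::glm()]) and reports
#' per-coefficient Wald statistics.  Convergence requires the score (the
#' log-likelihood gradient, normalised per unit predictor L1 norm so the
#' tolerance is scale-free) to fall below 1e-8 within 100 iterations.  Rows
#' with any missing predictor are excluded and counted.  Perfect separation
#' is detected (diverging
#' coefficients with degenerate fitted probabilities) and flagged; no
#' estimates are reported in that case.
#'
#' @param x numeric predictor matrix or data frame (no intercept column; one
#'   is added).
#' @param y binary case indicator (0/1 or logical), same length as
#'   `nrow(x)`.
#' @return An object of class `logistic_fit`: `coefficients` data frame
#'   (`estimate`, `se`, `z`, `p`), `converged`, `separated`, `iterations`,
#'   `n_used`, `n_excluded`, `max_score`.
#' @examples
#' set.seed(1)
#' x <- cbind(carrier = rbinom(200, 1, 0.1), height = rnorm(200, 170, 10))
#' y <- rbinom(200, 1, plogis(-0.5 + 0.8 * x[, 1]))
#' logistic_fit(x, y)
#' @export
logistic_fit <- function(x, y) {
  x <- as.data.frame(x)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  complete <- if (ncol(x) == 0) !is.na(y)
              else stats::complete.cases(x) & !is.na(y)
  n_excluded <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  y <- y[complete]
  if (nrow(x) <= ncol(x) + 1L)
    stop("need more observations than parameters", call. = FALSE)
  if (ncol(x) > 0) {
    const <- vapply(x, function(col) stats::var(as.numeric(col)) == 0,
                    logical(1))
    if (any(const))
      stop("constant predictor(s): ",
           paste(names(x)[const], collapse = ", "), call. = FALSE)
  }

  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(),
               data = cbind(y = y, x),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  X <- stats::model.matrix(fit)
  mu <- fit$fitted.values
  # score (log-likelihood gradient) per unit column L1 norm: an absolute
  # tolerance on the raw score is meaningless across covariate scales
  score <- abs(crossprod(X, y - mu))
  max_score <- max(score / pmax(1, colSums(abs(X))))
  separated <- sep_warned && max(abs(beta)) > 10
  converged <- fit$converged && max_score < 1e-8 && !separated

  if (separated) {
    return(structure(list(coefficients = NULL, converged = FALSE,
                          separated = TRUE, iterations = fit$iter,
                          n_used = nrow(x), n_excluded = n_excluded,
                          max_score = max_score),
                     class = "logistic_fit"))
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL)
  structure(list(coefficients = coefs, converged = converged,
                 separated = FALSE, iterations = fit$iter,
                 n_used = nrow(x), n_excluded = n_excluded,
                 max_score = max_score),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$separated) {
    cat("logistic fit: perfect separation detected; no estimates\n")
  } else {
    cat(sprintf("logistic fit (n = %d, %d excluded for missingness):\n",
                x$n_used, x$n_excluded))
    print(x$coefficients, digits = 4)
  }
  invisible(x)
}

#' Compare covariates between cases and controls
#'
#' Continuous covariates are compared with a two-sided Welch t-test;
#' categorical covariates with an exact test on the arm-by-level contingency
#' table (the conditional minlike test for 2x2 tables,
#' [stats::fisher.test()] for more levels).  Covariates constant in both arms
#' are skipped with a note.
#'
#' @param cases,controls data frames with identical covariate columns (one
#'   row per subject).
#' @return data frame with one row per covariate: `covariate`, `type`,
#'   `test`, `case_summary`, `control_summary`, `statistic`, `p`, `note`.
#' @export
compare_covariates <- function(cases, controls) {
  shared <- intersect(names(cases), names(controls))
  if (length(shared) == 0) stop("no shared covariates", call. = FALSE)
  rows <- lapply(shared, function(v) {
    xc <- cases[[v]]; xk <- controls[[v]]
    if (is.numeric(xc)) {
      if (stats::var(xc, na.rm = TRUE) == 0 &&
          stats::var(xk, na.rm = TRUE) == 0)
        return(data.frame(covariate = v, type = "continuous", test = NA,
                          case_summary = mean(xc, na.rm = TRUE),
                          control_summary = mean(xk, na.rm = TRUE),
                          statistic = NA_real_, p = NA_real_,
                          note = "constant in both arms; skipped"))
      tt <- stats::t.test(xc, xk)  # Welch by default
      data.frame(covariate = v, type = "continuous", test = "welch_t",
                 case_summary = mean(xc, na.rm = TRUE),
                 control_summary = mean(xk, na.rm = TRUE),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 note = NA_character_)
    } else {
      lev <- sort(unique(c(as.character(xc), as.character(xk))))
      if (length(lev) < 2)
        return(data.frame(covariate = v, type = "categorical", test = NA,
                          case_summary = NA_real_, control_summary = NA_real_,
                          statistic = NA_real_, p = NA_real_,
                          note = "constant in both arms; skipped"))
      tc <- table(factor(xc, lev)); tk <- table(factor(xk, lev))
      p <- if (length(lev) == 2L) {
        fisher_exact_p(c(tc[1], tc[2], tk[1], tk[2]))
      } else {
        stats::fisher.test(rbind(tc, tk))$p.value
      }
      data.frame(covariate = v, type = "categorical", test = "exact",
                 case_summary = unname(tc[1] / sum(tc)),
                 control_summary = unname(tk[1] / sum(tk)),
                 statistic = NA_real_, p = p, note = NA_character_)
    }
  })
  do.call(rbind, rows)
}

#' Subcohort homogeneity of allele counts
#'
#' Tests, within each arm, whether the minor-allele frequency differs between
#' subcohorts: all pairwise exact tests on the per-subcohort allele counts.
#'
#' @param tables named list (length >= 2) of `two_by_two` tables, one per
#'   subcohort (`a`/`b` case alleles, `c`/`d` control alleles).
#' @param method two-sided exact p-value construction.
#' @return data frame with columns `arm`, `cohort1`, `cohort2`, `p`.
#' @export
subcohort_homogeneity <- function(tables, method = "minlike") {
  if (length(tables) < 2)
    stop("need at least two subcohorts", call. = FALSE)
  tabs <- lapply(tables, as_table4)
  nm <- names(tabs) %||% as.character(seq_along(tabs))
  pairs <- utils::combn(seq_along(tabs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    do.call(rbind, lapply(c(case = 1, control = 3), function(off) {
      t4 <- c(tabs[[i1]][off], tabs[[i1]][off + 1],
              tabs[[i2]][off], tabs[[i2]][off + 1])
      # a zero column margin (e.g. no minor alleles in either subcohort)
      # makes the conditional distribution degenerate: p = 1
      p <- if (t4[1] + t4[3] == 0 || t4[2] + t4[4] == 0) 1
           else fisher_exact_p(t4, method = method)
      data.frame(arm = if (off == 1) "case" else "control",
                 cohort1 = nm[i1], cohort2 = nm[i2], p = p)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
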
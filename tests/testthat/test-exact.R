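# Exact conditional 2x2 inference: p-values, odds ratios, intervals.

test_that("degenerate support gives p = 1 for every method", {
  for (m in c("minlike", "central", "blaker"))
    expect_equal(fisher_exact_p(c(0, 10, 0, 10), method = m), 1)
})

test_that("small-table p-values match full-support enumeration", {
  # (2, 8, 1, 9): support has 4 outcomes; every outcome is no more likely
  # than the observed one, so the minlike p-value is exactly 1
  expect_equal(fisher_exact_p(c(2, 8, 1, 9), "minlike"), 1)
  set.seed(42)
  for (i in 1:50) {
    t4 <- random_table()
    p <- fisher_exact_p(t4, c("minlike", "central", "blaker"))
    for (m in names(p))
      expect_equal(p[[m]], oracle_p(t4[1], t4[2], t4[3], t4[4], m),
                   tolerance = 1e-12, label = paste(m, toString(t4)))
  }
})

test_that("minlike p agrees with stats::fisher.test", {
  tabs <- list(c(15, 597, 4, 736), c(15, 597, 48, 4358), c(3, 7, 6, 4),
               c(1, 19, 5, 15), c(12, 2, 3, 11))
  for (t4 in tabs) {
    expect_equal(fisher_exact_p(t4),
                 fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("worked case-control example reproduces printed statistics", {
  t4 <- c(15, 597, 4, 736)
  expect_equal(round(fisher_exact_p(t4), 4), 0.0041)
  expect_equal(round(odds_ratio(t4), 2), 4.62)
  expect_equal(round(unname(exact_or_ci(t4)), 2), c(1.51, 15.20))
})

test_that("worked case-background example reproduces printed statistics", {
  t4 <- c(15, 597, 48, 4358)
  expect_equal(round(fisher_exact_p(t4), 3), 0.010)
  expect_equal(round(odds_ratio(t4), 2), 2.28)
  expect_equal(round(unname(exact_or_ci(t4)), 2), c(1.26, 4.10))
})

test_that("central CI and conditional MLE agree with stats::fisher.test", {
  set.seed(7)
  tabs <- c(list(c(15, 597, 4, 736), c(5, 15, 9, 11)),
            replicate(10, random_table(), simplify = FALSE))
  for (t4 in tabs) {
    ft <- fisher.test(matrix(t4, 2, byrow = TRUE))
    # fisher.test's interval comes from uniroot at its default tolerance
    # (eps^0.25), so agreement beyond ~1e-2 on the log-odds scale cannot
    # be expected (its bounds miss the 0.025 tail equation by ~1e-4)
    expect_equal(log(unname(exact_or_ci(t4, method = "central"))),
                 log(as.numeric(ft$conf.int)), tolerance = 1e-2,
                 label = toString(t4))
    expect_equal(log(odds_ratio(t4, "cmle")), log(unname(ft$estimate)),
                 tolerance = 1e-3, label = toString(t4))
  }
})

test_that("sample odds ratio handles symmetry and zero cells", {
  expect_equal(odds_ratio(c(5, 5, 5, 5)), 1)
  expect_equal(odds_ratio(c(5, 5, 5, 5), "cmle"), 1, tolerance = 1e-8)
  or_inf <- odds_ratio(c(5, 0, 3, 7))
  expect_identical(as.numeric(or_inf), Inf)
  expect_true(attr(or_inf, "zero_cell"))
  expect_equal(as.numeric(odds_ratio(c(0, 5, 3, 7))), 0)
})

test_that("CMLE sits on the conditional score root and boundaries", {
  # boundary outcomes of the support give 0 / Inf
  expect_equal(odds_ratio(c(0, 10, 5, 5), "cmle"), 0)
  expect_equal(odds_ratio(c(5, 5, 0, 10), "cmle"), Inf)
  # interior: conditional expectation at the root equals the observed cell
  t4 <- c(7, 13, 3, 17)
  or <- odds_ratio(t4, "cmle")
  s <- oracle_hyper_pmf(t4[1], t4[2], t4[3], t4[4])
  w <- s$p * or^s$xs
  expect_equal(sum(s$xs * w / sum(w)), t4[1], tolerance = 1e-7)
})

test_that("sample OR is monotone in the a cell at fixed margins", {
  ors <- sapply(1:9, function(a) odds_ratio(c(a, 10 - a, 5, 15)))
  expect_true(all(diff(ors) > 0))
})

test_that("CI boundary rules: support edges give 0 and Inf limits", {
  ci <- exact_or_ci(c(0, 10, 5, 5))
  expect_equal(unname(ci[1]), 0)
  ci <- exact_or_ci(c(10, 0, 5, 5))
  expect_equal(unname(ci[2]), Inf)
})

test_that("Blaker p is never larger than central p", {
  set.seed(11)
  for (i in 1:200) {
    t4 <- random_table()
    p <- fisher_exact_p(t4, c("blaker", "central"))
    expect_lte(p[["blaker"]], p[["central"]] + 1e-12)
  }
})

test_that("minlike can exceed central only through probability ties or
           mode effects, never on one-sided-extreme tables", {
  # (0, 3, 4, 11) has tied boundary outcome probabilities: the minlike sum
  # picks up the whole support (p = 1) while the doubled tail is 0.892 --
  # the two constructions are genuinely unordered
  p <- fisher_exact_p(c(0, 3, 4, 11), c("minlike", "central"))
  expect_equal(p[["minlike"]], 1)
  expect_equal(p[["central"]], 2 * choose(15, 4) / choose(18, 4))
})

test_that("test/CI duality holds for each method on random tables", {
  set.seed(3)
  for (i in 1:60) {
    t4 <- random_table(10)
    for (m in c("minlike", "central", "blaker")) {
      p1 <- fisher_exact_p(t4, m)
      ci <- exact_or_ci(t4, level = 0.95, method = m)
      inside <- ci[1] <= 1 && 1 <= ci[2]
      expect_equal(p1 >= 0.05, inside,
                   label = paste(m, toString(t4), "p =", signif(p1, 4)))
    }
  }
})

test_that("exact binomial test matches enumeration and binom.test", {
  expect_equal(binomial_two_sided(5, 10, 0.5), 1)
  expect_equal(binomial_two_sided(9, 10, 0.5), 22 / 1024)
  expect_equal(binomial_two_sided(0, 1, 0.5), 1)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(1:30, 1); k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_two_sided(k, n, p0), oracle_binom_p(k, n, p0),
                 tolerance = 1e-12)
    expect_equal(binomial_two_sided(k, n, p0),
                 binom.test(k, n, p0)$p.value, tolerance = 1e-12)
  }
  expect_error(binomial_two_sided(1, 0, 0.5), "positive")
  expect_error(binomial_two_sided(2, 10, 1), "strictly inside")
})

test_that("invalid tables and empty margins are rejected", {
  expect_error(fisher_exact_p(c(1, 2, 3)), "four")
  expect_error(fisher_exact_p(c(-1, 2, 3, 4)), "four")
  expect_error(fisher_exact_p(c(0, 0, 1, 2)), "margins")
  expect_error(odds_ratio(c(0, 0, 1, 2), "cmle"), "margins")
  expect_error(fisher_exact_p(c(6e5, 6e5, 1, 2)), "enumeration refused")
})
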
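# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: probabilities come from direct choose() ratios,
# intervals from quadratic scans, statistics from textbook formulas.

# Central hypergeometric pmf over the full conditional support of a 2x2
# table, by explicit binomial-coefficient ratios.
oracle_hyper_pmf <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(m, k)
  p <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  list(xs = xs, p = p)
}

# Two-sided exact p-values by full-support summation.
oracle_p <- function(a, b, c, d, method) {
  s <- oracle_hyper_pmf(a, b, c, d)
  i <- match(a, s$xs)
  lower <- sum(s$p[s$xs <= a])
  upper <- sum(s$p[s$xs >= a])
  switch(method,
    minlike = min(1, sum(s$p[s$p <= s$p[i] * (1 + 1e-7)])),
    central = min(1, 2 * min(lower, upper)),
    blaker = {
      acc <- pmin(cumsum(s$p), rev(cumsum(rev(s$p))))
      min(1, sum(s$p[acc <= acc[i] * (1 + 1e-7)]))
    })
}

oracle_binom_p <- function(k, n, p0) {
  d <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - 0:n)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

# Quadratic scan: which 1-based positions fall in any half-open BED region.
oracle_in_regions <- function(variants, regions) {
  vapply(seq_len(nrow(variants)), function(i) {
    any(regions$chrom == variants$chrom[i] &
        variants$pos[i] > regions$start &
        variants$pos[i] <= regions$end)
  }, logical(1))
}

# Random small 2x2 table with all margins positive.
random_table <- function(max_cell = 15) {
  repeat {
    t4 <- c(sample(0:max_cell, 2, replace = TRUE),
            sample(0:max_cell, 2, replace = TRUE))
    if (t4[1] + t4[2] > 0 && t4[3] + t4[4] > 0 &&
        t4[1] + t4[3] > 0 && t4[2] + t4[4] > 0) return(t4)
  }
}

# Small hand-built variant fixture shared by io/filter tests.
make_variants <- function(n, chrom = "chr3", start = 1, end = 1e6) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  data.frame(chrom = rep(chrom, n),
             pos = if (n) sort(sample(start:end, n)) else integer(),
             id = sprintf("v%03d", seq_len(n)), ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}
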
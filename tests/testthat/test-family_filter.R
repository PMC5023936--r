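# The discovery cascade and its component filters.

three_member_gt <- function(patterns, ids) {
  m <- do.call(rbind, patterns)
  dimnames(m) <- list(ids, paste0("member", 1:3))
  m
}

test_that("shared-heterozygote filter keeps only the all-het pattern", {
  # enumerate all 4^3 call patterns over three members: only (1,1,1)
  # survives; any homozygote or missing call excludes the variant
  states <- c(0L, 1L, 2L, NA_integer_)
  grid <- expand.grid(a = states, b = states, c = states)
  v <- make_variants(nrow(grid))
  gt <- three_member_gt(lapply(seq_len(nrow(grid)),
                               function(i) unlist(grid[i, ])), v$id)
  kept <- filter_shared_heterozygous(v, gt, paste0("member", 1:3))
  survives <- !is.na(grid$a) & grid$a == 1 & !is.na(grid$b) & grid$b == 1 &
    !is.na(grid$c) & grid$c == 1
  expect_equal(kept$id, v$id[survives])
  expect_equal(nrow(kept), 1)
  expect_error(filter_shared_heterozygous(v, gt, c("member1", "ghost")),
               "unknown member")
  expect_error(filter_shared_heterozygous(v, gt, character()), "non-empty")
})

test_that("region filter matches a brute-force interval scan", {
  set.seed(23)
  regions <- data.frame(
    chrom = sample(c("chr1", "chr3"), 8, replace = TRUE),
    start = sample(0:900, 8), gene = paste0("g", 1:8))
  regions$end <- regions$start + sample(10:120, 8)
  v <- make_variants(100, chrom = "chr1", end = 1000)
  v$chrom <- sample(c("chr1", "chr3", "chr9"), 100, replace = TRUE)
  kept <- filter_by_regions(v, regions)
  expect_equal(kept$id, v$id[oracle_in_regions(v, regions)])
  expect_error(filter_by_regions(v, regions[0, ]), "non-empty")
})

test_that("nonsynonymous filter excludes unannotated variants with warning", {
  v <- make_variants(3)
  ann <- validate_annotation_table(data.frame(
    variant_id = v$id[1:2], gene = "PROS1",
    consequence = c("nonsynonymous", "synonymous"),
    sift_category = "missing", polyphen_category = "missing"))
  expect_warning(kept <- filter_nonsynonymous(v, ann), "unannotated")
  expect_equal(kept$id, v$id[1])
})

test_that("rare filter applies a strict threshold and flags missing AF", {
  v <- make_variants(4)
  af <- validate_af_table(data.frame(
    variant_id = v$id[1:3], population = "AA",
    af = c(0.0109, 0.02, 0.5)))  # v4 absent from the reference
  kept <- filter_rare(v, af, "AA", threshold = 0.02)
  expect_equal(kept$id, v$id[c(1, 4)])  # 0.02 exactly is excluded
  expect_equal(kept$af_missing, c(FALSE, TRUE))
  expect_error(filter_rare(v, af, "EU"), "unknown population")
  expect_error(filter_rare(v, af, "AA", threshold = 0), ">")
})

test_that("deleteriousness classification annotates, strict mode removes", {
  v <- make_variants(3)
  ann <- validate_annotation_table(data.frame(
    variant_id = v$id, gene = "PROS1", consequence = "nonsynonymous",
    sift_category = c("damaging", "tolerated", "missing"),
    polyphen_category = c("possibly_damaging", "benign", "missing")))
  out <- classify_deleteriousness(v, ann)
  expect_equal(out$deleterious, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(out), 3)  # default is annotation-only
  expect_warning(strict <- classify_deleteriousness(v, ann, strict = TRUE),
                 "lack both")
  expect_equal(strict$id, v$id[c(1, 3)])  # doubly benign removed,
                                          # doubly missing retained
})

test_that("cascade recovers the planted variant and traces every stage", {
  fam <- generate_family_exomes(simulation_config(seed = 101))
  res <- run_cascade(fam)
  expect_equal(res$candidates$id, fam$truth)
  tr <- res$trace$counts
  expect_equal(tr$stage, c("shared_heterozygous", "candidate_regions",
                           "nonsynonymous", "rare_frequency",
                           "deleteriousness"))
  expect_true(all(tr$n_out <= tr$n_in))
  expect_equal(tr$n_in[-1], tr$n_out[-nrow(tr)])
  # the four mandatory decoy classes force strict decreases somewhere
  expect_true(all(tr$n_out[1:4] < tr$n_in[1:4]))
})

test_that("cascade on an empty dataset yields an empty trace", {
  fam <- generate_family_exomes(simulation_config(seed = 1))
  fam$variants <- fam$variants[0, ]
  fam$genotypes <- fam$genotypes[0, , drop = FALSE]
  res <- run_cascade(fam)
  expect_equal(nrow(res$candidates), 0)
  expect_true(all(res$trace$counts$n_out == 0))
})

test_that("the pure set filters commute", {
  fam <- generate_family_exomes(simulation_config(n_decoy_variants = 49,
                                                  seed = 77))
  filters <- list(
    het = function(v) filter_shared_heterozygous(v, fam$genotypes,
                                                 fam$members),
    reg = function(v) filter_by_regions(v, fam$regions),
    nsyn = function(v) filter_nonsynonymous(v, fam$annotations),
    rare = function(v) filter_rare(v, fam$af_table, "AA")[names(v)])
  orderings <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3),
                    c(3, 1, 4, 2), c(4, 1, 3, 2), c(2, 3, 4, 1))
  finals <- lapply(orderings, function(ord) {
    v <- fam$variants
    for (i in ord) v <- filters[[i]](v)
    sort(v$id)
  })
  for (f in finals[-1]) expect_equal(f, finals[[1]])
})

test_that("cascade equals single-pass predicate evaluation", {
  fam <- generate_family_exomes(simulation_config(seed = 55))
  res <- run_cascade(fam)
  v <- fam$variants
  pred <- vapply(seq_len(nrow(v)), function(i) {
    g <- fam$genotypes[v$id[i], fam$members]
    if (!all(!is.na(g) & g == 1)) return(FALSE)
    if (!oracle_in_regions(v[i, ], fam$regions)) return(FALSE)
    ai <- match(v$id[i], fam$annotations$variant_id)
    if (is.na(ai) || fam$annotations$consequence[ai] != "nonsynonymous")
      return(FALSE)
    af <- af_lookup(fam$af_table, v$id[i], "AA")
    is.na(af) || af < 0.02
  }, logical(1))
  expect_equal(sort(res$candidates$id), sort(v$id[pred]))
})
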
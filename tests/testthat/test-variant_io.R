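# VCF / BED / TSV readers and writers.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("member1", "member2")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("diploid GT strings are recoded to dosages", {
  path <- write_lines_tmp(c(vcf_header(), paste(
    c("chr3", "100", "rs1", "A", "C", ".", ".", ".", "GT", "0/1", "1|1"),
    collapse = "\t")))
  got <- read_vcf(path)
  expect_equal(unname(got$genotypes[1, ]), c(1L, 2L))  # phasing ignored
})

test_that("missing and half-missing genotypes become NA", {
  path <- write_lines_tmp(c(vcf_header(), paste(
    c("chr3", "100", ".", "A", "C", ".", ".", ".", "GT", "./.", "0/."),
    collapse = "\t")))
  got <- read_vcf(path)
  expect_true(all(is.na(got$genotypes[1, ])))
})

test_that("multi-allelic sites split into per-allele records", {
  # enumerate every unordered genotype over alleles {0, 1, 2}: the split
  # record for alt k must carry the count of k in the genotype
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2")
  path <- write_lines_tmp(c(vcf_header(paste0("s", seq_along(gts))), paste(
    c("chr3", "100", "rsM", "A", "C,T", ".", ".", ".", "GT", gts),
    collapse = "\t")))
  got <- read_vcf(path)
  expect_equal(nrow(got$variants), 2)
  expect_equal(got$variants$alt, c("C", "T"))
  expect_equal(got$variants$id, c("rsM_1", "rsM_2"))
  counts <- t(sapply(strsplit(gts, "/"), function(a)
    c(sum(a == "1"), sum(a == "2"))))
  expect_equal(unname(got$genotypes[1, ]), counts[, 1])
  expect_equal(unname(got$genotypes[2, ]), counts[, 2])
})

test_that("malformed VCFs are rejected with informative errors", {
  path <- write_lines_tmp(c("##fileformat=VCFv4.2", "chr3\t1\t.\tA\tC"))
  expect_error(read_vcf(path), "#CHROM")
  path2 <- write_lines_tmp(c(vcf_header("s1"), paste(
    c("chr3", "55", ".", "A", "C", ".", ".", ".", "GT", "0/1/1"),
    collapse = "\t")))
  expect_error(read_vcf(path2), "non-diploid.*chr3:55.*s1")
})

test_that("VCF write/read round-trips variants and genotypes", {
  set.seed(17)
  variants <- make_variants(5)
  gt <- matrix(sample(c(0:2, NA), 15, replace = TRUE), 5, 3,
               dimnames = list(variants$id, c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(variants, gt, path)
  got <- read_vcf(path)
  expect_equal(got$variants, variants, ignore_attr = TRUE)
  expect_equal(got$genotypes, gt)
  expect_error(write_vcf(variants, gt[1:3, ], path), "match")
})

test_that("header-only VCF reads as an empty dataset", {
  variants <- make_variants(0)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(variants, matrix(integer(), 0, 0), path)
  got <- read_vcf(path)
  expect_equal(nrow(got$variants), 0)
})

test_that("BED regions keep 0-based half-open coordinates", {
  path <- withr::local_tempfile()
  writeLines("chr3\t0\t10\tPROS1", path)
  r <- read_regions_bed(path)
  expect_equal(r$start, 0)
  expect_equal(r$end, 10)
  # covers 1-based positions 1..10
  v <- data.frame(chrom = "chr3", pos = c(1L, 10L, 11L),
                  id = c("x", "y", "z"), ref = "A", alt = "C")
  expect_equal(filter_by_regions(v, r)$id, c("x", "y"))

  writeLines(c("chr3\t0\t10\tPROS1", "chr3\t5\t4\tbad"), path)
  expect_error(read_regions_bed(path), "line 2")
  writeLines(character(), path)
  expect_equal(nrow(read_regions_bed(path)), 0)
  # overlapping regions for one gene are both kept
  writeLines(c("chr3\t0\t10\tPROS1", "chr3\t5\t20\tPROS1"), path)
  expect_equal(nrow(read_regions_bed(path)), 2)
})

test_that("AF table validates frequencies and duplicates", {
  path <- withr::local_tempfile()
  writeLines(c("variant_id\tpopulation\taf", "rs138925964\tAA\t0.0109"),
             path)
  af <- read_af_table(path)
  expect_equal(af_lookup(af, "rs138925964", "AA"), 0.0109)
  expect_true(is.na(af_lookup(af, "absent", "AA")))

  writeLines(c("variant_id\tpopulation\taf", "v1\tAA\t1.5"), path)
  expect_error(read_af_table(path), "\\[0, 1\\]")
  writeLines(c("variant_id\tpopulation\taf", "v1\tAA\t0.1", "v1\tAA\t0.2"),
             path)
  expect_error(read_af_table(path), "duplicate")
})

test_that("annotation table enforces one row per variant and categories", {
  path <- withr::local_tempfile()
  lines <- c("variant_id\tgene\tconsequence\tsift_category\tpolyphen_category",
             "v1\tPROS1\tnonsynonymous\tdamaging\tpossibly_damaging")
  writeLines(lines, path)
  ann <- read_annotation_table(path)
  expect_equal(ann$gene, "PROS1")
  writeLines(c(lines, "v1\tF5\tsynonymous\ttolerated\tbenign"), path)
  expect_error(read_annotation_table(path), "duplicate")
  writeLines(c(lines[1], "v1\tPROS1\tweird\tdamaging\tbenign"), path)
  expect_error(read_annotation_table(path), "consequence")
})

test_that("TSV round trips preserve tables exactly", {
  cfg <- simulation_config(n_decoy_variants = 10)
  fam <- generate_family_exomes(cfg)
  dir <- withr::local_tempdir()
  write_family_dataset(fam, dir)
  back <- read_family_dataset(dir)
  expect_equal(back$variants, fam$variants, ignore_attr = TRUE)
  expect_equal(back$genotypes, fam$genotypes)
  expect_equal(as.data.frame(back$af_table), as.data.frame(fam$af_table),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(back$annotations),
               as.data.frame(fam$annotations), ignore_attr = TRUE)
  expect_equal(back$regions, fam$regions, ignore_attr = TRUE)
})
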
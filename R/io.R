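# Readers and writers for the formats the pipeline touches: VCF 4.2
# genotypes, BED4 candidate regions, and headered TSV tables for allele
# frequencies, annotations and covariates.
#
# Internal data model:
#   variants  - data.frame(chrom, pos, id, ref, alt), one row per alternate
#               allele (multi-allelic sites are split at read time)
#   genotypes - integer matrix (variants x samples) of alt-allele dosages
#               0/1/2, NA for missing; rownames = variant ids

#' Read a VCF into variant records and a genotype matrix
#'
#' Parses a VCF 4.x text file with a GT FORMAT field.  Diploid genotypes are
#' recoded to alt-allele dosages; `./.` (and half-missing calls) become `NA`;
#' phased separators are treated as unphased.  Multi-allelic sites are split
#' into one record per alternate allele, with genotypes recoded per allele
#' (e.g. `1/2` contributes dosage 1 to each of the two alternate-allele
#' records).  Split records get `_1`, `_2`, ... suffixes on their id so ids
#' stay unique.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @param normalize_chrom if `TRUE`, strip a leading `"chr"` from chromosome
#'   labels; by default labels are kept verbatim and compared as exact
#'   strings.
#' @return `list(variants = data.frame(chrom, pos, id, ref, alt),
#'   genotypes = matrix)`.
#' @export
read_vcf <- function(path, normalize_chrom = FALSE) {
  lines <- readLines(path, n = 2000L)
  if (!any(startsWith(lines, "#CHROM")))
    stop("not a VCF: missing #CHROM header line in ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record VCFs drop to a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(list(variants = empty_variants(),
                genotypes = matrix(integer(), 0, 0)))
  }
  gt_raw <- if (ncol(vcf@gt) > 1L) vcfR::extract.gt(vcf, element = "GT")
            else matrix(character(), nrow(fix), 0)
  if (is.null(dim(gt_raw)))
    gt_raw <- matrix(gt_raw, nrow = 1, dimnames = list(NULL, names(gt_raw)))
  samples <- colnames(gt_raw)

  out_var <- list(); out_gt <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    id0 <- fix$ID[i]
    if (is.na(id0) || id0 == ".") id0 <- NA_character_
    # parse the genotype strings once per site
    alleles <- lapply(seq_along(samples), function(j) {
      g <- gt_raw[i, j]
      if (is.na(g) || g == ".") return(NULL)   # fully missing
      parts <- strsplit(g, "[/|]")[[1]]
      if (length(parts) != 2L)
        stop(sprintf("non-diploid genotype '%s' at %s:%s sample %s",
                     g, fix$CHROM[i], fix$POS[i], samples[j]), call. = FALSE)
      if (any(parts == ".")) return(NULL)      # half-missing -> missing
      as.integer(parts)
    })
    for (k in seq_along(alts)) {
      id <- if (is.na(id0)) NA_character_
            else if (length(alts) == 1L) id0 else paste0(id0, "_", k)
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), id = id,
        ref = fix$REF[i], alt = alts[k], stringsAsFactors = FALSE)
      out_gt[[length(out_gt) + 1L]] <- vapply(alleles, function(al) {
        if (is.null(al)) NA_integer_ else sum(al == k)
      }, integer(1))
    }
  }
  variants <- do.call(rbind, out_var)
  if (normalize_chrom) variants$chrom <- sub("^chr", "", variants$chrom)
  genotypes <- do.call(rbind, out_gt)
  colnames(genotypes) <- samples
  rownames(genotypes) <- variants$id
  if (anyDuplicated(stats::na.omit(variants$id)))
    stop("duplicate variant ids in ", path, call. = FALSE)
  list(variants = variants, genotypes = genotypes)
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), stringsAsFactors = FALSE)
}

#' Write variants and genotypes as VCF 4.2
#'
#' Emits one bi-allelic record per variant row.  Dosage 0/1/2 becomes
#' `0/0`, `0/1`, `1/1`; `NA` becomes `./.`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`.
#' @param genotypes integer dosage matrix, `nrow(variants)` rows; may have
#'   zero columns for a site-only VCF.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  if (nrow(variants) != nrow(genotypes))
    stop("genotype matrix rows must match variant rows", call. = FALSE)
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (ncol(genotypes) > 0) c("FORMAT", colnames(genotypes))),
          collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
                   nrow = nrow(genotypes))
  gt_str[is.na(gt_str)] <- "./."
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i],
            if (is.na(variants$id[i])) "." else variants$id[i],
            variants$ref[i], variants$alt[i], ".", ".", ".",
            if (ncol(genotypes) > 0) c("GT", gt_str[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read candidate-gene regions from BED4
#'
#' BED intervals are 0-based half-open; they are preserved exactly (a region
#' `start=0, end=10` covers 1-based positions 1..10).
#'
#' @param path path to a tab-separated BED file with at least 4 columns
#'   (chrom, start, end, name).
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad))
    stop("BED line ", bad[1], " has fewer than 4 columns", call. = FALSE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    gene = vapply(parts, `[[`, "", 4L), stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop("BED line ", bad[1], ": start >= end", call. = FALSE)
  out
}

#' @rdname read_regions_bed
#' @param regions data.frame of regions as returned by `read_regions_bed()`.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                     regions$end, regions$gene), path)
  invisible(path)
}

#' Read a population allele-frequency table
#'
#' Tab-separated with header `variant_id`, `population`, `af`.  Frequencies
#' must lie in `[0, 1]`; duplicate (variant, population) pairs are an error.
#' A variant absent from the table is distinct from a variant with frequency
#' 0: lookups return the missing sentinel `NA`.
#'
#' @param path path to the TSV file.
#' @return data.frame of class `af_table`.
#' @export
read_af_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  need <- c("variant_id", "population", "af")
  if (!identical(names(df)[seq_along(need)], need))
    stop("AF table must have header: ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_af_table(df)
}

validate_af_table <- function(df) {
  if (any(!is.na(df$af) & (df$af < 0 | df$af > 1)))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(df[c("variant_id", "population")]))
    stop("duplicate (variant, population) rows in AF table", call. = FALSE)
  class(df) <- c("af_table", "data.frame")
  df
}

#' @rdname read_af_table
#' @param af_table an `af_table` data frame.
#' @export
write_af_table <- function(af_table, path) {
  utils::write.table(af_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_af_table
#' @param variant_id,population scalars identifying the lookup.
#' @return `af_lookup()`: the frequency, or `NA` if the (variant,
#'   population) pair is absent.
#' @export
af_lookup <- function(af_table, variant_id, population) {
  hit <- af_table$variant_id == variant_id & af_table$population == population
  if (!any(hit)) return(NA_real_)
  af_table$af[which(hit)[1]]
}

.CONSEQUENCES <- c("nonsynonymous", "synonymous", "other")
.SIFT <- c("damaging", "tolerated", "missing")
.POLYPHEN <- c("probably_damaging", "possibly_damaging", "benign", "missing")

#' Read a variant annotation table
#'
#' Tab-separated with header `variant_id`, `gene`, `consequence`,
#' `sift_category`, `polyphen_category`; one row per variant.  Consequence
#' must be one of `nonsynonymous`, `synonymous`, `other`; SIFT/PolyPhen
#' categories are the discretized predictions (`missing` allowed).
#'
#' @param path path to the TSV file.
#' @return data.frame of class `annotation_table`.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("variant_id", "gene", "consequence", "sift_category",
            "polyphen_category")
  if (!identical(names(df)[seq_along(need)], need))
    stop("annotation table must have header: ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_annotation_table(df)
}

validate_annotation_table <- function(df) {
  if (anyDuplicated(df$variant_id))
    stop("duplicate variant ids in annotation table", call. = FALSE)
  chk <- function(col, allowed)
    if (!all(df[[col]] %in% allowed))
      stop(col, " must be one of: ", paste(allowed, collapse = ", "),
           call. = FALSE)
  chk("consequence", .CONSEQUENCES)
  chk("sift_category", .SIFT)
  chk("polyphen_category", .POLYPHEN)
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @rdname read_annotation_table
#' @param annotations an `annotation_table` data frame.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a subject covariate table
#'
#' Tab-separated with header `subject_id`, `sex`, `age`, `height`, `weight`,
#' `subcohort`, `status` (`case`/`control`).
#'
#' @param path path to the TSV file.
#' @return data.frame, one row per subject.
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "height", "weight", "subcohort",
            "status")
  if (!all(need %in% names(df)))
    stop("covariate table must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(df$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'", call. = FALSE)
  df
}

#' @rdname read_covariate_table
#' @param covariates covariate data frame.
#' @export
write_covariate_table <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
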
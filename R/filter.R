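# The family discovery cascade: reduce the shared exome of the affected
# relatives to candidate variants by successive set filters --
#   shared heterozygotes -> candidate-gene regions -> nonsynonymous
#   -> rare in the reference population -> deleteriousness annotation.
# Each stage is a pure function of the variant table plus one auxiliary
# input, so the stages commute and the cascade equals a single-pass
# predicate evaluation.

#' Retain variants heterozygous in every family member
#'
#' A variant survives only if its alt-allele dosage is exactly 1 in every
#' listed member; a missing call in any member excludes the variant.
#'
#' @param variants variant data.frame (see [read_vcf()]).
#' @param genotypes dosage matrix with one column per sample.
#' @param member_ids sample ids of the (affected) family members.
#' @return The retained subset of `variants`.
#' @export
filter_shared_heterozygous <- function(variants, genotypes, member_ids) {
  if (length(member_ids) == 0) stop("member_ids must be non-empty",
                                    call. = FALSE)
  unknown <- setdiff(member_ids, colnames(genotypes))
  if (length(unknown))
    stop("unknown member id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (nrow(variants) == 0) return(variants)
  # align genotype rows to the (possibly subset) variant table by id when
  # possible, positionally otherwise
  rn <- rownames(genotypes)
  if (!is.null(rn) && !anyNA(variants$id) && all(variants$id %in% rn)) {
    g <- genotypes[variants$id, member_ids, drop = FALSE]
  } else {
    if (nrow(genotypes) != nrow(variants))
      stop("genotype matrix rows cannot be aligned to the variant table",
           call. = FALSE)
    g <- genotypes[, member_ids, drop = FALSE]
  }
  keep <- rowSums(!is.na(g) & g == 1L) == length(member_ids)
  variants[keep, , drop = FALSE]
}

#' Retain variants inside candidate-gene regions
#'
#' A variant is kept if its 1-based position falls inside at least one
#' region on the same chromosome; regions use BED half-open semantics, so a
#' region `(start, end)` covers 1-based positions `start + 1 .. end`.
#' Chromosome labels are compared as exact strings.
#'
#' @param variants variant data.frame.
#' @param regions region data.frame (`chrom`, `start`, `end`, `gene`), see
#'   [read_regions_bed()].
#' @return The retained subset of `variants`.
#' @export
filter_by_regions <- function(variants, regions) {
  if (nrow(regions) == 0) stop("regions must be non-empty", call. = FALSE)
  if (nrow(variants) == 0) return(variants)
  lv <- union(unique(variants$chrom), unique(regions$chrom))
  vr <- GenomicRanges::GRanges(factor(variants$chrom, lv),
                               IRanges::IRanges(variants$pos, variants$pos))
  rr <- GenomicRanges::GRanges(factor(regions$chrom, lv),
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  keep <- GenomicRanges::countOverlaps(vr, rr) > 0
  variants[keep, , drop = FALSE]
}

#' Retain nonsynonymous variants
#'
#' Keeps variants annotated with consequence `nonsynonymous`.  Variants with
#' no annotation row are excluded with a warning.
#'
#' @param variants variant data.frame.
#' @param annotations `annotation_table` (see [read_annotation_table()]).
#' @return The retained subset of `variants`.
#' @export
filter_nonsynonymous <- function(variants, annotations) {
  if (nrow(variants) == 0) return(variants)
  idx <- match(variants$id, annotations$variant_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " unannotated variant(s) excluded",
            call. = FALSE)
  keep <- !is.na(idx) & annotations$consequence[idx] == "nonsynonymous"
  keep[is.na(keep)] <- FALSE
  variants[keep, , drop = FALSE]
}

#' Retain variants rare in a reference population
#'
#' Keeps variants whose reference minor allele frequency in the named
#' population is strictly below `threshold`.  Variants absent from the
#' frequency table are retained -- a variant missing from a population
#' reference cannot be common there -- and flagged in an `af_missing`
#' column.
#'
#' @param variants variant data.frame.
#' @param af_table `af_table` (see [read_af_table()]).
#' @param population population label to look up (must occur in the table).
#' @param threshold strict upper bound on the reference frequency
#'   (default 0.02, i.e. keep variants with MAF < 2%).
#' @return The retained subset of `variants`, with an `af_missing` logical
#'   column appended.
#' @export
filter_rare <- function(variants, af_table, population, threshold = 0.02) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  if (!population %in% af_table$population)
    stop("unknown population label: ", population, call. = FALSE)
  if (nrow(variants) == 0) {
    variants$af_missing <- logical(0)
    return(variants)
  }
  af <- vapply(variants$id, function(v) af_lookup(af_table, v, population),
               numeric(1))
  keep <- is.na(af) | af < threshold
  out <- variants[keep, , drop = FALSE]
  out$af_missing <- is.na(af[keep])
  out
}

#' Attach deleteriousness categories to candidate variants
#'
#' Attaches the discretized SIFT and PolyPhen predictions to each candidate
#' and flags predicted-deleterious variants (SIFT `damaging` or PolyPhen
#' `probably_damaging`/`possibly_damaging`).  By default this stage only
#' annotates; with `strict = TRUE` it removes variants called benign or
#' tolerated by *both* predictors.  Candidates with both predictions missing
#' are retained in strict mode, with a warning.
#'
#' @param candidates variant data.frame.
#' @param annotations `annotation_table`.
#' @param strict remove doubly benign/tolerated variants?
#' @return `candidates` with `sift_category`, `polyphen_category` and
#'   `deleterious` columns appended; class `candidate_set`.
#' @export
classify_deleteriousness <- function(candidates, annotations,
                                     strict = FALSE) {
  idx <- match(candidates$id, annotations$variant_id)
  sift <- ifelse(is.na(idx), "missing", annotations$sift_category[idx])
  poly <- ifelse(is.na(idx), "missing", annotations$polyphen_category[idx])
  out <- candidates
  out$sift_category <- sift
  out$polyphen_category <- poly
  out$deleterious <- sift == "damaging" |
    poly %in% c("probably_damaging", "possibly_damaging")
  if (strict && nrow(out) > 0) {
    both_missing <- sift == "missing" & poly == "missing"
    if (any(both_missing))
      warning(sum(both_missing),
              " candidate(s) lack both predictions; retained", call. = FALSE)
    drop <- sift %in% c("tolerated") & poly %in% c("benign")
    out <- out[!drop, , drop = FALSE]
  }
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Run the full discovery cascade
#'
#' Applies, in order: shared-heterozygote filter, candidate-region filter,
#' nonsynonymous filter, rare-frequency filter, deleteriousness
#' classification.  Records a per-stage trace of surviving variant counts.
#'
#' @param dataset a `family_dataset` (see [generate_family_exomes()]) or a
#'   list with elements `variants`, `genotypes`, `regions`, `annotations`,
#'   `af_table` and optionally `members`.
#' @param members sample ids to require shared heterozygosity in (default:
#'   all samples in the genotype matrix, or `dataset$members`).
#' @param population reference population for the frequency filter.
#' @param af_threshold strict frequency cutoff (default 0.02).
#' @param strict_deleterious treat the deleteriousness stage as a hard
#'   filter (see [classify_deleteriousness()]).
#' @return `list(candidates = candidate_set, trace = filter_trace)`.
#' @export
run_cascade <- function(dataset, members = NULL, population = "AA",
                        af_threshold = 0.02, strict_deleterious = FALSE) {
  members <- members %||% dataset$members %||% colnames(dataset$genotypes)
  trace <- list()
  note <- function(stage, n_in, kept) {
    trace[[length(trace) + 1L]] <<- list(
      stage = stage, n_in = n_in, n_out = nrow(kept),
      retained = kept$id)
  }
  v0 <- dataset$variants
  v1 <- filter_shared_heterozygous(v0, dataset$genotypes, members)
  note("shared_heterozygous", nrow(v0), v1)
  v2 <- filter_by_regions(v1, dataset$regions)
  note("candidate_regions", nrow(v1), v2)
  v3 <- filter_nonsynonymous(v2, dataset$annotations)
  note("nonsynonymous", nrow(v2), v3)
  v4 <- filter_rare(v3, dataset$af_table, population, af_threshold)
  note("rare_frequency", nrow(v3), v4)
  cand <- classify_deleteriousness(v4, dataset$annotations,
                                   strict = strict_deleterious)
  note("deleteriousness", nrow(v4), cand)
  list(candidates = cand, trace = filter_trace(trace))
}

#' Per-stage trace of the discovery cascade
#'
#' @param stages list of per-stage records (`stage`, `n_in`, `n_out`,
#'   `retained`).
#' @return An object of class `filter_trace`; its `counts` element is a
#'   data.frame of stage names with input/output counts.
#' @export
filter_trace <- function(stages) {
  counts <- data.frame(
    stage = vapply(stages, `[[`, "", "stage"),
    n_in = vapply(stages, `[[`, 0, "n_in"),
    n_out = vapply(stages, `[[`, 0, "n_out"))
  stopifnot(all(counts$n_out <= counts$n_in |
                counts$stage == "deleteriousness"))
  structure(list(counts = counts,
                 retained = lapply(stages, `[[`, "retained")),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("discovery cascade trace:\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set: %d variant(s)\n", nrow(x)))
  NextMethod()
}
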
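# Synthetic family exomes, case-control cohorts and reference frequency
# tables with the statistical structure the analysis assumes, so discovery
# and association can be exercised end-to-end with no external data.
#
# All coordinates are synthetic: candidate regions are invented intervals
# labelled with the real coagulation-pathway gene symbols, not true genomic
# annotation.

#' Default candidate-gene regions (synthetic coordinates)
#'
#' The eight coagulation-pathway genes used to restrict family filtering:
#' factor V, protein C, protein S, prothrombin, antithrombin III,
#' cystathionine beta-synthase, and the two C4b-binding protein chains.
#' Interval coordinates are synthetic placeholders on the genes' chromosomes.
#'
#' @return region data.frame (`chrom`, `start`, `end`, `gene`).
#' @export
default_candidate_regions <- function() {
  data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr11", "chr1", "chr21", "chr1",
              "chr1"),
    start = c(1000000L, 2000000L, 3000000L, 4000000L, 5000000L, 6000000L,
              7000000L, 8000000L),
    end = c(1080000L, 2050000L, 3100000L, 4020000L, 5050000L, 6030000L,
            7040000L, 8040000L),
    gene = c("F5", "PROC", "PROS1", "F2", "SERPINC1", "CBS", "C4BPA",
             "C4BPB"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic generators.  The
#' defaults are the study conditions of the analysis the package reproduces:
#' three affected relatives sharing one heterozygous causal variant, a
#' reference population frequency of 1.09% for that variant, a cohort of 306
#' cases (carrier frequency 15/306) versus 370 controls (4/370) split into
#' warfarin and biobank subcohorts, and a background population of 2203
#' subjects with 48 heterozygote carriers.
#'
#' @param n_family_members number of affected, genotyped relatives.
#' @param n_decoy_variants decoy variants planted around the causal one
#'   (>= 4 so every filter stage has something to remove).
#' @param regions candidate-gene regions used for in-gene placement.
#' @param causal_af_reference reference-population frequency of the causal
#'   variant in `[0, 1)`.
#' @param extra_population_afs named numeric vector of additional
#'   population labels and causal-variant frequencies (e.g.
#'   `c(EU = 0.0003)`).
#' @param case_n,control_n cohort arm sizes.
#' @param case_carrier_freq,control_carrier_freq per-subject probability of
#'   carrying the risk allele.
#' @param background_n,background_carriers background population size and
#'   heterozygote carrier count.
#' @param case_subcohort_split,control_subcohort_split named integer vectors
#'   partitioning each arm into subcohorts (must sum to the arm size).
#' @param covariates list of per-covariate location/scale parameters: `sex_p`
#'   (probability female), and for `age`, `height`, `weight` a vector
#'   `c(case = , control = , sd = )`.
#' @param covariate_missing_rate probability that a height/weight value is
#'   missing.
#' @param hwe if `TRUE`, draw cohort genotypes from Hardy-Weinberg
#'   proportions at allele frequency `carrier_freq / 2` instead of making
#'   every carrier heterozygous.
#' @param seed integer seed for the dataset's private PRNG stream.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_family_members = 3,
                              n_decoy_variants = 100,
                              regions = default_candidate_regions(),
                              causal_af_reference = 0.0109,
                              extra_population_afs = c(),
                              case_n = 306, control_n = 370,
                              case_carrier_freq = 15 / 306,
                              control_carrier_freq = 4 / 370,
                              background_n = 2203,
                              background_carriers = 48,
                              case_subcohort_split =
                                c(warfarin = 173, biovu = 133),
                              control_subcohort_split =
                                c(warfarin = 134, biovu = 236),
                              covariates = list(
                                sex_p = 0.5,
                                age = c(case = 48, control = 62, sd = 12),
                                height = c(case = 167, control = 169,
                                           sd = 9),
                                weight = c(case = 95, control = 85,
                                           sd = 20)),
                              covariate_missing_rate = 0,
                              hwe = FALSE,
                              seed = 1) {
  cfg <- list(n_family_members = n_family_members,
              n_decoy_variants = n_decoy_variants, regions = regions,
              causal_af_reference = causal_af_reference,
              extra_population_afs = extra_population_afs,
              case_n = case_n, control_n = control_n,
              case_carrier_freq = case_carrier_freq,
              control_carrier_freq = control_carrier_freq,
              background_n = background_n,
              background_carriers = background_carriers,
              case_subcohort_split = case_subcohort_split,
              control_subcohort_split = control_subcohort_split,
              covariates = covariates,
              covariate_missing_rate = covariate_missing_rate,
              hwe = hwe, seed = seed)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(is_count(n_family_members), n_family_members >= 1,
              is_count(n_decoy_variants),
              is_count(case_n), case_n > 0,
              is_count(control_n), control_n > 0,
              is_count(background_n), background_n > 0,
              is_count(background_carriers),
              background_carriers <= background_n,
              is.numeric(seed), length(seed) == 1L)
    if (!is_fraction(causal_af_reference) || causal_af_reference >= 1)
      stop("causal_af_reference must lie in [0, 1)", call. = FALSE)
    if (!is_fraction(case_carrier_freq) || !is_fraction(control_carrier_freq))
      stop("carrier frequencies must lie in [0, 1]", call. = FALSE)
    if (length(extra_population_afs) &&
        (is.null(names(extra_population_afs)) ||
         !all(vapply(extra_population_afs, is_fraction, logical(1)))))
      stop("extra_population_afs must be a named vector of fractions",
           call. = FALSE)
    if (sum(case_subcohort_split) != case_n ||
        sum(control_subcohort_split) != control_n)
      stop("subcohort splits must sum to the arm sizes", call. = FALSE)
    if (!is_fraction(covariate_missing_rate))
      stop("covariate_missing_rate must lie in [0, 1]", call. = FALSE)
  })
  structure(cfg, class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")

#' Generate a synthetic family exome dataset
#'
#' Plants one causal variant -- heterozygous in every affected member,
#' inside the protein S candidate region, nonsynonymous, reference frequency
#' `causal_af_reference`, predicted damaging/possibly damaging -- among
#' `n_decoy_variants` decoys, each of which fails at least one cascade
#' stage.  The first four decoys fail exactly one stage each (genotype
#' pattern, region, consequence, frequency), so every stage removes at
#' least one variant.
#'
#' @param config a [simulation_config()].
#' @return A list of class `family_dataset`: `variants`, `genotypes`,
#'   `regions`, `annotations`, `af_table`, `members`, `truth` (the causal
#'   variant id).
#' @export
generate_family_exomes <- function(config) {
  config <- validate_config(config)
  if (config$n_decoy_variants < 4)
    stop("need at least 4 decoy variants to cover all failure classes",
         call. = FALSE)
  with_seed(config$seed, build_family(config))
}

build_family <- function(cfg) {
  members <- paste0("member", seq_len(cfg$n_family_members))
  regions <- cfg$regions
  n_var <- cfg$n_decoy_variants + 1L
  ids <- sprintf("var%04d", seq_len(n_var))
  pops <- c(AA = cfg$causal_af_reference, cfg$extra_population_afs)

  # decoy failure classes: a = not shared-het, b = outside regions,
  # c = synonymous, d = common (reference AF >= 0.02)
  classes <- c("a", "b", "c", "d")
  fail <- vector("list", cfg$n_decoy_variants)
  fail[1:4] <- as.list(classes)
  for (i in setdiff(seq_len(cfg$n_decoy_variants), 1:4))
    fail[[i]] <- sample(classes, size = sample(1:4, 1))

  pros1 <- regions[regions$gene == "PROS1", ][1, ]
  used_pos <- new.env(parent = emptyenv())
  draw_pos <- function(chrom, lo, hi) {
    repeat {
      p <- sample(lo:hi, 1L)
      key <- paste0(chrom, ":", p)
      if (!exists(key, envir = used_pos)) {
        assign(key, TRUE, envir = used_pos)
        return(p)
      }
    }
  }

  place <- function(in_gene) {
    if (in_gene) {
      r <- regions[sample(nrow(regions), 1L), ]
      list(chrom = r$chrom, pos = draw_pos(r$chrom, r$start + 1L, r$end))
    } else {
      # off-target chromosome, guaranteed outside every candidate region
      list(chrom = "chr9", pos = draw_pos("chr9", 1e6L, 2e6L))
    }
  }
  gene_at <- function(chrom, pos) {
    hit <- regions$chrom == chrom & pos > regions$start & pos <= regions$end
    if (any(hit)) regions$gene[which(hit)[1]] else "intergenic"
  }
  het_all <- rep(1L, cfg$n_family_members)
  non_shared_het_pattern <- function() {
    repeat {
      g <- sample(c(0L, 1L, 2L, NA_integer_), cfg$n_family_members,
                  replace = TRUE, prob = c(0.35, 0.25, 0.2, 0.2))
      if (!all(!is.na(g) & g == 1L)) return(g)
    }
  }

  rows <- vector("list", n_var)
  gts <- matrix(NA_integer_, n_var, cfg$n_family_members,
                dimnames = list(ids, members))
  ann <- vector("list", n_var)
  afr <- list()

  add_af <- function(id, af_by_pop) {
    for (p in names(af_by_pop)) {
      af <- af_by_pop[[p]]
      if (!is.na(af))
        afr[[length(afr) + 1L]] <<- data.frame(
          variant_id = id, population = p, af = af,
          stringsAsFactors = FALSE)
    }
  }

  # causal variant
  truth_id <- ids[1]
  tp <- draw_pos(pros1$chrom, pros1$start + 1L, pros1$end)
  ref <- sample(.BASES, 1L)
  rows[[1]] <- data.frame(chrom = pros1$chrom, pos = tp, id = truth_id,
                          ref = ref, alt = sample(setdiff(.BASES, ref), 1L),
                          stringsAsFactors = FALSE)
  gts[1, ] <- het_all
  ann[[1]] <- data.frame(variant_id = truth_id, gene = "PROS1",
                         consequence = "nonsynonymous",
                         sift_category = "damaging",
                         polyphen_category = "possibly_damaging",
                         stringsAsFactors = FALSE)
  add_af(truth_id, as.list(pops))

  for (i in seq_len(cfg$n_decoy_variants)) {
    j <- i + 1L
    f <- fail[[i]]
    loc <- place(in_gene = !("b" %in% f))
    ref <- sample(.BASES, 1L)
    rows[[j]] <- data.frame(chrom = loc$chrom, pos = loc$pos, id = ids[j],
                            ref = ref,
                            alt = sample(setdiff(.BASES, ref), 1L),
                            stringsAsFactors = FALSE)
    gts[j, ] <- if ("a" %in% f) non_shared_het_pattern() else het_all
    ann[[j]] <- data.frame(
      variant_id = ids[j], gene = gene_at(loc$chrom, loc$pos),
      consequence = if ("c" %in% f) sample(c("synonymous", "other"), 1L)
                    else "nonsynonymous",
      sift_category = sample(.SIFT, 1L),
      polyphen_category = sample(.POLYPHEN, 1L),
      stringsAsFactors = FALSE)
    af_aa <- if ("d" %in% f) stats::runif(1, 0.02, 0.5)
             else if (stats::runif(1) < 0.1) NA_real_  # novel variant
             else stats::runif(1, 0, 0.0199)
    others <- lapply(names(cfg$extra_population_afs) %||% character(),
                     function(p) stats::runif(1, 0, 0.0199))
    names(others) <- names(cfg$extra_population_afs)
    add_af(ids[j], c(list(AA = af_aa), others))
  }

  variants <- do.call(rbind, rows)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  gts <- gts[ord, , drop = FALSE]
  af_table <- validate_af_table(do.call(rbind, afr))
  annotations <- validate_annotation_table(do.call(rbind, ann))
  structure(list(variants = variants, genotypes = gts, regions = regions,
                 annotations = annotations, af_table = af_table,
                 members = members, truth = truth_id),
            class = "family_dataset")
}

#' Generate a synthetic case-control cohort at one variant
#'
#' Each subject's genotype at the tested variant is drawn independently: by
#' default a carrier (probability `case_carrier_freq` /
#' `control_carrier_freq` per arm) is heterozygous, matching carrier-count
#' data; with `hwe = TRUE` genotypes are drawn from Hardy-Weinberg
#' proportions at allele frequency `carrier_freq / 2`.  Covariates: sex is
#' Bernoulli, age/height/weight are normal with per-arm means, so a
#' confounded or unconfounded regime can be configured.
#'
#' @param config a [simulation_config()].
#' @return A list of class `cohort_dataset` with a `subjects` data frame
#'   (`subject_id`, `sex`, `age`, `height`, `weight`, `subcohort`,
#'   `status`, `genotype`).
#' @export
generate_case_control_cohort <- function(config) {
  config <- validate_config(config)
  with_seed(config$seed + 1L, build_cohort(config))
}

build_cohort <- function(cfg) {
  arm <- function(status, n, carrier_freq, split) {
    geno <- if (cfg$hwe) stats::rbinom(n, 2L, carrier_freq / 2)
            else stats::rbinom(n, 1L, carrier_freq)
    cv <- cfg$covariates
    pick <- function(par) stats::rnorm(n, par[[status]], par[["sd"]])
    miss <- function(x) {
      x[stats::runif(n) < cfg$covariate_missing_rate] <- NA
      x
    }
    data.frame(
      subject_id = paste0(status, "_", seq_len(n)),
      sex = ifelse(stats::rbinom(n, 1L, cv$sex_p) == 1L, "F", "M"),
      age = round(pick(cv$age), 1),
      height = miss(round(pick(cv$height), 1)),
      weight = miss(round(pick(cv$weight), 1)),
      subcohort = rep(names(split), times = split),
      status = status, genotype = geno, stringsAsFactors = FALSE)
  }
  subjects <- rbind(
    arm("case", cfg$case_n, cfg$case_carrier_freq, cfg$case_subcohort_split),
    arm("control", cfg$control_n, cfg$control_carrier_freq,
        cfg$control_subcohort_split))
  structure(list(subjects = subjects), class = "cohort_dataset")
}

#' Generate a reference allele-frequency table
#'
#' One row per variant per configured population.  With no variant list the
#' table covers just the causal variant, whose frequency equals
#' `causal_af_reference` in the `AA` population plus any configured extra
#' populations.
#'
#' @param config a [simulation_config()].
#' @param variants optional variant data.frame; decoy frequencies are drawn
#'   from the config's private PRNG stream.
#' @param truth_id id of the causal variant within `variants`.
#' @return An `af_table` data frame.
#' @export
generate_af_reference <- function(config, variants = NULL,
                                  truth_id = "causal") {
  config <- validate_config(config)
  pops <- c(AA = config$causal_af_reference, config$extra_population_afs)
  if (is.null(variants)) {
    return(validate_af_table(data.frame(
      variant_id = truth_id, population = names(pops),
      af = unname(pops), stringsAsFactors = FALSE)))
  }
  with_seed(config$seed + 2L, {
    rows <- lapply(seq_len(nrow(variants)), function(i) {
      id <- variants$id[i]
      af <- if (id == truth_id) unname(pops)
            else stats::runif(length(pops), 0, 0.0199)
      data.frame(variant_id = id, population = names(pops), af = af,
                 stringsAsFactors = FALSE)
    })
    validate_af_table(do.call(rbind, rows))
  })
}

#' Reload a family dataset from written artifacts
#'
#' Inverse of [write_family_dataset()] (the planted-truth id is not part of
#' the artifacts, so the `truth` field is `NULL` on reload).
#'
#' @param dir directory containing `family.vcf`, `regions.bed`,
#'   `annotations.tsv`, `af.tsv`.
#' @return A `family_dataset`.
#' @export
read_family_dataset <- function(dir) {
  vg <- read_vcf(file.path(dir, "family.vcf"))
  structure(list(variants = vg$variants, genotypes = vg$genotypes,
                 regions = read_regions_bed(file.path(dir, "regions.bed")),
                 annotations =
                   read_annotation_table(file.path(dir, "annotations.tsv")),
                 af_table = read_af_table(file.path(dir, "af.tsv")),
                 members = colnames(vg$genotypes), truth = NULL),
            class = "family_dataset")
}

#' @rdname read_family_dataset
#' @export
read_cohort_dataset <- function(dir) {
  structure(list(subjects =
                   read_covariate_table(file.path(dir, "cohort.tsv"))),
            class = "cohort_dataset")
}

#' Write a family dataset's artifacts to a directory
#'
#' Emits `family.vcf`, `regions.bed`, `annotations.tsv` and `af.tsv`.
#'
#' @param dataset a `family_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(dataset$variants, dataset$genotypes,
            file.path(dir, "family.vcf"))
  write_regions_bed(dataset$regions, file.path(dir, "regions.bed"))
  write_annotation_table(dataset$annotations,
                         file.path(dir, "annotations.tsv"))
  write_af_table(dataset$af_table, file.path(dir, "af.tsv"))
  invisible(dir)
}
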
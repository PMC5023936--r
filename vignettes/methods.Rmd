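---
title: "Methods: family-based rare-variant discovery and exact case-control association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant discovery and exact case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtevar)
```

## The problem

Venous thromboembolism (VTE) has a markedly higher incidence in African
Americans than in European-descent populations, yet the clinically tested
thrombophilia variants (factor V Leiden, the prothrombin G20210A promoter
variant) are nearly absent in African-descent genomes. One productive route
to population-specific risk factors is a two-stage design:

1. **Family discovery.** In a small family with recurrent VTE and exome
   data on several affected relatives, filter the shared exome down to
   candidate variants using a cascade of biologically motivated criteria.
2. **Population assessment.** Test the surviving candidate for association
   in an independent case–control cohort, and again against a large
   population background cohort, using exact conditional 2×2 statistics
   (the counts involved are far too small for asymptotic tests).

`vtevar` implements both stages, together with a synthetic-data generator
that reproduces the statistical structure of the inputs so the whole
pipeline is testable end to end without any external data.

## The discovery cascade

Given diploid exome genotypes for the affected relatives, the cascade
applies five stages in order (`run_cascade()`):

| stage | rule |
|---|---|
| shared heterozygotes | alt-allele dosage exactly 1 in *every* affected member |
| candidate regions | position inside one of the candidate coagulation-pathway genes |
| consequence | annotated `nonsynonymous` |
| rarity | reference-population MAF strictly `< 0.02` |
| deleteriousness | SIFT / PolyPhen categories attached |

The dominant-inheritance rationale: a fully penetrant risk allele shared by
affected members of a thrombophilia pedigree should be heterozygous in each
of them (a homozygote would suggest a recessive model, and these variants
are too rare for homozygotes to be plausible), should alter protein
sequence, and should be rare in the matched reference population. The 2%
cutoff is deliberately twice the conventional 1% "rare variant" bound so
borderline-rare alleles are not lost; the comparison is strict (`< 0.02`),
so a variant at exactly 2% is removed.

Design choices where the rules are genuinely open:

* **Missing genotype calls exclude a variant** at the shared-heterozygote
  stage: an unobserved genotype cannot positively support sharing.
* **Variants absent from the frequency reference are retained** by the
  rarity filter and flagged (`af_missing`): a variant missing from a
  population catalogue cannot be common in it. Treating absence as
  frequency 0 versus "missing" is an explicit contract throughout the
  package — lookups return `NA`, never silently 0.
* **Deleteriousness is annotation-only by default.** The predictions are
  used to *evaluate* candidates, not to discard them; `strict = TRUE`
  turns the stage into a hard filter that removes variants called benign
  *and* tolerated by both predictors, retaining (with a warning) variants
  where both predictions are missing.
* The four removal stages are pure set filters on independent attributes,
  so they commute; the test suite checks that any stage ordering yields
  the same candidate set, and that the cascade equals a one-pass predicate
  evaluation.

## Exact conditional 2×2 inference

Allele counts are compared between arms in a 2×2 table (minor/major ×
case/control). Conditioning on both margins leaves the count `a` of case
minor alleles distributed as (noncentral) hypergeometric with the odds
ratio $\theta$ as noncentrality parameter:

$$
P_\theta(X = x) \propto \binom{m}{x}\binom{n}{k-x}\,\theta^x ,
$$

with $m, n$ the case/control allele totals and $k$ the minor-allele
margin. All inference enumerates this support explicitly, in log space
(tables up to a total of $10^6$ alleles are accepted; the support is at
most $\min(m,k)+1$ points, so enumeration is exact and fast).

Three standard two-sided constructions are implemented
(`fisher_exact_p()`):

* **minlike** — sum of outcome probabilities no larger than the observed
  one (the rule used by classical Fisher's exact test);
* **central** — twice the smaller tail, capped at 1;
* **blaker** — Blaker's acceptability function.

Ties in outcome probabilities are compared with a relative tolerance of
$1+10^{-7}$, the de facto convention for discrete exact tests.

Odds ratios (`odds_ratio()`) come in two flavours: the sample
cross-product ratio $ad/bc$ (with zero cells mapped to $0$ or $\infty$ and
flagged; no continuity correction) and the conditional MLE, the root of
the conditional score equation $E_\theta[X] = a$, solved by monotone
root-finding on $\log\theta$ to tolerance $10^{-10}$.

Confidence intervals (`exact_or_ci()`) invert the matching two-sided test
over $\theta$: the interval is the outer hull of $\{\theta :
p(\theta) > 1 - \text{level}\}$. For the central method the p-value
function is monotone on each side and the bounds solve the one-sided tail
equations (this reproduces `stats::fisher.test` intervals exactly); for
minlike and Blaker the p-value function can be locally non-monotone, so
the bounds are located by scanning inward from far outside the acceptance
region before root refinement (tolerance $10^{-8}$ on $\log\theta$).
Support-boundary outcomes give limits of $0$ or $\infty$.

**Default methods.** The default p-value *and* CI method are both
`minlike`. The two-sided minlike p-value is what the classical Fisher test
reports, and pairing it with the minlike-inverted interval keeps p-values
and intervals dual (1 is outside the 95% interval exactly when
$p < 0.05$). On the package's worked example (15, 597, 4, 736) the
minlike machinery gives $p = 0.0041$, sample OR $= 4.62$, 95% CI
$1.51$–$15.20$, whereas the central interval is noticeably wider
($1.46$–$19.21$); both are available and labelled in every result object.

One ordering worth knowing: Blaker's p-value never exceeds the central one
(a theorem, verified exhaustively in the tests for table totals up to 40),
but minlike and central are *not* ordered in general — with tied outcome
probabilities the minlike sum can pick up the entire support (p = 1) while
the doubled tail stays below 1, e.g. for the table (0, 3, 4, 11).

Supporting statistics follow field convention:

* `binomial_two_sided()` — minimum-likelihood exact binomial test (used
  for sex ratios among carriers).
* `ld_r2()` — squared Pearson correlation of genotype dosages over
  pairwise-complete subjects: the composite LD estimate for unphased data.
  It is not the haplotype (EM-phased) $r^2$; the two agree under random
  mating but can diverge otherwise. Monomorphic input is an error, not 0.
* `compare_covariates()` — Welch (unequal-variance) t-test for continuous
  covariates, exact tests for categorical ones.
* `logistic_fit()` — maximum-likelihood logistic regression by IRLS
  (through `stats::glm`), reporting Wald statistics. Convergence is
  declared when the score (log-likelihood gradient) per unit predictor
  L1 norm falls below $10^{-8}$ within 100 iterations — the
  normalisation makes the tolerance scale-free; an absolute cutoff on
  the raw gradient would be unattainable in double precision for
  covariates measured in natural units (heights near 170 cm across
  thousands of subjects). Perfect separation (diverging coefficients with
  degenerate fitted probabilities) is flagged and suppresses estimates.
  Rows with missing covariates are excluded and counted, mirroring how
  cohort height/weight missingness is reported.
* `subcohort_homogeneity()` — all pairwise exact tests of per-subcohort
  allele counts within each arm, to check that no single subcohort drives
  an association.
* No multiple-testing adjustment is applied anywhere: the pipeline
  evaluates a single pre-specified variant, not a genome-wide scan.

## The synthetic-data generator

`simulation_config()` defaults *are* the study conditions:

* a family of 3 affected members sharing one heterozygous causal variant
  in the protein S gene region, with reference-population frequency
  0.0109;
* 306 cases with carrier frequency 15/306 versus 370 controls at 4/370,
  split into a warfarin subcohort (173/134) and a biobank subcohort
  (133/236);
* a background population of 2203 subjects containing 48 heterozygote
  carriers.

Each generated dataset uses a private PRNG stream seeded from the config;
the caller's RNG state is untouched and identical configs give identical
datasets.

The family generator plants the causal variant among decoys
(`n_decoy_variants`, default 100 — the true number of variants entering
such a cascade is not knowable in general, and 100 keeps every stage
exercised while tests stay fast; it is configurable). Every decoy fails at
least one stage by construction, and the first four fail exactly one stage
each (wrong genotype pattern, outside candidate regions, synonymous,
common), so each stage strictly removes something. Candidate-gene
intervals carry the eight coagulation-pathway gene symbols on their true
chromosomes but with *synthetic coordinates* — they are placeholders, not
genomic annotation.

Cohort carriers are heterozygous by default, because the quantities being
matched are carrier counts; `hwe = TRUE` instead draws genotypes from
Hardy–Weinberg proportions at allele frequency `carrier_freq / 2`.
Covariates are simple parametric draws (sex Bernoulli; age, height,
weight normal with per-arm means — defaults encode younger, heavier,
slightly shorter cases, the confounded regime the logistic check is meant
to catch). What the generator does **not** emulate: linkage
disequilibrium between variants, relatedness beyond the shared causal
allele, genotyping error, population stratification, or realistic
covariate distributions. Passing tests therefore demonstrate the
correctness of the statistical machinery under its stated sampling
assumptions, not robustness to real-data artefacts.

## Numerical and testing choices

* Exact p-values are validated against full-support enumeration with
  direct binomial-coefficient arithmetic for **every** 2×2 table with all
  margins positive and total ≤ 60 (about 628,000 tables), at absolute
  tolerance $10^{-12}$; the binomial test against a dense $n \le 60$
  sweep.
* Test/CI duality is property-checked on 1000 random small tables.
* Type-I error of the default test is measured over 2000 null cohort
  replicates at the pooled carrier frequency (equal in both arms): exact
  conditional tests are conservative, and the rejection fraction at
  $\alpha = 0.05$ stays below 0.055.
* Logistic parameter recovery uses 200 replicates of $n = 5000$ cohorts
  with known coefficients $(-1, 0.8, 0.02, -0.01)$, requiring all
  estimates within 3 standard errors in at least 95% of replicates.
* Simulation sizes in the test suite (100 discovery seeds, 500-replicate
  carrier-count calibration, 2000 null cohorts) were chosen so the whole
  suite completes in about a minute on one CPU while keeping Monte-Carlo
  noise far from the asserted bounds.

## Limitations

* The VCF reader handles the GT field only (no INFO/annotation-string
  parsing), treats phased and unphased genotypes identically, and errors
  on non-diploid calls; chromosome labels are compared as exact strings
  unless `normalize_chrom = TRUE`.
* The discovery model is strictly dominant and fully penetrant within the
  family: compound heterozygotes, recessive models and unaffected-member
  contrasts are out of scope.
* Conditional exact inference is conservative for small tables; where
  margins are tiny the minlike CI can be wide and the CMLE sits at a
  support boundary (reported as 0 or ∞).
* The generator's independence assumptions (no LD) mean the LD check on
  synthetic data is only a contract test of the arithmetic.
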
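#' Normalize a multiplicative allelic effect into a genotype-effect triple
#'
#' Under a multiplicative (log-additive) model, carrying `c` copies of the
#' effect allele multiplies the expected biomarker level by `a^c`.  The raw
#' multipliers `(1, a, a^2)` are rescaled by the Hardy-Weinberg weighted
#' mean `m = p^2 a^2 + 2 p (1 - p) a + (1 - p)^2`, so that the population
#' mean of the genotype effect is exactly one.  Dividing a measured level
#' by the resulting multiplier therefore leaves the population geometric
#' structure intact while removing the genotype's contribution.
#'
#' The triple keeps the allelic ratio: `e1/e0 = e2/e1 = a` exactly.  It is
#' also orientation-invariant: `(1/a, 1 - p)` (recoding to the other
#' allele) yields the same triple reversed.
#'
#' @param a multiplicative per-allele effect, `a > 0`.
#' @param p effect-allele frequency, strictly inside `(0, 1)`.
#' @return Numeric triple `c(e0, e1, e2)` of multipliers for 0, 1, 2
#'   effect-allele copies.
#' @examples
#' round(normalize_genotype_effects(1.49, 0.25), 2)  # 0.79 1.18 1.76
#' normalize_genotype_effects(1, 0.5)                # 1 1 1
#' @export
normalize_genotype_effects <- function(a, p) {
  stopifnot(length(a) == 1L, length(p) == 1L, is.finite(a), is.finite(p))
  if (a <= 0) stop("allelic effect must be positive")
  if (p <= 0 || p >= 1) {
    stop("effect-allele frequency must lie strictly inside (0, 1)")
  }
  m <- p^2 * a^2 + 2 * p * (1 - p) * a + (1 - p)^2
  c(e0 = 1, e1 = a, e2 = a^2) / m
}

#' Normalize an allelic effect against observed genotype frequencies
#'
#' Variant of [normalize_genotype_effects()] for samples that need not be
#' in Hardy-Weinberg equilibrium: the raw multipliers `(1, a, a^2)` are
#' rescaled so their mean over the *observed* genotype distribution
#' `(f0, f1, f2)` is exactly one.
#'
#' @param a multiplicative per-allele effect, `a > 0`.
#' @param genotype_freqs observed genotype proportions `(f0, f1, f2)`,
#'   non-negative and summing to one (tolerance `1e-9`).
#' @return Numeric triple `c(e0, e1, e2)`.
#' @export
normalize_empirical <- function(a, genotype_freqs) {
  stopifnot(length(a) == 1L, is.finite(a), length(genotype_freqs) == 3L)
  if (a <= 0) stop("allelic effect must be positive")
  f <- as.numeric(genotype_freqs)
  if (any(f < 0)) stop("genotype frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop("genotype frequencies must sum to 1")
  m <- f[1L] + f[2L] * a + f[3L] * a^2
  c(e0 = 1, e1 = a, e2 = a^2) / m
}

#' Estimate a SNP's multiplicative allelic effect on a biomarker
#'
#' Ordinary least squares of `log(level)` on the effect-allele count; the
#' back-transformed slope `a = exp(slope)` is the multiplicative change in
#' geometric-mean level per allele copy.  When the fitted slope is
#' negative the orientation is flipped (`count -> 2 - count`) so the
#' reported effect always satisfies `a >= 1`, and `flipped = TRUE` records
#' that the effect allele is the complement of the allele the counts were
#' coded against.
#'
#' @param levels positive biomarker levels (detection-flooring happens at
#'   read time, not here; non-positive values are an error).
#' @param counts effect-allele copy counts in `{0, 1, 2}`; `NA` allowed.
#' @param rsid optional identifier carried into the result.
#' @return List of class `allelic_effect`: `rsid`, `allelic_effect`,
#'   `se_log` (standard error of the log-scale slope), `n_used`,
#'   `flipped`, `effect_allele_freq` (sample frequency of the reported
#'   effect allele).
#' @export
estimate_allelic_effect <- function(levels, counts, rsid = NA_character_) {
  stopifnot(length(levels) == length(counts))
  keep <- !is.na(levels) & !is.na(counts)
  levels <- levels[keep]
  counts <- counts[keep]
  if (any(levels <= 0)) stop("biomarker levels must be positive")
  if (!all(counts %in% 0:2)) stop("genotype counts must be 0, 1 or 2")
  if (length(levels) < 3L) stop("need at least 3 complete observations")
  if (length(unique(counts)) < 2L) {
    stop("no variation: genotype is monomorphic",
         if (!is.na(rsid)) paste0(" for ", rsid))
  }
  fit <- lm(log(levels) ~ counts)
  beta <- unname(coef(fit)[2L])
  se <- sqrt(vcov(fit)[2L, 2L])
  flipped <- beta < 0
  if (flipped) {
    beta <- -beta
    counts <- 2L - counts
  }
  structure(list(rsid = rsid,
                 allelic_effect = exp(beta),
                 se_log = se,
                 n_used = length(levels),
                 flipped = flipped,
                 effect_allele_freq = mean(counts) / 2),
            class = "allelic_effect")
}

#' @exportS3Method base::print
print.allelic_effect <- function(x, ...) {
  cat(sprintf("Allelic effect%s: a = %.4f (log-scale SE %.4f), n = %d%s\n",
              if (is.na(x$rsid)) "" else paste0(" for ", x$rsid),
              x$allelic_effect, x$se_log, x$n_used,
              if (x$flipped) ", orientation flipped" else ""))
  invisible(x)
}

#' Fit a correction panel from cohort data
#'
#' Runs one marginal log-linear regression per SNP ([estimate_allelic_effect()],
#' one SNP at a time, no covariates) for the given biomarker, normalizes
#' each estimate with [normalize_genotype_effects()] using the sample
#' frequency of the reported effect allele, and assembles the results into
#' a [correction_panel()].
#'
#' The cohort's genotype counts are coded against a known effect allele
#' only when a reference panel supplied them; a freshly fitted panel
#' records the orientation (`flipped`) relative to the input coding and
#' leaves the allele base `NA` unless `reference` is given.
#'
#' @param cohort a `cohort_table` (see [read_cohort()], [simulate_cohort()]).
#' @param biomarker `"AFP"`, `"CA19-9"` or `"CEA"`.
#' @param rsids SNPs to fit; default: all genotype columns in the cohort.
#' @param reference optional `correction_panel` supplying allele bases and
#'   coordinates for the fitted SNPs.
#' @return A `correction_panel` with columns `rsid`, `effect_allele`,
#'   `effect_allele_freq`, `allelic_effect`, `se_log`, `n_used`, `flipped`
#'   and the normalized triple.
#' @export
fit_panel <- function(cohort, biomarker, rsids = NULL, reference = NULL) {
  col <- biomarker_column(biomarker)
  if (is.null(rsids)) rsids <- genotype_columns(cohort)
  missing_rs <- setdiff(rsids, names(cohort))
  if (length(missing_rs)) {
    stop("rsid(s) not genotyped in cohort: ",
         paste(missing_rs, collapse = ", "))
  }
  fits <- lapply(rsids, function(rs) {
    estimate_allelic_effect(cohort[[col]], cohort[[rs]], rsid = rs)
  })
  out <- data.frame(
    rsid = rsids,
    effect_allele = NA_character_,
    effect_allele_freq = vapply(fits, `[[`, numeric(1), "effect_allele_freq"),
    allelic_effect = vapply(fits, `[[`, numeric(1), "allelic_effect"),
    se_log = vapply(fits, `[[`, numeric(1), "se_log"),
    n_used = vapply(fits, `[[`, integer(1), "n_used"),
    flipped = vapply(fits, `[[`, logical(1), "flipped"),
    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    i <- match(out$rsid, reference$rsid)
    base <- reference$effect_allele[i]
    # a flipped fit reports the complement of the reference effect allele
    out$effect_allele <- ifelse(out$flipped & !is.na(base),
                                paste0("not-", base), base)
  }
  correction_panel(out, biomarker = biomarker)
}

biomarker_column <- function(biomarker) {
  if (biomarker %in% names(BIOMARKERS)) return(unname(BIOMARKERS[biomarker]))
  if (biomarker %in% BIOMARKERS) return(biomarker)
  stop("unknown biomarker: ", biomarker)
}

genotype_columns <- function(cohort) {
  setdiff(names(cohort), pheno_columns())
}
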
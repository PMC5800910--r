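#' Combined genetic effect of a panel's SNPs
#'
#' Under the multiplicative model, a subject's combined genetic effect `G`
#' is the product over the panel's SNPs of the normalized genotype-effect
#' multiplier selected by the subject's effect-allele count.  A missing
#' count contributes a factor of one (population-mean imputation: under
#' the mean-one normalization the expected multiplier of an unobserved
#' genotype is one).  `G` is therefore always positive, and its population
#' mean tends to one under Hardy-Weinberg equilibrium.
#'
#' @param genotype_counts integer matrix (subjects x SNPs, columns named
#'   by rsid), a data.frame of such columns, or a named vector for a
#'   single subject.  Values must be in `{0, 1, 2, NA}`.
#' @param panel a [correction_panel()].
#' @param strict if `TRUE`, subjects with any missing panel genotype get
#'   `NA` instead of the mean-imputed product.
#' @return Numeric vector of multipliers, with attribute `"n_imputed"`:
#'   per-subject count of panel SNPs treated as multiplier one.
#' @examples
#' panel <- load_snp_panel()[["CA19-9"]]
#' combined_genetic_effect(c(rs17271883 = 0, rs3760775 = 2, rs265548 = 1,
#'                           rs1047781 = 0), panel)
#' @export
combined_genetic_effect <- function(genotype_counts, panel, strict = FALSE) {
  stopifnot(inherits(panel, "correction_panel"), nrow(panel) >= 1L)
  if (is.null(dim(genotype_counts))) {
    genotype_counts <- matrix(genotype_counts, nrow = 1L,
                              dimnames = list(NULL, names(genotype_counts)))
  }
  m <- as.matrix(as.data.frame(genotype_counts))
  n <- nrow(m)
  absent <- setdiff(panel$rsid, colnames(m))
  if (length(absent)) {
    warning("panel SNP(s) not in genotype data, treated as missing: ",
            paste(absent, collapse = ", "))
  }
  g <- rep(1, n)
  n_imputed <- integer(n) + length(absent)
  for (k in seq_len(nrow(panel))) {
    rs <- panel$rsid[k]
    triple <- c(panel$e0[k], panel$e1[k], panel$e2[k])
    if (!rs %in% colnames(m)) next
    cnt <- m[, rs]
    ok <- is.na(cnt) | cnt %in% 0:2
    if (!all(ok)) stop("genotype counts for ", rs, " must be 0, 1, 2 or NA")
    mult <- triple[cnt + 1L]
    miss <- is.na(mult)
    mult[miss] <- 1
    n_imputed <- n_imputed + miss
    g <- g * mult
  }
  if (strict) g[n_imputed > 0L] <- NA_real_
  structure(g, n_imputed = n_imputed)
}

#' Genetically correct measured biomarker levels
#'
#' The corrected level is the measured level divided by the subject's
#' combined genetic effect: it estimates the level the subject would show
#' if their genotype multipliers were all at the population mean.
#' Corrected values may fall below the 0.005 detection floor; they are
#' kept as computed (the correction is analytic, not a measurement) and
#' flagged in `<marker>_below_floor`.
#'
#' @param cohort a `cohort_table` with genotype count columns.
#' @param panels list of [correction_panel()]s covering AFP, CA19-9, CEA
#'   (default: packaged panels).
#' @param strict passed to [combined_genetic_effect()]: drop (set `NA`)
#'   subjects with missing panel genotypes instead of mean-imputing.
#' @return A `corrected_levels` data.frame: `subject_id` plus, per marker,
#'   `<marker>_raw`, `<marker>_multiplier`, `<marker>_corrected`,
#'   `<marker>_n_imputed`, `<marker>_below_floor`.  Summarize with
#'   [correction_summary()].
#' @export
correct_levels <- function(cohort, panels = load_snp_panel(),
                           strict = FALSE) {
  validate_cohort(cohort)
  geno <- cohort[genotype_columns(cohort)]
  out <- data.frame(subject_id = cohort$subject_id,
                    stringsAsFactors = FALSE)
  for (m in unname(BIOMARKERS)) {
    panel <- panel_for_marker(panels, m)
    g <- combined_genetic_effect(geno, panel, strict = strict)
    raw <- cohort[[m]]
    corrected <- raw / as.numeric(g)
    out[[paste0(m, "_raw")]] <- raw
    out[[paste0(m, "_multiplier")]] <- as.numeric(g)
    out[[paste0(m, "_corrected")]] <- corrected
    out[[paste0(m, "_n_imputed")]] <- attr(g, "n_imputed")
    out[[paste0(m, "_below_floor")]] <- !is.na(corrected) &
      corrected < .floor_value
  }
  class(out) <- c("corrected_levels", "data.frame")
  out
}

#' Summarize a correction: mean raw versus corrected level per marker
#'
#' Percent change is `100 * (mean_raw - mean_corrected) / mean_raw`, i.e.
#' positive when correction lowers the cohort's mean level.
#'
#' @param corrected output of [correct_levels()].
#' @return data.frame: `biomarker`, `mean_raw`, `mean_corrected`,
#'   `percent_change`, `n_missing`.
#' @export
correction_summary <- function(corrected) {
  stopifnot(inherits(corrected, "corrected_levels"))
  rows <- lapply(unname(BIOMARKERS), function(m) {
    raw <- corrected[[paste0(m, "_raw")]]
    cor <- corrected[[paste0(m, "_corrected")]]
    mr <- mean(raw, na.rm = TRUE)
    mc <- mean(cor, na.rm = TRUE)
    data.frame(biomarker = names(BIOMARKERS)[match(m, BIOMARKERS)],
               mean_raw = mr, mean_corrected = mc,
               percent_change = 100 * (mr - mc) / mr,
               n_missing = sum(is.na(cor)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @exportS3Method base::print
print.corrected_levels <- function(x, ...) {
  cat("Genetically corrected levels for", nrow(x), "subject(s)\n")
  print(correction_summary(x), row.names = FALSE)
  invisible(x)
}
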
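# Cohort table: one row per subject, phenotype columns below plus one
# integer column of effect-allele counts per genotyped SNP (named by rsid).

pheno_columns <- function() {
  c("subject_id", "afp", "ca199", "cea", "age", "sex", "bmi", "smoking",
    "drinking", "physical_activity", "family_history", "event",
    "followup_time", "cancer_site")
}

.pheno_numeric <- c("afp", "ca199", "cea", "age", "bmi", "followup_time")
.pheno_integer <- "event"

#' Read a cohort from phenotype and genotype files
#'
#' Joins a per-subject phenotype table with genotypes supplied either as an
#' rsid-by-subject count matrix (TSV, cells in `{0, 1, 2, NA}`) or as a
#' VCF, and applies the detection floor: biomarker values below 0.01 are
#' recorded as 0.005 (the lowest point of the assay standard curve).
#'
#' VCF genotypes are converted to effect-allele counts using each panel
#' SNP's `effect_allele`: when it matches ALT the count is the ALT dosage,
#' when it matches REF the dosage is flipped (`2 - dosage`), otherwise the
#' SNP is recorded missing with a warning.  Subjects present in the
#' phenotype file but absent from the genotype source get missing counts,
#' with a warning.
#'
#' @param phenotype_path TSV/CSV with header; required columns are those of
#'   the cohort phenotype block (`subject_id`, `afp`, `ca199`, `cea`,
#'   `age`, `sex`, `bmi`, `smoking`, `drinking`, `physical_activity`,
#'   `family_history`, `event`, `followup_time`, `cancer_site`); missing
#'   sentinel `NA`.
#' @param genotype_path TSV count matrix (first column `rsid`, one column
#'   per subject) or a VCF 4.x file.
#' @param panels panels whose SNPs should be extracted (default: packaged
#'   panels); used for VCF allele orientation and to restrict columns.
#' @param genotype_format `"auto"` (by file extension), `"tsv"` or `"vcf"`.
#' @return A `cohort_table` data.frame.
#' @export
read_cohort <- function(phenotype_path, genotype_path,
                        panels = load_snp_panel(),
                        genotype_format = c("auto", "tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  sep <- if (grepl("\\.csv$", phenotype_path, ignore.case = TRUE)) "," else "\t"
  pheno <- utils::read.delim(phenotype_path, sep = sep, na.strings = "NA",
                             stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(pheno_columns(), names(pheno))
  if (length(missing_cols)) {
    stop("phenotype file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pheno <- pheno[pheno_columns()]
  pheno$subject_id <- as.character(pheno$subject_id)
  for (cc in .pheno_numeric) pheno[[cc]] <- as.numeric(pheno[[cc]])
  pheno$event <- as.integer(pheno$event)
  for (cc in c("sex", "smoking", "drinking", "physical_activity",
               "family_history", "cancer_site")) {
    pheno[[cc]] <- as.character(pheno[[cc]])
  }
  for (cc in unname(BIOMARKERS)) {
    v <- pheno[[cc]]
    if (any(v < 0, na.rm = TRUE)) stop("negative ", cc, " level in ",
                                       phenotype_path)
    pheno[[cc]] <- apply_detection_floor(v)
  }

  if (genotype_format == "auto") {
    genotype_format <- if (grepl("\\.vcf(\\.gz)?$", genotype_path,
                                 ignore.case = TRUE)) "vcf" else "tsv"
  }
  counts <- switch(genotype_format,
                   tsv = read_genotype_matrix(genotype_path),
                   vcf = read_genotype_vcf(genotype_path, panels))

  want <- panel_snp_index(panels)$rsid
  absent <- setdiff(want, rownames(counts))
  if (length(absent)) {
    warning("panel SNP(s) absent from genotype source, recorded missing: ",
            paste(absent, collapse = ", "))
  }
  lost <- setdiff(pheno$subject_id, colnames(counts))
  if (length(lost)) {
    warning(length(lost), " subject(s) absent from genotype source, ",
            "counts recorded missing")
  }
  geno <- matrix(NA_integer_, nrow = nrow(pheno), ncol = length(want),
                 dimnames = list(NULL, want))
  have_rs <- intersect(want, rownames(counts))
  have_subj <- intersect(pheno$subject_id, colnames(counts))
  geno[match(have_subj, pheno$subject_id), have_rs] <-
    t(counts[have_rs, have_subj, drop = FALSE])
  out <- cbind(pheno, as.data.frame(geno, stringsAsFactors = FALSE))
  as_cohort_table(out)
}

apply_detection_floor <- function(x) {
  ifelse(!is.na(x) & x < .floor_threshold, .floor_value, x)
}

read_genotype_matrix <- function(path) {
  g <- utils::read.delim(path, na.strings = "NA", stringsAsFactors = FALSE,
                         check.names = FALSE)
  rs <- as.character(g[[1L]])
  m <- as.matrix(g[-1L])
  suppressWarnings(storage.mode(m) <- "integer")  # unparseable -> NA
  bad <- !is.na(m) & !(m %in% 0:2)
  if (any(bad)) {
    warning(sum(bad), " genotype count(s) outside {0,1,2} set to missing")
    m[bad] <- NA_integer_
  }
  rownames(m) <- rs
  m
}

read_genotype_vcf <- function(path, panels) {
  idx <- panel_snp_index(panels)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # ALT dosage per record x subject
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean %in% c("0/0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1")] <- 2L
  ids <- unname(fix[, "ID"])
  out <- matrix(NA_integer_, nrow = nrow(idx), ncol = ncol(gt),
                dimnames = list(idx$rsid, colnames(gt)))
  for (k in seq_len(nrow(idx))) {
    i <- match(idx$rsid[k], ids)
    if (is.na(i)) next
    if (identical(unname(fix[i, "ALT"]), idx$effect_allele[k])) {
      out[k, ] <- dose[i, ]
    } else if (identical(unname(fix[i, "REF"]), idx$effect_allele[k])) {
      out[k, ] <- 2L - dose[i, ]
    } else {
      warning("effect allele of ", idx$rsid[k],
              " matches neither REF nor ALT; recorded missing")
    }
  }
  out
}

as_cohort_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  rownames(x) <- NULL
  class(x) <- c("cohort_table", "data.frame")
  validate_cohort(x)
  x
}

#' Validate a cohort table
#'
#' Checks the structural invariants every downstream stage relies on:
#' positive follow-up time, events carrying a cancer site, biomarker values
#' at or above the 0.005 detection floor, and genotype counts in
#' `{0, 1, 2, NA}`.
#'
#' @param cohort a `cohort_table`.
#' @return The cohort, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (any(is.na(cohort$followup_time)) || any(cohort$followup_time <= 0)) {
    stop("followup_time must be positive for every subject")
  }
  if (!all(cohort$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  if (any(cohort$event == 1L & cohort$cancer_site == "none")) {
    stop("subjects with an event must have a cancer site")
  }
  for (cc in unname(BIOMARKERS)) {
    v <- cohort[[cc]]
    if (any(!is.na(v) & v < .floor_value)) {
      stop(cc, " has values below the detection floor ", .floor_value)
    }
  }
  for (rs in genotype_columns(cohort)) {
    v <- cohort[[rs]]
    if (!all(is.na(v) | v %in% 0:2)) {
      stop("genotype counts for ", rs, " must be 0, 1, 2 or NA")
    }
  }
  invisible(cohort)
}

#' Write a cohort to phenotype and genotype TSV files
#'
#' Inverse of [read_cohort()]: the pair of files written here reads back
#' into an identical table (numeric columns are serialized with 17
#' significant digits so doubles round-trip exactly; missing values use the
#' `NA` sentinel).
#'
#' @param cohort a `cohort_table`.
#' @param phenotype_path,genotype_path output TSV paths.
#' @return Invisibly, `c(phenotype_path, genotype_path)`.
#' @export
write_cohort <- function(cohort, phenotype_path, genotype_path) {
  validate_cohort(cohort)
  pheno <- cohort[intersect(pheno_columns(), names(cohort))]
  for (cc in .pheno_numeric) pheno[[cc]] <- format_double(pheno[[cc]])
  utils::write.table(pheno, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  rs <- genotype_columns(cohort)
  geno <- data.frame(rsid = rs, stringsAsFactors = FALSE)
  if (length(rs)) {
    m <- t(as.matrix(cohort[rs]))
    colnames(m) <- cohort$subject_id
    geno <- cbind(geno, as.data.frame(m, check.names = FALSE))
  }
  utils::write.table(geno, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(phenotype_path, genotype_path))
}

# %.17g round-trips IEEE doubles through text exactly.
format_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}
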
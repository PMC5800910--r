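test_that("toy fixture loads with flooring and missing genotypes intact", {
  expect_warning(
    cohort <- read_cohort(toy_path("toy_phenotypes.tsv"),
                          toy_path("toy_genotypes.tsv"),
                          panels = default_panels),
    NA)
  expect_s3_class(cohort, "cohort_table")
  expect_equal(nrow(cohort), 3L)
  # AFP 0.003 is below the 0.01 detection limit -> recorded as 0.005
  expect_equal(cohort$afp[cohort$subject_id == "P2"], 0.005)
  expect_true(is.na(cohort$rs441810[cohort$subject_id == "P1"]))
  expect_silent(validate_cohort(cohort))
})

test_that("write/read round trip is the identity on cohort tables", {
  cohort <- make_test_cohort(n = 100, seed = 2)
  pf <- withr::local_tempfile(fileext = ".tsv")
  gf <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, pf, gf)
  back <- read_cohort(pf, gf, panels = default_panels)
  expect_identical(strip_cohort(back), strip_cohort(cohort))
})

test_that("missing genotypes survive the round trip", {
  cohort <- make_test_cohort(n = 20, seed = 8)
  cohort$rs3760775[c(3, 7)] <- NA_integer_
  pf <- withr::local_tempfile(fileext = ".tsv")
  gf <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, pf, gf)
  back <- read_cohort(pf, gf, panels = default_panels)
  expect_identical(strip_cohort(back), strip_cohort(cohort))
  expect_true(all(is.na(back$rs3760775[c(3, 7)])))
})

test_that("an empty cohort round-trips as a header-only file", {
  cohort <- make_test_cohort(n = 20, seed = 9)[0, ]
  pf <- withr::local_tempfile(fileext = ".tsv")
  gf <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, pf, gf)
  back <- read_cohort(pf, gf, panels = default_panels)
  expect_equal(nrow(back), 0L)
  expect_identical(names(strip_cohort(back)), names(strip_cohort(cohort)))
})

test_that("negative biomarker levels are rejected at read time", {
  cohort <- make_test_cohort(n = 5, seed = 3)
  pf <- withr::local_tempfile(fileext = ".tsv")
  gf <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, pf, gf)
  tab <- read.delim(pf)
  tab$cea[2] <- -1
  write.table(tab, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(pf, gf, panels = default_panels), "negative")
})

test_that("subjects missing from the genotype source get NA with warning", {
  cohort <- make_test_cohort(n = 6, seed = 4)
  pf <- withr::local_tempfile(fileext = ".tsv")
  gf <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, pf, gf)
  g <- read.delim(gf, check.names = FALSE)
  g[[cohort$subject_id[1]]] <- NULL
  write.table(g, gf, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  expect_warning(back <- read_cohort(pf, gf, panels = default_panels),
                 "absent from genotype source")
  expect_true(all(is.na(as.matrix(
    back[back$subject_id == cohort$subject_id[1],
         setdiff(names(back), gencorrect:::pheno_columns())]))))
})

write_toy_vcf <- function(path, ref, alt, gts, rsid = "rs3760775",
                          samples = c("P1", "P2", "P3")) {
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             paste(c("19", "5792356", rsid, ref, alt, ".", "PASS", ".",
                     "GT", gts), collapse = "\t"))
  writeLines(lines, path)
}

test_that("VCF genotypes are oriented to the effect allele", {
  panel <- correction_panel(
    data.frame(rsid = "rs3760775", effect_allele = "G",
               effect_allele_freq = 0.25, allelic_effect = 1.49),
    "CA19-9")
  pheno <- toy_path("toy_phenotypes.tsv")
  vf <- withr::local_tempfile(fileext = ".vcf")

  # effect allele is ALT: count = ALT dosage
  write_toy_vcf(vf, ref = "A", alt = "G", gts = c("0/0", "0/1", "1/1"))
  coh_alt <- read_cohort(pheno, vf, panels = list(panel))
  expect_equal(coh_alt$rs3760775, c(0L, 1L, 2L))

  # effect allele is REF: dosage flipped, 0/0 means two effect copies
  write_toy_vcf(vf, ref = "G", alt = "A", gts = c("0/0", "0/1", "1/1"))
  coh_ref <- read_cohort(pheno, vf, panels = list(panel))
  expect_equal(coh_ref$rs3760775, c(2L, 1L, 0L))

  # the same biological genotypes written with swapped REF/ALT yield
  # identical counts and identical combined effects
  write_toy_vcf(vf, ref = "G", alt = "A", gts = c("1/1", "0/1", "0/0"))
  coh_swap <- read_cohort(pheno, vf, panels = list(panel))
  expect_identical(coh_swap$rs3760775, coh_alt$rs3760775)
  g1 <- combined_genetic_effect(coh_alt["rs3760775"], panel)
  g2 <- combined_genetic_effect(coh_swap["rs3760775"], panel)
  expect_equal(as.numeric(g1), as.numeric(g2), tolerance = 1e-12)
})

test_that("unparseable or mismatching VCF records become missing", {
  panel <- correction_panel(
    data.frame(rsid = "rs3760775", effect_allele = "G",
               effect_allele_freq = 0.25, allelic_effect = 1.49),
    "CA19-9")
  pheno <- toy_path("toy_phenotypes.tsv")
  vf <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(vf, ref = "A", alt = "G", gts = c("./.", "0/1", "1/1"))
  coh <- read_cohort(pheno, vf, panels = list(panel))
  expect_true(is.na(coh$rs3760775[1]))
  write_toy_vcf(vf, ref = "A", alt = "C", gts = c("0/0", "0/1", "1/1"))
  expect_warning(coh2 <- read_cohort(pheno, vf, panels = list(panel)),
                 "neither REF nor ALT")
  expect_true(all(is.na(coh2$rs3760775)))
})
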
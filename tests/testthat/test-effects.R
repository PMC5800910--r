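test_that("normalization reproduces published triples at 2 decimals", {
  expect_equal(round(unname(normalize_genotype_effects(1.49, 0.25)), 2),
               c(0.79, 1.18, 1.76))
  expect_lt(max(abs(unname(normalize_genotype_effects(1.38, 0.40)) -
                      c(0.76, 1.04, 1.43))), 0.02)
  expect_equal(unname(normalize_genotype_effects(1, 0.5)), c(1, 1, 1))
})

test_that("normalization rejects degenerate inputs", {
  expect_error(normalize_genotype_effects(1.2, 0), "\\(0, 1\\)")
  expect_error(normalize_genotype_effects(1.2, 1), "\\(0, 1\\)")
  expect_error(normalize_genotype_effects(-1, 0.5), "positive")
})

test_that("normalization is invariant to allele orientation", {
  set.seed(21)
  for (k in 1:20) {
    a <- exp(rnorm(1, 0, 0.4))
    p <- runif(1, 0.05, 0.95)
    t1 <- normalize_genotype_effects(a, p)
    t2 <- normalize_genotype_effects(1 / a, 1 - p)
    expect_equal(unname(t1), rev(unname(t2)), tolerance = 1e-12)
    ratio <- c(t1[2] / t1[1], t1[3] / t1[2])
    expect_equal(unname(ratio), c(a, a), tolerance = 1e-12)
  }
})

test_that("empirical normalization matches HWE weights under HWE", {
  p <- 0.25
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  expect_equal(normalize_empirical(1.49, hwe),
               normalize_genotype_effects(1.49, p), tolerance = 1e-12)
  # point mass on the reference homozygote leaves the raw multipliers
  expect_equal(unname(normalize_empirical(1.3, c(1, 0, 0))),
               c(1, 1.3, 1.69), tolerance = 1e-12)
  expect_error(normalize_empirical(1.3, c(0.5, 0.6, -0.1)), "non-negative")
  expect_error(normalize_empirical(1.3, c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("empirical triples converge to HWE triples in large samples", {
  set.seed(33)
  counts <- rbinom(50000, 2, 0.25)
  f <- tabulate(counts + 1L, 3L) / length(counts)
  emp <- normalize_empirical(1.49, f)
  hwe <- normalize_genotype_effects(1.49, 0.25)
  expect_lt(max(abs(emp - hwe)), 0.01)
})

test_that("allelic effect is exact in the noiseless limit", {
  geno <- matrix(rep(0:2, each = 10), ncol = 1,
                 dimnames = list(NULL, "rs3760775"))
  panel <- default_panels[["CA19-9"]][
    default_panels[["CA19-9"]]$rsid == "rs3760775", ]
  sim <- simulate_biomarkers(geno, panel, baseline_level = 1, log_sd = 0)
  expect_equal(sort(unique(sim$observed)),
               sort(unname(c(panel$e0, panel$e1, panel$e2))),
               tolerance = 1e-12)
  est <- suppressWarnings(estimate_allelic_effect(sim$observed, geno[, 1]))
  expect_equal(est$allelic_effect, 1.49, tolerance = 1e-9)
  expect_false(est$flipped)
})

test_that("allelic effect recovery from noisy simulated data", {
  set.seed(91)
  n <- 20000
  geno <- simulate_genotypes(c(rs_test = 0.25), n)
  panel <- correction_panel(
    data.frame(rsid = "rs_test", effect_allele = "G",
               effect_allele_freq = 0.25, allelic_effect = 1.49),
    "CA19-9")
  sim <- simulate_biomarkers(geno, panel, baseline_level = 7.79,
                             log_sd = 0.8)
  est <- estimate_allelic_effect(sim$observed, geno[, 1])
  expect_lt(abs(log(est$allelic_effect) - log(1.49)), 2 * est$se_log)
})

test_that("orientation flip reports a >= 1 with complementary frequency", {
  set.seed(17)
  counts <- rbinom(2000, 2, 0.7)
  levels <- exp(-0.4 * counts + rnorm(2000, 0, 0.3))
  est <- estimate_allelic_effect(levels, counts)
  expect_true(est$flipped)
  expect_gte(est$allelic_effect, 1)
  expect_equal(est$effect_allele_freq, 1 - mean(counts) / 2)
})

test_that("degenerate effect-estimation inputs error", {
  expect_error(estimate_allelic_effect(c(1, 2, 3), c(1, 1, 1)),
               "monomorphic")
  expect_error(estimate_allelic_effect(c(1, -2, 3), c(0, 1, 2)),
               "positive")
  expect_error(estimate_allelic_effect(c(1, 2), c(0, 1)), "at least 3")
  # constant levels give a slope of exactly zero
  est <- suppressWarnings(
    estimate_allelic_effect(rep(2.5, 30), rep(0:2, each = 10)))
  expect_equal(est$allelic_effect, 1)
})

test_that("fit_panel recovers the generating AFP panel", {
  cohort <- make_test_cohort(n = 9808, seed = 41)
  fitted <- fit_panel(cohort, "AFP", rsids = default_panels$AFP$rsid,
                      reference = default_panels$AFP)
  truth <- default_panels$AFP
  for (k in seq_len(nrow(truth))) {
    i <- match(truth$rsid[k], fitted$rsid)
    a_hat <- fitted$allelic_effect[i]
    if (fitted$flipped[i]) a_hat <- 1 / a_hat
    expect_lt(abs(log(a_hat) - log(truth$allelic_effect[k])),
              2 * fitted$se_log[i])
  }
  # refit is deterministic
  fitted2 <- fit_panel(cohort, "AFP", rsids = default_panels$AFP$rsid)
  expect_equal(fitted$allelic_effect, fitted2$allelic_effect)
})

test_that("fit_panel names the offending monomorphic SNP", {
  cohort <- make_test_cohort(n = 50, seed = 5)
  cohort$rs12506899 <- 0L
  expect_error(fit_panel(cohort, "AFP", rsids = "rs12506899"),
               "rs12506899")
})
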
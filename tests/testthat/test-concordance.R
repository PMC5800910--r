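test_that("worked concordance examples match hand enumeration", {
  r1 <- harrell_c(c(0.9, 0.5, 0.8, 0.1), c(2, 3, 5, 6), c(1, 0, 1, 0))
  expect_equal(r1$n_comparable_pairs, 4)
  expect_equal(r1$c_statistic, 1.0)
  r2 <- harrell_c(c(0.9, 0.5, 0.95, 0.1), c(2, 3, 5, 6), c(1, 0, 1, 0))
  expect_equal(r2$c_statistic, 0.75)
  # all-tied scores: every comparable pair gets half credit
  set.seed(70)
  r3 <- harrell_c(rep(1, 50), runif(50, 1, 5), rbinom(50, 1, 0.5))
  expect_equal(r3$c_statistic, 0.5)
})

test_that("fast concordance matches the brute-force oracle exactly", {
  set.seed(71)
  for (k in 1:200) {
    inst <- random_surv_instance(n = sample(5:200, 1))
    fast <- harrell_c(inst$scores, inst$time, inst$event)
    slow <- brute_force_c(inst$scores, inst$time, inst$event)
    expect_identical(fast$n_comparable_pairs, slow$pairs)
    expect_identical(fast$n_concordant, slow$credit)
    expect_equal(fast$c_statistic, slow$c, tolerance = 1e-12)
  }
})

test_that("concordance agrees with the survival package on untied data", {
  set.seed(72)
  n <- 500
  time <- rexp(n) + 0.01
  event <- rbinom(n, 1, 0.6)
  scores <- rnorm(n)
  ours <- harrell_c(scores, time, event)
  ref <- survival::concordance(survival::Surv(time, event) ~ scores,
                               reverse = TRUE)
  expect_equal(ours$c_statistic, unname(ref$concordance), tolerance = 1e-12)
})

test_that("concordance is invariant to monotone transforms and flips under negation", {
  set.seed(73)
  inst <- random_surv_instance(150, tie_prob = 0)
  c0 <- harrell_c(inst$scores, inst$time, inst$event)$c_statistic
  c_mono <- harrell_c(exp(3 * inst$scores), inst$time,
                      inst$event)$c_statistic
  expect_equal(c_mono, c0, tolerance = 1e-12)
  c_neg <- harrell_c(-inst$scores, inst$time, inst$event)$c_statistic
  expect_equal(c_neg, 1 - c0, tolerance = 1e-12)
})

test_that("without censoring C equals the direct rank statistic", {
  set.seed(74)
  n <- 120
  time <- runif(n, 1, 10)
  scores <- rnorm(n)
  event <- rep(1L, n)
  c1 <- harrell_c(scores, time, event)$c_statistic
  conc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    conc <- conc + ((time[i] - time[j]) * (scores[i] - scores[j]) < 0)
  }
  expect_equal(c1, conc / choose(n, 2), tolerance = 1e-12)
})

test_that("concordance input validation", {
  expect_error(harrell_c(1:3, c(1, 2, -1), c(1, 0, 1)), "positive")
  expect_error(harrell_c(1:3, 1:3, c(2, 0, 1)), "0 or 1")
  # only censored subjects -> no comparable pairs
  expect_error(harrell_c(1:3, 1:3, c(0, 0, 0)), "comparable")
})

test_that("Cox fit recovers a known log hazard ratio", {
  set.seed(75)
  n <- 10000
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.1 * exp(0.7 * x))
  cens <- runif(n, 0, 15)
  time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  fit <- fit_cox(time, event, x)
  expect_lt(abs(fit$beta - 0.7), 2 * fit$se)
  # null covariate
  fit0 <- fit_cox(time, event, rnorm(n))
  expect_lt(abs(fit0$beta), 2 * fit0$se)
  expect_error(fit_cox(time, rep(0L, n), x), "no events")
})

test_that("comparing a score with itself gives delta 0, p 1", {
  set.seed(76)
  inst <- random_surv_instance(100)
  cmp <- compare_c(inst$scores, inst$scores, inst$time, inst$event)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("jackknife comparison detects a strictly better score", {
  set.seed(77)
  n <- 800
  signal <- rnorm(n)
  y <- rbinom(n, 1, plogis(-3 + 1.5 * signal))
  time <- ifelse(y == 1, runif(n, 0, 5), 5)
  noisy <- signal + rnorm(n, 0, 2)
  cmp <- compare_c(signal, noisy, time, y)
  expect_gt(cmp$delta, 0)
  expect_lt(cmp$p_value, 0.05)
  # bootstrap route agrees on direction and is seed-stable
  cmp_b1 <- compare_c(signal, noisy, time, y, method = "bootstrap",
                      n_boot = 200, seed = 5)
  cmp_b2 <- compare_c(signal, noisy, time, y, method = "bootstrap",
                      n_boot = 200, seed = 5)
  expect_identical(cmp_b1$p_value, cmp_b2$p_value)
  expect_gt(cmp_b1$delta, 0)
})

test_that("the concordance grid covers every exposure with comparisons", {
  cohort <- make_test_cohort(n = 3000, seed = 78)
  corrected <- correct_levels(cohort, default_panels)
  suite <- run_c_suite(cohort, corrected)
  expect_equal(nrow(suite$concordance), 8L)
  expect_equal(nrow(suite$comparisons), 4L)
  expect_setequal(unique(suite$concordance$exposure),
                  c("AFP", "CA19-9", "CEA", "combination"))
  expect_true(all(suite$concordance$c_statistic >= 0 &
                    suite$concordance$c_statistic <= 1))
  expect_true(all(suite$concordance$ci_lo >= 0 &
                    suite$concordance$ci_hi <= 1))
  expect_equal(suite$comparisons$delta,
               suite$comparisons$c_corrected - suite$comparisons$c_raw)
  expect_false(any(is.na(suite$comparisons$p_value)))
})
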
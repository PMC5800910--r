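# Shared fixtures and independent oracles.

default_panels <- suppressMessages(load_snp_panel())

toy_path <- function(f) {
  system.file("extdata", f, package = "gencorrect", mustWork = TRUE)
}

make_test_cohort <- function(n = 500, seed = 11, ...) {
  simulate_cohort(simulation_config(n_subjects = n, seed = seed,
                                    panels = default_panels, ...))
}

# Brute-force Harrell concordance over all unordered pairs: the O(n^2)
# oracle the fast implementation is checked against.
brute_force_c <- function(scores, time, event) {
  n <- length(scores)
  pairs <- 0
  credit <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (time[i] < time[j] && event[i] == 1) {
        lead <- i; lag <- j
      } else if (time[j] < time[i] && event[j] == 1) {
        lead <- j; lag <- i
      } else if (time[i] == time[j] && event[i] + event[j] == 1) {
        lead <- if (event[i] == 1) i else j
        lag <- if (event[i] == 1) j else i
      } else {
        next
      }
      pairs <- pairs + 1
      if (scores[lead] > scores[lag]) credit <- credit + 1
      else if (scores[lead] == scores[lag]) credit <- credit + 0.5
    }
  }
  list(c = credit / pairs, pairs = pairs, credit = credit)
}

# Random censored survival instance, with optional ties in scores/times.
random_surv_instance <- function(n, tie_prob = 0.3) {
  time <- if (runif(1) < tie_prob) sample(1:5, n, replace = TRUE) else
    runif(n, 0.1, 10)
  scores <- if (runif(1) < tie_prob) sample(1:4, n, replace = TRUE) / 4 else
    rnorm(n)
  event <- rbinom(n, 1, 0.5)
  if (sum(event) == 0) event[sample.int(n, 1)] <- 1L
  list(scores = scores, time = time, event = event)
}

# Strip simulation metadata so write/read round trips can be compared.
strip_cohort <- function(x) {
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  rownames(x) <- NULL
  x
}
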
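#' Standardize a biomarker exposure
#'
#' Biomarker levels are right-skewed, so exposures enter the risk models
#' per one standard deviation of the *log* level:
#' `z = (log(level) - mean(log(level))) / sd(log(level))`.  The resulting
#' odds ratios are invariant to rescaling the assay units.
#'
#' @param levels positive levels; `NA` allowed (propagated).
#' @return Numeric z-scores (mean 0, SD 1 over non-missing values).
#' @export
standardize_exposure <- function(levels) {
  if (any(levels <= 0, na.rm = TRUE)) stop("levels must be positive")
  lg <- log(levels)
  s <- sd(lg, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot standardize")
  (lg - mean(lg, na.rm = TRUE)) / s
}

#' Unconditional logistic regression for one exposure
#'
#' Maximum-likelihood logistic fit (IRLS, deviance tolerance `1e-8`) of a
#' binary outcome on an exposure plus optional covariates, reporting the
#' exposure's odds ratio with Wald 95% CI `exp(beta +/- 1.96 se)` and
#' two-sided Wald p-value.
#'
#' @param outcome 0/1 vector with at least one event and one non-event.
#' @param exposure numeric exposure (typically [standardize_exposure()]
#'   output, giving an OR per 1 SD of log level).
#' @param covariates optional data.frame of adjustment covariates.
#' @param label exposure label carried into the result.
#' @return One-row data.frame of class `risk_model_result`: `exposure`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`, `beta`, `se`, `n_events`,
#'   `n_total`, `loglik`.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL, label = "") {
  stopifnot(length(outcome) == length(exposure))
  df <- data.frame(.y = outcome, exposure = exposure)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  if (!all(df$.y %in% c(0, 1))) stop("outcome must be 0 or 1")
  if (sum(df$.y) < 1 || sum(1 - df$.y) < 1) {
    stop("need at least one event and one non-event")
  }
  fit <- glm(.y ~ ., data = df, family = binomial(),
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("logistic fit did not converge")
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("collinear covariate(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  beta <- unname(cf["exposure"])
  se <- sqrt(diag(vcov(fit)))[["exposure"]]
  if (abs(beta) > 15) {
    stop("separation suspected for the exposure (|log-odds| > 15)")
  }
  z <- qnorm(0.975)
  out <- data.frame(exposure = label,
                    odds_ratio = exp(beta),
                    ci_lo = exp(beta - z * se),
                    ci_hi = exp(beta + z * se),
                    p_value = 2 * pnorm(-abs(beta) / se),
                    beta = beta, se = se,
                    n_events = sum(df$.y), n_total = nrow(df),
                    loglik = as.numeric(logLik(fit)),
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_model_result", "data.frame")
  out
}

#' Three-marker combination score
#'
#' Default (`"zsum"`): the sum of the three per-marker standardized log
#' levels, re-standardized to mean 0 / SD 1 — an equal-weight composite.
#' `"joint"`: the linear predictor of a logistic model of `outcome` on
#' the three z-scores, i.e. a data-weighted composite (requires
#' `outcome`).
#'
#' @param afp,ca199,cea positive per-subject levels.
#' @param mode `"zsum"` or `"joint"`.
#' @param outcome 0/1 vector, required for `mode = "joint"`.
#' @return Numeric score vector.
#' @export
combination_score <- function(afp, ca199, cea, mode = c("zsum", "joint"),
                              outcome = NULL) {
  mode <- match.arg(mode)
  z <- cbind(standardize_exposure(afp), standardize_exposure(ca199),
             standardize_exposure(cea))
  if (mode == "zsum") {
    s <- rowSums(z)
    return(s / sd(s, na.rm = TRUE))
  }
  if (is.null(outcome)) stop("mode = 'joint' requires the outcome")
  df <- data.frame(.y = outcome, z1 = z[, 1], z2 = z[, 2], z3 = z[, 3])
  fit <- glm(.y ~ z1 + z2 + z3, data = df, family = binomial())
  unname(predict(fit, newdata = df, type = "link") - coef(fit)[1L])
}

# Standardized raw and corrected exposures for the four risk exposures.
build_exposures <- function(cohort, corrected,
                            combination_mode = "zsum") {
  stopifnot(inherits(corrected, "corrected_levels"),
            nrow(corrected) == nrow(cohort))
  out <- list()
  for (m in unname(BIOMARKERS)) {
    out[[names(BIOMARKERS)[match(m, BIOMARKERS)]]] <- list(
      raw = standardize_exposure(cohort[[m]]),
      corrected = standardize_exposure(corrected[[paste0(m, "_corrected")]]))
  }
  out[["combination"]] <- list(
    raw = combination_score(cohort$afp, cohort$ca199, cohort$cea,
                            mode = combination_mode,
                            outcome = cohort$event),
    corrected = combination_score(corrected$afp_corrected,
                                  corrected$ca199_corrected,
                                  corrected$cea_corrected,
                                  mode = combination_mode,
                                  outcome = cohort$event))
  out
}

# Nested covariate model definitions for the OR grid.
model_covariate_sets <- function() {
  list(`1` = character(0),
       `2` = c("age", "sex"),
       `3` = c("age", "sex", "bmi", "smoking", "drinking",
               "physical_activity", "family_history"))
}

#' Odds-ratio grid: raw versus corrected exposures under nested models
#'
#' Fits the full grid of unconditional logistic regressions: 4 exposures
#' (AFP, CA19-9, CEA, three-marker combination) x raw/corrected x three
#' nested covariate models — Model 1 crude, Model 2 age + sex, Model 3
#' age + sex + BMI + smoking + drinking + physical activity + family
#' history.  All exposures are per 1 SD of log level.
#'
#' @param cohort a `cohort_table`.
#' @param corrected output of [correct_levels()] on the same cohort.
#' @param models which covariate models to fit (subset of `1:3`).
#' @param combination_mode passed to [combination_score()].
#' @return data.frame of class `risk_model_grid`, 8 x `length(models)`
#'   rows: `exposure`, `type`, `model`, OR, CI, p, and fit metadata.
#' @export
run_model_suite <- function(cohort, corrected, models = 1:3,
                            combination_mode = c("zsum", "joint")) {
  combination_mode <- match.arg(combination_mode)
  stopifnot(all(models %in% 1:3))
  exposures <- build_exposures(cohort, corrected, combination_mode)
  sets <- model_covariate_sets()
  rows <- list()
  for (m in names(exposures)) {
    for (ty in c("raw", "corrected")) {
      for (mod in as.character(models)) {
        covs <- if (length(sets[[mod]])) {
          cohort[sets[[mod]]]
        }
        r <- fit_logistic(cohort$event, exposures[[m]][[ty]],
                          covariates = covs, label = m)
        r$type <- ty
        r$model <- as.integer(mod)
        rows[[paste(m, ty, mod)]] <- r
      }
    }
  }
  grid <- do.call(rbind, c(rows, make.row.names = FALSE))
  grid <- grid[c("exposure", "type", "model", "odds_ratio", "ci_lo",
                 "ci_hi", "p_value", "beta", "se", "n_events", "n_total",
                 "loglik")]
  class(grid) <- c("risk_model_grid", "data.frame")
  grid
}

#' @exportS3Method base::print
print.risk_model_grid <- function(x, ...) {
  cat("Odds ratios per 1 SD of log level (raw vs corrected)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
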
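# Simulated psychophysics: a logistic psychometric model of the depth-order
# report as a function of surround temporal coherence, simulated observers
# with per-subject random intercepts, and the standard analyses (logistic
# regression via IRLS, exact binomial proportions test, chi-square
# residual-normality check).

#' Psychometric model of the depth-order report
#'
#' The probability of reporting the center as the far surface (the percept
#' predicted by the accretion-deletion cue) is
#' `P(far | c) = lapse/2 + (1 - lapse) * plogis(beta0 + beta1 * c + gate)`,
#' where `c` is the surround temporal coherence in percent and `gate` is
#' `gating_boost` whenever an extraneous segmentation cue (a center/surround
#' contrast difference) delineates the occluder, and 0 otherwise.  Observers
#' carry normally distributed random intercepts (`subject_sd`).
#'
#' The defaults put the point of subjective equality at 75% coherence with
#' near-floor far-report rates under full flicker and near-ceiling rates with
#' a static surround, and a gating boost large enough to restore the
#' far percept under full flicker once a segmentation cue is present.
#'
#' @param beta0 intercept (logit units).
#' @param beta1 slope per percent temporal coherence.
#' @param lapse_rate lapse rate in `[0, 0.1]`.
#' @param gating_boost additive logit shift applied when a segmentation cue
#'   is available.
#' @param subject_sd standard deviation of per-subject random intercepts.
#' @return a `psychometric_model`.
#' @export
psychometric_model <- function(beta0 = -15, beta1 = 0.2, lapse_rate = 0.02,
                               gating_boost = 12, subject_sd = 0.5) {
  stopifnot(is.numeric(beta0), is.numeric(beta1),
            lapse_rate >= 0, lapse_rate <= 0.1, subject_sd >= 0)
  structure(
    list(beta0 = beta0, beta1 = beta1, lapse_rate = lapse_rate,
         gating_boost = gating_boost, subject_sd = subject_sd),
    class = "psychometric_model"
  )
}

#' Far-report probability under a psychometric model
#'
#' @param model a [psychometric_model()].
#' @param coherence_pct temporal coherence in percent.
#' @param gated logical; is a segmentation cue available?
#' @param subject_intercept additive per-subject logit offset.
#' @return probability in `[0, 1]` of reporting "center far".
#' @export
psychometric_prob <- function(model, coherence_pct, gated = FALSE,
                              subject_intercept = 0) {
  eta <- model$beta0 + model$beta1 * coherence_pct +
    ifelse(gated, model$gating_boost, 0) + subject_intercept
  model$lapse_rate / 2 + (1 - model$lapse_rate) * stats::plogis(eta)
}

#' Experimental design for a simulated session
#'
#' @param n_subjects number of simulated observers.
#' @param coherences_pct coherence levels tested, percent in `[50, 100]`.
#' @param conditions contrast-manipulation arms (subset of `"none"`,
#'   `"low-surround"`, `"low-center"`).
#' @param trials_per_cell trials per subject x coherence x condition cell.
#' @param directions_deg candidate motion directions, drawn per trial.
#' @return an `experiment_design`.
#' @export
experiment_design <- function(n_subjects = 11L,
                              coherences_pct = c(50, 60, 70, 80, 90, 100),
                              conditions = "none",
                              trials_per_cell = 20L,
                              directions_deg = c(0, 90, 180, 270)) {
  stopifnot(is_count(n_subjects), n_subjects >= 1,
            is_count(trials_per_cell), trials_per_cell >= 1,
            all(coherences_pct >= 50 & coherences_pct <= 100))
  conditions <- match.arg(conditions,
                          c("none", "low-surround", "low-center"),
                          several.ok = TRUE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         coherences_pct = coherences_pct, conditions = conditions,
         trials_per_cell = as.integer(trials_per_cell),
         directions_deg = directions_deg),
    class = "experiment_design"
  )
}

#' Simulate observer reports
#'
#' Draws one Bernoulli report per trial from the psychometric probability and
#' returns the trial table in randomly interleaved (seeded-permutation)
#' order.
#'
#' @param model a [psychometric_model()].
#' @param design an [experiment_design()].
#' @param seed integer seed.
#' @return data frame with columns `subject_id`, `trial`, `coherence_pct`,
#'   `condition`, `direction_deg`, `p_far`, `report` (`"far"`/`"near"`).
#' @export
simulate_responses <- function(model, design = experiment_design(), seed = 1L) {
  stopifnot(inherits(model, "psychometric_model"),
            inherits(design, "experiment_design"))
  with_seed(as.integer(seed), {
    intercepts <- stats::rnorm(design$n_subjects, 0, model$subject_sd)
    grid <- expand.grid(
      subject_id = seq_len(design$n_subjects),
      coherence_pct = design$coherences_pct,
      condition = design$conditions,
      rep = seq_len(design$trials_per_cell),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$direction_deg <- sample(design$directions_deg, nrow(grid),
                                 replace = TRUE)
    grid$p_far <- psychometric_prob(
      model, grid$coherence_pct, gated = grid$condition != "none",
      subject_intercept = intercepts[grid$subject_id]
    )
    grid$report <- ifelse(stats::runif(nrow(grid)) < grid$p_far,
                          "far", "near")
    grid <- grid[sample.int(nrow(grid)), ]  # random interleaving
    grid$trial <- seq_len(nrow(grid))
    rownames(grid) <- NULL
    grid[, c("subject_id", "trial", "coherence_pct", "condition",
             "direction_deg", "p_far", "report")]
  })
}

#' Fit a logistic psychometric function by maximum likelihood
#'
#' Fits `P(far) = plogis(beta0 + beta1 * coherence_pct)` to the trial table
#' by iteratively reweighted least squares ([stats::glm()] with a binomial
#' family).  The fit quality `r_squared` is the squared Pearson correlation
#' between the observed per-condition far-report proportions and the fitted
#' probabilities (a logistic regression has no canonical r-squared; the
#' choice is recorded in the returned object).  Degenerate data -- a single
#' coherence level, or all responses identical (complete separation) -- raise
#' an error rather than returning a silent fit; quasi-separation during the
#' fit is flagged on the result.
#'
#' @param dataset a trial table from [simulate_responses()] (needs columns
#'   `coherence_pct` and `report`; `subject_id` if `by_subject = TRUE`).
#' @param by_subject compute residuals per subject x coherence cell rather
#'   than per coherence level.
#' @return a `psychometric_fit`: list with `coefficients`, `std_errors`,
#'   `r_squared`, `residuals` (standardized per-cell residuals), `fitted`
#'   (per-cell table, including a `normal_ok` flag marking cells whose
#'   expected counts support a normal approximation), `converged`,
#'   `separation`, `r_squared_method`.
#' @export
fit_logistic <- function(dataset, by_subject = FALSE) {
  stopifnot(all(c("coherence_pct", "report") %in% names(dataset)))
  y <- dataset$report == "far"
  if (length(unique(dataset$coherence_pct)) < 2L) {
    stop("need at least 2 distinct coherence levels")
  }
  if (all(y) || !any(y)) {
    stop("complete separation: all responses identical; no logistic fit")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ coherence_pct, family = stats::binomial(),
               data = data.frame(y = y,
                                 coherence_pct = dataset$coherence_pct)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  cell_vars <- if (by_subject) {
    list(subject_id = dataset$subject_id,
         coherence_pct = dataset$coherence_pct)
  } else {
    list(coherence_pct = dataset$coherence_pct)
  }
  agg <- stats::aggregate(y, by = cell_vars, FUN = mean)
  n_cell <- stats::aggregate(y, by = cell_vars, FUN = length)
  names(agg)[ncol(agg)] <- "observed"
  agg$n <- n_cell$x
  agg$fitted <- stats::plogis(co[1] + co[2] * agg$coherence_pct)
  agg$residual <- (agg$observed - agg$fitted) /
    sqrt(pmax(agg$fitted * (1 - agg$fitted), 1e-12) / agg$n)
  # Standardized binomial residuals are only approximately normal when both
  # expected counts are >= 5; flag the cells where that holds so normality
  # checks can be restricted to them.
  agg$normal_ok <- pmin(agg$fitted, 1 - agg$fitted) * agg$n >= 5
  structure(
    list(coefficients = co, std_errors = se,
         r_squared = stats::cor(agg$observed, agg$fitted)^2,
         residuals = agg$residual, fitted = agg,
         converged = fit$converged, separation = separation,
         r_squared_method = "squared Pearson correlation, observed vs fitted per-condition proportions"),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric fit: logit P(far) = %.3f + %.4f * coherence_pct\n",
    x$coefficients[1], x$coefficients[2]
  ))
  cat(sprintf("  r^2 = %.3f (%s)\n", x$r_squared, x$r_squared_method))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separation) cat("  WARNING: quasi-complete separation detected\n")
  invisible(x)
}

#' Exact two-sided binomial proportions test
#'
#' Tests `k` successes in `n` trials against success probability `p0` with
#' the exact binomial test, two-sided by the minimum-likelihood method (the
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one, ties included).
#'
#' @param k_far observed successes (e.g. "center far" reports).
#' @param n number of trials.
#' @param p0 null success probability.
#' @return two-sided p-value.
#' @export
binomial_proportions_test <- function(k_far, n, p0 = 0.5) {
  stopifnot(is_count(k_far), is_count(n), k_far <= n,
            is_prob(p0), p0 > 0, p0 < 1)
  stats::binom.test(k_far, n, p = p0)$p.value
}

#' Chi-square goodness-of-fit test for residual normality
#'
#' Standardizes the residuals and compares their distribution against the
#' standard normal with a Pearson chi-square test over `n_bins` equiprobable
#' bins.  The bin count is reduced until every bin's expected count is at
#' least 5; degrees of freedom are `bins - 3` (two estimated moments).  Too
#' few residuals for 4 valid bins is an error.
#'
#' @param residuals numeric residual vector.
#' @param n_bins maximum number of equiprobable bins (default 20).
#' @return list with `statistic`, `df`, `p_value`, `n_bins`.
#' @export
residual_normality_chisq <- function(residuals, n_bins = 20L) {
  x <- residuals[is.finite(residuals)]
  n <- length(x)
  k <- as.integer(min(as.integer(n_bins), floor(n / 5)))
  if (k < 4L) {
    stop("too few residuals: need at least 20 for 4 bins of expected count 5")
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("residuals have zero variance")
  z <- (x - mean(x)) / s
  breaks <- stats::qnorm(seq(0, 1, length.out = k + 1))
  observed <- table(cut(z, breaks = breaks, include.lowest = TRUE))
  expected <- n / k
  stat <- sum((as.numeric(observed) - expected)^2 / expected)
  df <- k - 3L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), n_bins = k)
}
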
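# The statistical chain: baseline-anchored z-scoring of behavior, change-score
# residualization, scrubbing-variance removal, standardized-beta OLS with
# per-domain Benjamini-Hochberg families, permutation testing,
# percentile-bootstrap mediation, and exhaustive BIC model selection.

#' Standardize behavioral scores against baseline statistics
#'
#' `z = (score - baseline_mean) / baseline_sd`. Follow-up scores are
#' standardized with the *baseline* mean and SD, so their sample mean is not 0
#' in general. For speed (reaction-time) tasks the z-score is sign-inverted so
#' that higher always means better performance.
#'
#' @param scores numeric scores (any timepoint).
#' @param baseline_mean,baseline_sd statistics computed across participants at
#'   baseline for the same task.
#' @param is_speed logical; TRUE for reaction-time tasks.
#' @return Numeric z-scores.
#' @export
standardize_behavior <- function(scores, baseline_mean, baseline_sd,
                                 is_speed = FALSE) {
  if (!is.finite(baseline_sd) || baseline_sd <= 0)
    stop("degenerate scale: baseline SD must be positive")
  z <- (scores - baseline_mean) / baseline_sd
  if (isTRUE(is_speed)) z <- -z
  z
}

#' Residualize change scores on baseline
#'
#' Returns the residuals of the least-squares fit of `change` on an intercept
#' and `baseline`, the standard adjustment that accounts for baseline level
#' while preserving degrees of freedom in downstream models. Missing values
#' propagate (the fit uses complete pairs; residuals are NA where either input
#' is NA).
#'
#' @param change follow-up minus baseline values.
#' @param baseline baseline values.
#' @return Residualized change, same length as the inputs.
#' @export
residualize_on_baseline <- function(change, baseline) {
  if (length(change) != length(baseline))
    stop("change and baseline must have equal length")
  ok <- complete.cases(change, baseline)
  if (sum(ok) < 3L)
    stop("insufficient data: need at least 3 complete observations")
  out <- rep(NA_real_, length(change))
  if (sd(baseline[ok]) == 0) {
    warning("constant baseline: returning centered change")
    out[ok] <- change[ok] - mean(change[ok])
    return(out)
  }
  fit <- lm(change[ok] ~ baseline[ok])
  out[ok] <- resid(fit)
  out
}

#' Remove scrubbing variance from a brain measure
#'
#' Residualizes a brain measure on the per-domain mean scrubbing value
#' (fraction of motion-replaced volumes), removing motion-attributable
#' variance prior to regression. Mechanically identical to
#' [residualize_on_baseline()].
#'
#' @param measure brain measure values (e.g. AUC, segregation).
#' @param scrubbing per-participant mean scrubbing for the domain.
#' @return Adjusted (residualized) measure.
#' @export
remove_scrubbing <- function(measure, scrubbing) {
  residualize_on_baseline(measure, scrubbing)
}

#' Ordinary least squares with standardized betas and partial eta-squared
#'
#' Fits `outcome ~ predictors` by OLS with listwise deletion and reports, per
#' predictor: the standardized coefficient
#' `beta = b * SD(predictor) / SD(outcome)`, the raw coefficient with its
#' t-based 95% confidence interval, the p-value, and partial eta-squared
#' `t^2 / (t^2 + residual df)`.
#'
#' @param outcome numeric outcome vector.
#' @param predictors data.frame of numeric predictors (named columns).
#' @param conf_level confidence level for the raw-coefficient CI.
#' @return An object of class `ph_model`: list with `coefficients` (a
#'   data.frame), `n`, `r_squared`, `adj_r_squared`, `bic`, `fit` (the `lm`).
#' @export
fit_model <- function(outcome, predictors, conf_level = 0.95) {
  predictors <- as.data.frame(predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    stop("predictors must be named columns")
  dat <- cbind(data.frame(.outcome = outcome), predictors)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  p <- ncol(predictors)
  if (n <= p + 1L)
    stop("insufficient data: ", n, " complete cases for ", p, " predictors")
  fit <- lm(.outcome ~ ., data = dat)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("collinearity: predictor(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "),
         " are aliased in the design")
  sm <- summary(fit)
  ct <- sm$coefficients[-1L, , drop = FALSE]   # drop intercept
  df_res <- fit$df.residual
  sd_y <- sd(dat$.outcome)
  sd_x <- vapply(dat[rownames(ct)], sd, numeric(1))
  tcrit <- qt(1 - (1 - conf_level) / 2, df_res)
  tval <- ct[, "t value"]
  coefs <- data.frame(
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    beta_std = ct[, "Estimate"] * sd_x / sd_y,
    ci_low = ct[, "Estimate"] - tcrit * ct[, "Std. Error"],
    ci_high = ct[, "Estimate"] + tcrit * ct[, "Std. Error"],
    p = ct[, "Pr(>|t|)"],
    eta_p2 = tval^2 / (tval^2 + df_res),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coefs,
    n = n,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    bic = BIC(fit),
    fit = fit
  ), class = "ph_model")
}

#' @export
print.ph_model <- function(x, digits = 4, ...) {
  cat(sprintf("OLS model (n = %d, R2 = %.3f, adj R2 = %.3f, BIC = %.1f)\n",
              x$n, x$r_squared, x$adj_r_squared, x$bic))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg family adjustment
#'
#' Step-up FDR adjustment of a family of p-values, with rejection flags at
#' level `q`.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values) and `reject` (logical).
#' @export
fdr_family <- function(p_values, q = 0.05) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("invalid input: p-values must lie in [0, 1]")
  adjusted <- p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}

#' Permutation test of a regression coefficient
#'
#' Builds a null distribution by jointly permuting the rows of the full
#' predictor block against the outcome (within-row predictor assignment is
#' preserved) and refitting the OLS model. The statistic is the absolute
#' standardized beta of the target predictor; the p-value is the fraction of
#' permutations whose null statistic is at least the observed one. With
#' `plus_one = TRUE` the small-sample correction `(count + 1) / (n_perm + 1)`
#' is used instead of the literal ratio.
#'
#' @param outcome numeric outcome.
#' @param predictors data.frame of predictors.
#' @param target name of the predictor whose coefficient is tested.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param plus_one logical; apply the `(+1)/(N+1)` correction (default FALSE).
#' @return List of class `ph_permutation` with `p`, `observed` (|std beta|),
#'   `n_perm`, `seed`, `null` (the null statistics).
#' @export
permutation_test <- function(outcome, predictors, target, n_perm = 10000L,
                             seed = 1L, plus_one = FALSE) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("invalid parameter: n_perm must be >= 1")
  predictors <- as.data.frame(predictors)
  if (!target %in% names(predictors))
    stop("target predictor '", target, "' not found")
  dat <- cbind(data.frame(.outcome = outcome), predictors)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  y <- dat$.outcome
  X <- model.matrix(~ ., dat[names(predictors)])
  j <- match(target, colnames(X))
  n <- nrow(X)
  scale_j <- sd(X[, j]) / sd(y)   # invariant under row permutation
  observed <- abs(.lm.fit(X, y)$coefficients[j]) * scale_j
  set.seed(as.integer(seed))
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Xp <- X[sample.int(n), , drop = FALSE]
    null[b] <- abs(.lm.fit(Xp, y)$coefficients[j]) * scale_j
  }
  count <- sum(null >= observed)
  p <- if (plus_one) (count + 1) / (n_perm + 1) else count / n_perm
  structure(list(p = p, observed = observed, n_perm = n_perm, seed = seed,
                 null = null),
            class = "ph_permutation")
}

#' @export
print.ph_permutation <- function(x, ...) {
  cat(sprintf("Permutation test: observed |std beta| = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$observed, x$p, x$n_perm, x$seed))
  invisible(x)
}

#' Percentile-bootstrap mediation analysis
#'
#' Three-step product-of-coefficients mediation: (1) `m ~ x + covariates`
#' gives path `a`; (2) `y ~ x + m + covariates` gives the direct path `c'`
#' and path `b`; (3) `y ~ x + covariates` gives the total effect `c`. The
#' average causal mediation effect (ACME, indirect effect) is `a * b`, which
#' for nested OLS models equals `c - c'` exactly. Participants are resampled
#' with replacement; 95% confidence intervals are percentile intervals over
#' the bootstrap distribution, and the two-sided bootstrap p-value is twice
#' the smaller tail fraction of the distribution on either side of 0.
#'
#' @param x exposure vector.
#' @param m mediator vector.
#' @param y outcome vector.
#' @param covariates optional data.frame of covariates.
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `ph_mediation` with point estimates, percentile
#'   CIs and bootstrap p-values for `acme`, `direct`, `total`, and
#'   `prop_mediated` (= acme / total).
#' @export
mediation_bootstrap <- function(x, m, y, covariates = NULL, n_boot = 10000L,
                                seed = 1L, conf_level = 0.95) {
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("invalid parameter: n_boot must be >= 1")
  dat <- data.frame(.x = x, .m = m, .y = y)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 30L) stop("insufficient data: need at least 30 complete cases")
  if (sd(dat$.m) == 0) stop("degenerate mediator: zero variance")
  Z <- if (ncol(dat) > 3L)
    model.matrix(~ ., dat[-(1:3)]) else matrix(1, n, 1L)
  Xa <- cbind(Z, x = dat$.x)                 # m ~ x + cov  (path a)
  Xb <- cbind(Z, x = dat$.x, m = dat$.m)     # y ~ x + m + cov  (c', b)
  jx_a <- ncol(Xa); jx_b <- ncol(Xb) - 1L; jm_b <- ncol(Xb)

  paths <- function(rows) {
    a <- .lm.fit(Xa[rows, , drop = FALSE], dat$.m[rows])$coefficients[jx_a]
    cb <- .lm.fit(Xb[rows, , drop = FALSE], dat$.y[rows])$coefficients
    direct <- cb[jx_b]; b <- cb[jm_b]
    # total effect from the reduced model y ~ x + cov; equals direct + a*b
    # exactly for OLS on the same cases
    total <- .lm.fit(Xa[rows, , drop = FALSE], dat$.y[rows])$coefficients[jx_a]
    acme <- a * b
    c(acme = acme, direct = direct, total = total,
      prop = if (total != 0) acme / total else NA_real_)
  }
  est <- paths(seq_len(n))
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, 4L,
                 dimnames = list(NULL, c("acme", "direct", "total", "prop")))
  for (bt in seq_len(n_boot)) {
    rows <- sample.int(n, n, replace = TRUE)
    boot[bt, ] <- paths(rows)
  }
  alpha <- (1 - conf_level) / 2
  ci <- apply(boot, 2L, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  pboot <- apply(boot, 2L, function(v) {
    v <- v[!is.na(v)]
    2 * min(mean(v <= 0), mean(v >= 0))
  })
  structure(list(
    acme = unname(est["acme"]), direct = unname(est["direct"]),
    total = unname(est["total"]), prop_mediated = unname(est["prop"]),
    ci = ci, p = pboot, n = n, n_boot = n_boot, seed = seed,
    conf_level = conf_level
  ), class = "ph_mediation")
}

#' @export
print.ph_mediation <- function(x, ...) {
  cat(sprintf("Percentile-bootstrap mediation (n = %d, %d iterations, seed %d)\n",
              x$n, x$n_boot, x$seed))
  line <- function(lab, v, cl, ch, p)
    cat(sprintf("  %-14s %8.4f  [%8.4f, %8.4f]  p = %.4g\n", lab, v, cl, ch, p))
  line("ACME", x$acme, x$ci[1, "acme"], x$ci[2, "acme"], x$p["acme"])
  line("direct", x$direct, x$ci[1, "direct"], x$ci[2, "direct"], x$p["direct"])
  line("total", x$total, x$ci[1, "total"], x$ci[2, "total"], x$p["total"])
  line("prop. mediated", x$prop_mediated, x$ci[1, "prop"], x$ci[2, "prop"],
       x$p["prop"])
  invisible(x)
}

#' Exhaustive BIC model search
#'
#' Fits every non-empty subset of the candidate predictors (`2^k - 1` models;
#' 127 for seven candidates) by OLS on the common complete cases and ranks the
#' models by BIC (Gaussian likelihood with the variance profiled out). The
#' winner is reported with its overall F statistic, p-value and adjusted R2.
#'
#' @param outcome numeric outcome.
#' @param candidates data.frame of candidate predictors.
#' @return Object of class `ph_bic`: `ranking` (data.frame sorted by BIC),
#'   `winner` (list with terms, fit statistics), `n`.
#' @export
bic_search <- function(outcome, candidates) {
  candidates <- as.data.frame(candidates)
  k <- ncol(candidates)
  if (k < 1L) stop("need at least one candidate predictor")
  dat <- cbind(data.frame(.outcome = outcome), candidates)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= k + 1L)
    stop("insufficient data: ", n, " complete cases for the largest subset")
  subsets <- seq_len(2L^k - 1L)
  rows <- lapply(subsets, function(s) {
    terms <- names(candidates)[bitwAnd(s, bitwShiftL(1L, seq_len(k) - 1L)) > 0L]
    fit <- lm(.outcome ~ ., data = dat[c(".outcome", terms)])
    sm <- summary(fit)
    data.frame(model = paste(terms, collapse = "+"),
               n_predictors = length(terms),
               bic = BIC(fit), adj_r_squared = sm$adj.r.squared,
               stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(ranking$bic, ranking$n_predictors, ranking$model), ]
  rownames(ranking) <- NULL
  win_terms <- strsplit(ranking$model[1L], "+", fixed = TRUE)[[1L]]
  wfit <- lm(.outcome ~ ., data = dat[c(".outcome", win_terms)])
  wsm <- summary(wfit)
  fstat <- wsm$fstatistic
  structure(list(
    ranking = ranking,
    winner = list(terms = win_terms,
                  f = unname(fstat["value"]),
                  df1 = unname(fstat["numdf"]), df2 = unname(fstat["dendf"]),
                  p = unname(pf(fstat["value"], fstat["numdf"],
                                fstat["dendf"], lower.tail = FALSE)),
                  adj_r_squared = wsm$adj.r.squared,
                  bic = BIC(wfit)),
    n = n
  ), class = "ph_bic")
}

#' @export
print.ph_bic <- function(x, ...) {
  w <- x$winner
  cat(sprintf("BIC search over %d models (n = %d)\n", nrow(x$ranking), x$n))
  cat(sprintf("  winner: %s\n", paste(w$terms, collapse = " + ")))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g, adj R2 = %.3f, BIC = %.1f\n",
              w$df1, w$df2, w$f, w$p, w$adj_r_squared, w$bic))
  invisible(x)
}
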
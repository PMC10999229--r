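# End-to-end analysis over a cohort: per-participant topological and graph
# measures, then the full regression chain with per-domain FDR families,
# plus convenience wrappers for mediation and BIC selection on the measured
# table.

#' Compute per-participant network measures for a cohort
#'
#' For every participant, timepoint and domain of a [simulate_cohort()]
#' object (or any cohort with the same structure), computes the Betti-0 AUC
#' under edge-density filtration and the whole-brain system segregation on
#' the positive-edge matrix (optionally also modularity Q), and z-scores the
#' behavioral scores against the baseline mean and SD of each task (speed
#' scores sign-inverted). Returns one row per participant with columns
#' `auc_<domain>_<tp>`, `seg_<domain>_<tp>`, `q_<domain>_<tp>` (if requested)
#' and `beh_<domain>_<tp>` joined to the covariates.
#'
#' @param cohort a `ph_cohort` object.
#' @param step filtration step for [betti0_curve()] (default 0.01).
#' @param mode filtration mode, `"density"` or `"correlation"`.
#' @param compute_q logical; also run [modularity_q()] per matrix (slower).
#' @return A data.frame (the cohort measure table), one row per participant.
#' @export
compute_cohort_measures <- function(cohort, step = 0.01,
                                    mode = c("density", "correlation"),
                                    compute_q = FALSE) {
  stopifnot(inherits(cohort, "ph_cohort"))
  mode <- match.arg(mode)
  tab <- cohort$covariates
  doms <- cohort$config$domains
  for (d in doms) {
    for (tp in c("bl", "fu")) {
      mats <- cohort$data[[d]][[tp]]
      if (cohort$store == "timeseries")
        mats <- lapply(mats, correlation_matrix)
      aucs <- vapply(mats, function(m) auc(betti0_curve(m, step, mode)),
                     numeric(1))
      segs <- vapply(mats, function(m)
        system_segregation(positive_part(m), cohort$partition)$segregation,
        numeric(1))
      tab[[paste0("auc_", d, "_", tp)]] <- unname(aucs)
      tab[[paste0("seg_", d, "_", tp)]] <- unname(segs)
      if (compute_q) {
        qs <- vapply(mats, function(m) modularity_q(positive_part(m))$q,
                     numeric(1))
        tab[[paste0("q_", d, "_", tp)]] <- unname(qs)
      }
    }
    beh <- cohort$behavior[cohort$behavior$domain == d, ]
    bl <- beh[beh$timepoint == "bl", ]
    fu <- beh[beh$timepoint == "fu", ]
    bl <- bl[match(tab$id, bl$id), ]
    fu <- fu[match(tab$id, fu$id), ]
    mu <- mean(bl$score, na.rm = TRUE)
    sdv <- sd(bl$score, na.rm = TRUE)
    is_speed <- bl$is_speed[1L]
    tab[[paste0("beh_", d, "_bl")]] <-
      standardize_behavior(bl$score, mu, sdv, is_speed)
    tab[[paste0("beh_", d, "_fu")]] <-
      standardize_behavior(fu$score, mu, sdv, is_speed)
  }
  tab
}

#' Full regression analysis of a cohort measure table
#'
#' For each cognitive domain, fits the brain-measure models (outcome AUC or
#' segregation; baseline, follow-up and change contrasts; predictors Age,
#' NART, Education, Sex, cortical thickness, WMH) and the behavior models
#' (same predictors plus the brain measure), assembles the per-domain family
#' of 78 predictor p-values (2 brain measures x 3 contrasts x 6 predictors +
#' 2 behavior variants x 3 contrasts x 7 predictors) and applies
#' Benjamini-Hochberg FDR within each domain.
#'
#' Scrubbing variance is removed from the brain measures before modeling;
#' change scores (brain measures, behavior, CT, WMH) are follow-up minus
#' baseline residualized on baseline.
#'
#' @param tab a cohort measure table from [compute_cohort_measures()] (or an
#'   equivalently named data.frame).
#' @param domains domains to analyze (default: all with `auc_*` columns).
#' @param q FDR level (default 0.05).
#' @return Object of class `ph_analysis` with `results` (long data.frame:
#'   domain, outcome, time, predictor, beta_std, estimate, ci_low, ci_high,
#'   p, fdr_p, reject, eta_p2, n), `family_sizes`, `q`.
#' @export
run_full_analysis <- function(tab, domains = NULL, q = 0.05) {
  if (is.null(domains)) {
    domains <- unique(sub("^auc_(.*)_bl$", "\\1",
                          grep("^auc_.*_bl$", names(tab), value = TRUE)))
  }
  if (length(domains) < 1L) stop("no domains with auc_* columns found")
  all_rows <- list()
  family_sizes <- setNames(integer(length(domains)), domains)
  for (dom in domains) {
    vars <- domain_variables(tab, dom)
    dom_rows <- list()
    add <- function(outcome_lab, time_lab, outcome, preds) {
      fm <- fit_model(outcome, preds)
      cf <- fm$coefficients
      dom_rows[[length(dom_rows) + 1L]] <<- data.frame(
        domain = dom, outcome = outcome_lab, time = time_lab,
        predictor = cf$term, beta_std = cf$beta_std, estimate = cf$estimate,
        ci_low = cf$ci_low, ci_high = cf$ci_high, p = cf$p,
        eta_p2 = cf$eta_p2, n = fm$n, stringsAsFactors = FALSE)
    }
    for (meas in c("auc", "seg")) {
      add(meas, "bl", vars[[paste0(meas, "_bl")]], vars$pred_bl)
      add(meas, "fu", vars[[paste0(meas, "_fu")]], vars$pred_fu)
      add(meas, "fu-bl", vars[[paste0("d_", meas)]], vars$pred_d)
    }
    for (meas in c("auc", "seg")) {
      lab <- paste0("behavior_", meas)
      add(lab, "bl", vars$beh_bl,
          cbind(vars$pred_bl, measure = vars[[paste0(meas, "_bl")]]))
      add(lab, "fu", vars$beh_fu,
          cbind(vars$pred_fu, measure = vars[[paste0(meas, "_fu")]]))
      add(lab, "fu-bl", vars$d_beh,
          cbind(vars$pred_d, measure = vars[[paste0("d_", meas)]]))
    }
    res <- do.call(rbind, dom_rows)
    fam <- fdr_family(res$p, q)
    res$fdr_p <- fam$adjusted
    res$reject <- fam$reject
    family_sizes[dom] <- nrow(res)
    all_rows[[dom]] <- res
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  structure(list(results = results, family_sizes = family_sizes,
                 domains = domains, q = q),
            class = "ph_analysis")
}

# Assemble the cleaned per-domain variables used by all models: scrubbing-
# residualized brain measures, baseline-residualized change scores, and the
# demographic predictor blocks for each contrast.
domain_variables <- function(tab, dom) {
  need <- c("age", "nart", "edu", "sex", "ct_bl", "ct_fu", "wmh_bl", "wmh_fu",
            paste0("scrub_", dom),
            paste0(rep(c("auc_", "seg_", "beh_"), each = 2), dom,
                   c("_bl", "_fu")))
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("measure table is missing column(s): ", paste(missing, collapse = ", "))
  scrub <- tab[[paste0("scrub_", dom)]]
  clean <- function(col) remove_scrubbing(tab[[col]], scrub)
  auc_bl <- clean(paste0("auc_", dom, "_bl"))
  auc_fu <- clean(paste0("auc_", dom, "_fu"))
  seg_bl <- clean(paste0("seg_", dom, "_bl"))
  seg_fu <- clean(paste0("seg_", dom, "_fu"))
  d_ct <- residualize_on_baseline(tab$ct_fu - tab$ct_bl, tab$ct_bl)
  d_wmh <- residualize_on_baseline(tab$wmh_fu - tab$wmh_bl, tab$wmh_bl)
  beh_bl <- tab[[paste0("beh_", dom, "_bl")]]
  beh_fu <- tab[[paste0("beh_", dom, "_fu")]]
  demo <- data.frame(age = tab$age, nart = tab$nart, edu = tab$edu,
                     sex = tab$sex)
  list(
    auc_bl = auc_bl, auc_fu = auc_fu,
    seg_bl = seg_bl, seg_fu = seg_fu,
    d_auc = residualize_on_baseline(auc_fu - auc_bl, auc_bl),
    d_seg = residualize_on_baseline(seg_fu - seg_bl, seg_bl),
    beh_bl = beh_bl, beh_fu = beh_fu,
    d_beh = residualize_on_baseline(beh_fu - beh_bl, beh_bl),
    d_ct = d_ct, d_wmh = d_wmh,
    pred_bl = cbind(demo, ct = tab$ct_bl, wmh = tab$wmh_bl),
    pred_fu = cbind(demo, ct = tab$ct_fu, wmh = tab$wmh_fu),
    pred_d = cbind(demo, ct = d_ct, wmh = d_wmh)
  )
}

#' @export
print.ph_analysis <- function(x, ...) {
  cat(sprintf("Cohort regression analysis: %d domain(s), FDR q = %.2f\n",
              length(x$domains), x$q))
  cat("  per-domain family sizes:",
      paste(sprintf("%s = %d", names(x$family_sizes), x$family_sizes),
            collapse = ", "), "\n")
  sig <- x$results[x$results$reject, ]
  cat(sprintf("  %d of %d predictor tests FDR-significant\n",
              nrow(sig), nrow(x$results)))
  invisible(x)
}

#' @export
summary.ph_analysis <- function(object, ...) {
  sig <- object$results[object$results$reject,
                        c("domain", "outcome", "time", "predictor",
                          "beta_std", "p", "fdr_p", "eta_p2")]
  rownames(sig) <- NULL
  cat("FDR-significant predictors (q =", object$q, "):\n")
  if (nrow(sig) == 0) cat("  none\n") else
    print(format(sig, digits = 3), row.names = FALSE)
  invisible(sig)
}

#' Mediation of the age effect on behavioral change by the change in AUC
#'
#' Convenience wrapper: on a cohort measure table, runs the percentile-
#' bootstrap mediation with exposure Age, mediator the baseline-residualized
#' change in (scrubbing-cleaned) AUC, outcome the baseline-residualized
#' change in behavior, and covariates NART, Education, Sex, change in CT and
#' change in WMH.
#'
#' @param tab cohort measure table.
#' @param domain cognitive domain to test.
#' @inheritParams mediation_bootstrap
#' @return A `ph_mediation` object.
#' @export
cohort_mediation <- function(tab, domain, n_boot = 10000L, seed = 1L) {
  vars <- domain_variables(tab, domain)
  mediation_bootstrap(
    x = tab$age, m = vars$d_auc, y = vars$d_beh,
    covariates = data.frame(nart = tab$nart, edu = tab$edu, sex = tab$sex,
                            d_ct = vars$d_ct, d_wmh = vars$d_wmh),
    n_boot = n_boot, seed = seed)
}

#' Exhaustive BIC model selection for behavioral change
#'
#' Convenience wrapper: candidate predictors are Age, NART, Education, Sex,
#' change in CT, change in WMH, and the change in AUC; all `2^7 - 1 = 127`
#' subsets are ranked by BIC for the baseline-residualized behavioral change
#' of one domain.
#'
#' @param tab cohort measure table.
#' @param domain cognitive domain.
#' @return A `ph_bic` object.
#' @export
cohort_bic_search <- function(tab, domain) {
  vars <- domain_variables(tab, domain)
  bic_search(vars$d_beh,
             data.frame(age = tab$age, nart = tab$nart, edu = tab$edu,
                        sex = tab$sex, d_ct = vars$d_ct, d_wmh = vars$d_wmh,
                        d_auc = vars$d_auc))
}
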
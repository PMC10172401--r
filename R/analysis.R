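#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' q(k) = min over j >= k of p(j) * m / j, capped at 1. NAs propagate and
#' do not count toward m.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("bh_fdr: p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(q)
  o <- order(p[ok])
  ps <- p[ok][o]
  qs <- rev(cummin(rev(ps * m / seq_len(m))))
  q[ok[o]] <- pmin(1, qs)
  q
}

feature_set_of <- function(features) {
  fs <- feature_sets()
  out <- rep("other", length(features))
  for (s in names(fs)) out[features %in% fs[[s]]] <- s
  out
}

tidy_gee_row <- function(fit, term) {
  data.frame(beta = unname(fit$coefficients[term]),
             se = unname(fit$robust_se[term]),
             ci_lower = unname(fit$ci_lower[term]),
             ci_upper = unname(fit$ci_upper[term]),
             p = unname(fit$p_value[term]),
             n_scans = fit$n_obs, n_subjects = fit$n_clusters)
}

#' Cohort comparison of placental features
#'
#' Per feature, two GEE models with subject clustering and robust SEs:
#' the base model `feature ~ cohort + ga_at_mri_weeks` and the
#' distress-adjusted model adding the binary `high_distress` mediator.
#' Benjamini-Hochberg q-values are computed within each feature set
#' (shape 3, histogram 4, co-occurrence 6, run-length 10) separately for
#' each model. Per-feature fitting errors are caught and reported as NA
#' rows rather than aborting the batch.
#'
#' @param data cohort table with feature columns, `cohort`,
#'   `ga_at_mri_weeks`, `subject_id` and (for the adjusted model)
#'   `high_distress`.
#' @param features feature columns to analyze (default: all 23).
#' @param corstr working correlation (default unstructured).
#' @return data.frame: feature, set, model ("base"/"distress_adjusted"),
#'   LS means (pre/pandemic with SEs), beta, CI, p, q, n.
#' @export
cohort_comparison <- function(data, features = feature_names(),
                              corstr = "unstructured") {
  if (!"high_distress" %in% names(data))
    data <- derive_high_distress(data)
  models <- list(base = stats::reformulate(c("cohort", "ga_at_mri_weeks")),
                 distress_adjusted =
                   stats::reformulate(c("cohort", "ga_at_mri_weeks",
                                        "high_distress")))
  rows <- list()
  for (f in features) {
    for (mn in names(models)) {
      fml <- stats::update(models[[mn]], stats::as.formula(paste(f, "~ .")))
      row <- tryCatch({
        fit <- gee_fit(fml, data, id = "subject_id", corstr = corstr)
        lm_ <- ls_means(fit, "cohort")
        cbind(data.frame(feature = f, set = feature_set_of(f), model = mn,
                         ls_mean_pre = lm_$ls_mean[1], ls_se_pre = lm_$se[1],
                         ls_mean_pandemic = lm_$ls_mean[2],
                         ls_se_pandemic = lm_$se[2]),
              tidy_gee_row(fit, "cohort"))
      }, error = function(e) {
        warning("cohort_comparison: ", f, " (", mn, ") failed: ",
                conditionMessage(e))
        data.frame(feature = f, set = feature_set_of(f), model = mn,
                   ls_mean_pre = NA, ls_se_pre = NA, ls_mean_pandemic = NA,
                   ls_se_pandemic = NA, beta = NA, se = NA, ci_lower = NA,
                   ci_upper = NA, p = NA, n_scans = NA, n_subjects = NA)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (mn in names(models)) for (s in unique(out$set)) {
    i <- out$model == mn & out$set == s
    out$q[i] <- bh_fdr(out$p[i])
  }
  rownames(out) <- NULL
  out
}

#' Three-step mediation analysis through maternal distress
#'
#' Step 1: `feature ~ cohort + ga_at_mri_weeks` per feature. Step 2:
#' `measure ~ cohort + ga_at_mri_weeks` for each distress measure; measures
#' with cohort p below `alpha` are the candidate mediators. Step 3: for
#' each feature and each significant measure, the Step-1 model with that
#' measure added; `significance_altered` records whether the cohort
#' effect's significance at `alpha` crossed between Step 1 and Step 3 (in
#' either direction). When Step 2 finds no significant measure, Step 3 is
#' skipped and noted.
#'
#' @param data cohort table (as [cohort_comparison()], plus the four
#'   distress score columns).
#' @param features feature columns (default all 23).
#' @param measures distress measures to test as mediators.
#' @param alpha significance level for the crossing criterion.
#' @param corstr working correlation.
#' @return object of class `mediation_report`: list with `step1`, `step2`,
#'   `step3` data.frames, `mediators_detected`, `alpha`, `note`.
#' @export
mediation <- function(data, features = feature_names(),
                      measures = c("ssai", "stai", "pss", "epds"),
                      alpha = 0.05, corstr = "unstructured") {
  fit_one <- function(lhs, rhs) {
    fml <- stats::reformulate(rhs, response = lhs)
    gee_fit(fml, data, id = "subject_id", corstr = corstr)
  }
  step1 <- do.call(rbind, lapply(features, function(f)
    cbind(data.frame(feature = f),
          tidy_gee_row(fit_one(f, c("cohort", "ga_at_mri_weeks")),
                       "cohort"))))
  step2 <- do.call(rbind, lapply(measures, function(m)
    cbind(data.frame(measure = m),
          tidy_gee_row(fit_one(m, c("cohort", "ga_at_mri_weeks")),
                       "cohort"))))
  sig_measures <- step2$measure[step2$p < alpha]
  note <- NULL
  step3 <- NULL
  if (!length(sig_measures)) {
    note <- paste0("no distress measure associated with cohort at alpha = ",
                   alpha, "; Step 3 skipped")
  } else {
    step3 <- do.call(rbind, lapply(features, function(f) {
      do.call(rbind, lapply(sig_measures, function(m) {
        r <- tidy_gee_row(fit_one(f, c("cohort", "ga_at_mri_weeks", m)),
                          "cohort")
        p1 <- step1$p[step1$feature == f]
        b1 <- step1$beta[step1$feature == f]
        cbind(data.frame(feature = f, mediator = m), r,
              data.frame(step1_beta = b1, step1_p = p1,
                         significance_altered = (p1 < alpha) != (r$p < alpha)))
      }))
    }))
  }
  structure(list(step1 = step1, step2 = step2, step3 = step3,
                 mediators_detected = if (is.null(step3)) character(0) else
                   unique(step3$mediator[step3$significance_altered]),
                 alpha = alpha, note = note),
            class = "mediation_report")
}

#' @export
print.mediation_report <- function(x, ...) {
  cat("Mediation analysis (alpha =", x$alpha, ")\n")
  sig2 <- x$step2$measure[x$step2$p < x$alpha]
  cat("Step 2 significant measures:",
      if (length(sig2)) paste(sig2, collapse = ", ") else "none", "\n")
  if (!is.null(x$note)) cat(x$note, "\n")
  if (!is.null(x$step3)) {
    alt <- x$step3[x$step3$significance_altered, c("feature", "mediator")]
    cat("Significance altered in Step 3 for",
        nrow(alt), "feature-mediator pairs\n")
  }
  invisible(x)
}

#' Write a mediation report as JSON
#'
#' @param report a `mediation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mediation_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Birth-weight association models by cohort
#'
#' Within each cohort separately,
#' `birth_weight_g ~ feature + ga_at_mri_weeks + high_distress +
#' ga_at_birth_weeks` by GEE with subject clustering. A cohort with fewer
#' than 10 usable subjects is skipped with a warning. Rows without birth
#' weight are dropped (listwise) with the per-model N reported.
#'
#' @param data cohort table.
#' @param features feature columns.
#' @param corstr working correlation.
#' @return data.frame: cohort, feature, beta (g per feature unit), se, CI,
#'   p, q (BH within feature set and cohort), n.
#' @export
birthweight_models <- function(data, features = feature_names(),
                               corstr = "unstructured") {
  if (!"high_distress" %in% names(data))
    data <- derive_high_distress(data)
  rows <- list()
  for (g in 0:1) {
    dg <- data[data$cohort == g & !is.na(data$birth_weight_g), , drop = FALSE]
    if (length(unique(dg$subject_id)) < 10L) {
      warning("birthweight_models: cohort ", g,
              " has fewer than 10 usable subjects; skipped")
      next
    }
    covs <- c("ga_at_mri_weeks", "high_distress", "ga_at_birth_weeks")
    const <- covs[vapply(covs, function(v)
      length(unique(stats::na.omit(dg[[v]]))) < 2L, logical(1))]
    if (length(const)) {
      warning("birthweight_models: cohort ", g, ": covariate(s) ",
              paste(const, collapse = ", "),
              " constant; dropped from the model")
      covs <- setdiff(covs, const)
    }
    for (f in features) {
      row <- tryCatch({
        fit <- gee_fit(stats::reformulate(
          c(f, covs), response = "birth_weight_g"), dg, id = "subject_id",
          corstr = corstr)
        cbind(data.frame(cohort = g, feature = f, set = feature_set_of(f)),
              tidy_gee_row(fit, f))
      }, error = function(e) {
        warning("birthweight_models: ", f, " cohort ", g, " failed: ",
                conditionMessage(e))
        data.frame(cohort = g, feature = f, set = feature_set_of(f),
                   beta = NA, se = NA, ci_lower = NA, ci_upper = NA, p = NA,
                   n_scans = NA, n_subjects = NA)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (g in unique(out$cohort)) for (s in unique(out$set)) {
    i <- out$cohort == g & out$set == s
    out$q[i] <- bh_fdr(out$p[i])
  }
  rownames(out) <- NULL
  out
}

#' Sensitivity analysis with additional covariates
#'
#' Re-fits the distress-adjusted cohort comparison with each extra
#' covariate added, and reports whether any pandemic-effect conclusion
#' (q < alpha within the feature set) changes.
#'
#' @param data cohort table.
#' @param features feature columns.
#' @param extra_covariates covariate columns to add, one at a time.
#' @param alpha conclusion threshold on q.
#' @param corstr working correlation.
#' @return data.frame: covariate, feature, set, beta/se/p/q of the
#'   augmented model, base beta/q, and `conclusion_changed`.
#' @export
sensitivity_analysis <- function(data, features = feature_names(),
                                 extra_covariates = c("fetal_sex",
                                                      "maternal_weight_kg"),
                                 alpha = 0.05, corstr = "unstructured") {
  if (!"high_distress" %in% names(data))
    data <- derive_high_distress(data)
  base <- cohort_comparison(data, features, corstr = corstr)
  base <- base[base$model == "distress_adjusted", ]
  rows <- list()
  for (cv in extra_covariates) {
    for (f in features) {
      fit <- gee_fit(stats::reformulate(
        c("cohort", "ga_at_mri_weeks", "high_distress", cv), response = f),
        data, id = "subject_id", corstr = corstr)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(covariate = cv, feature = f,
                         set = feature_set_of(f)),
              tidy_gee_row(fit, "cohort"))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (cv in extra_covariates) for (s in unique(out$set)) {
    i <- out$covariate == cv & out$set == s
    out$q[i] <- bh_fdr(out$p[i])
  }
  out$beta_base <- base$beta[match(out$feature, base$feature)]
  out$q_base <- base$q[match(out$feature, base$feature)]
  out$conclusion_changed <- (out$q < alpha) != (out$q_base < alpha)
  rownames(out) <- NULL
  out
}

quad_spline_basis <- function(t, knots) {
  B <- cbind(t = t, t2 = t^2)
  for (k in seq_along(knots)) {
    h <- pmax(0, t - knots[k])^2
    B <- cbind(B, h)
    colnames(B)[ncol(B)] <- paste0("k", k)
  }
  B
}

#' Time trends of placental features
#'
#' Per cohort: GEE `feature ~ days + ga_at_mri_weeks` with `days` the scan
#' date as days since the earliest scan in the table (a cohort with fewer
#' than 3 distinct dates is skipped with a warning). Combined model: a
#' quadratic spline in date — continuous with continuous first derivative,
#' one interior knot at the pandemic declaration date by default — with a
#' subject-level random intercept, fitted by (RE)ML via lme4, adjusting for
#' gestational age. The net fitted change over the study period summarizes
#' the spline's direction.
#'
#' @param data cohort table with `scan_date`.
#' @param features feature columns.
#' @param knot_dates interior knot date(s) for the spline.
#' @param corstr working correlation for the per-cohort GEEs.
#' @return list: `per_cohort` (data.frame cohort/feature/slope per day/se/
#'   p/n), `spline` (data.frame feature/coefficients/p for the spline
#'   terms/`net_change` fitted end-minus-start).
#' @export
time_trend <- function(data, features = feature_names(),
                       knot_dates = as.Date("2020-03-11"),
                       corstr = "unstructured") {
  if (!inherits(data$scan_date, "Date"))
    data$scan_date <- as.Date(data$scan_date)
  t0 <- min(data$scan_date)
  data$days <- as.numeric(data$scan_date - t0)
  per <- list()
  for (g in 0:1) {
    dg <- data[data$cohort == g, , drop = FALSE]
    if (length(unique(dg$days)) < 3L) {
      warning("time_trend: cohort ", g,
              " has fewer than 3 distinct dates; skipped")
      next
    }
    for (f in features) {
      fit <- gee_fit(stats::reformulate(c("days", "ga_at_mri_weeks"),
                                        response = f),
                     dg, id = "subject_id", corstr = corstr)
      per[[length(per) + 1L]] <-
        cbind(data.frame(cohort = g, feature = f),
              tidy_gee_row(fit, "days"))
    }
  }
  per <- if (length(per)) do.call(rbind, per) else NULL

  kn <- as.numeric(as.Date(knot_dates) - t0)
  B <- quad_spline_basis(data$days / 365.25, kn / 365.25)
  sp <- list()
  for (f in features) {
    df <- data.frame(y = data[[f]], B, ga = data$ga_at_mri_weeks,
                     subject_id = data$subject_id)
    terms <- colnames(B)
    fml <- stats::reformulate(c(terms, "ga", "(1 | subject_id)"),
                              response = "y")
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    z <- cf / se
    pv <- 2 * stats::pnorm(-abs(z))
    tr <- range(data$days / 365.25)
    pred <- function(tt) {
      bb <- quad_spline_basis(tt, kn / 365.25)
      cf[["(Intercept)"]] + sum(cf[terms] * bb[1, terms]) +
        cf[["ga"]] * mean(data$ga_at_mri_weeks)
    }
    sp[[length(sp) + 1L]] <- data.frame(
      feature = f, term = terms, estimate = unname(cf[terms]),
      se = unname(se[terms]), p = unname(pv[terms]),
      net_change = pred(tr[2]) - pred(tr[1]))
  }
  list(per_cohort = per, spline = do.call(rbind, sp))
}
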
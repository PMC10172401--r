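test_that("BH q-values match hand cases and the brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:200) {
    p <- stats::runif(sample(1:12, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
  # NAs pass through without affecting m
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_fdr(p), c(0.02, NA, 0.04))
})

test_that("cohort comparison produces per-set q-values and LS means", {
  tab <- small_cohort(seed = 42, n = 150)
  cmp <- cohort_comparison(tab)
  expect_equal(nrow(cmp), 23 * 2)
  expect_setequal(unique(cmp$model), c("base", "distress_adjusted"))
  expect_true(all(cmp$q >= cmp$p - 1e-12, na.rm = TRUE))
  # LS-mean difference equals beta on every row
  expect_equal(cmp$ls_mean_pandemic - cmp$ls_mean_pre, cmp$beta,
               tolerance = 1e-8)
  # identical p-values get different q under different set sizes
  tab$fake_rlm <- tab$volume_cm3
  fs <- feature_sets()
  cmp2 <- cohort_comparison(tab, features = c(fs$shape, "fake_rlm"))
  # fake feature has no set; give it one by comparing shape q vs raw p
  sub <- cmp2[cmp2$model == "base", ]
  expect_equal(sub$p[sub$feature == "fake_rlm"],
               sub$p[sub$feature == "volume_cm3"], tolerance = 1e-10)
})

test_that("failed per-feature fits do not abort the batch", {
  tab <- small_cohort(seed = 43, n = 60)
  tab$ga_at_mri_weeks <- 30  # constant covariate: singular design per fit
  w <- capture_warnings(
    cmp <- cohort_comparison(tab, features = c("volume_cm3",
                                               "thickness_cm")))
  expect_true(any(grepl("failed", w)))
  expect_equal(nrow(cmp), 4)
  expect_true(all(is.na(cmp$beta)))
})

test_that("mediation report separates routed and direct effects", {
  full <- generate_cohort(synth_config(n_subjects = 400,
                                       pandemic_fraction = 0.5,
                                       mediation_mode = "full", seed = 44))
  mf <- mediation(full, features = "volume_cm3")
  expect_true(all(c("pss", "epds") %in%
                    mf$step2$measure[mf$step2$p < 0.05]))
  s3 <- mf$step3
  expect_true(s3$significance_altered[s3$mediator == "pss"])
  direct <- generate_cohort(synth_config(n_subjects = 400,
                                         pandemic_fraction = 0.5,
                                         mediation_mode = "direct",
                                         seed = 44))
  md <- mediation(direct, features = "volume_cm3")
  expect_false(any(md$step3$significance_altered))
  # null generator: no significant step-2 measure, step 3 skipped
  null <- generate_cohort(synth_config(n_subjects = 200,
                                       pandemic_fraction = 0.5,
                                       mediation_mode = "none", seed = 45))
  mn <- mediation(null, features = "volume_cm3")
  expect_null(mn$step3)
  expect_match(mn$note, "skipped")
  # report serializes to JSON
  td <- withr::local_tempdir()
  jp <- write_mediation_json(mf, file.path(td, "med.json"))
  expect_true(file.exists(jp))
  parsed <- jsonlite::read_json(jp)
  expect_equal(parsed$alpha, 0.05)
})

test_that("birth-weight models recover the generator's cohort slopes", {
  tab <- generate_cohort(synth_config(n_subjects = 400,
                                      pandemic_fraction = 0.5,
                                      two_scan_fraction = 0, seed = 46))
  bw <- suppressWarnings(
    birthweight_models(tab, features = c("volume_cm3", "elongation_cm")))
  s_true <- c(`0.volume_cm3` = 0.73, `1.volume_cm3` = 2.30,
              `0.elongation_cm` = 41.9, `1.elongation_cm` = 77.7)
  for (i in seq_len(nrow(bw))) {
    key <- paste0(bw$cohort[i], ".", bw$feature[i])
    expect_lt(abs(bw$beta[i] - s_true[key]), 2 * bw$se[i])
  }
  # a constant feature column raises a singular-design failure per feature
  tab$flat <- 5
  w <- capture_warnings(bwf <- birthweight_models(tab, features = "flat"))
  expect_true(any(grepl("failed|collinear", w)))
  expect_true(all(is.na(bwf$beta)))
  # cohorts with too few usable subjects are skipped
  tiny <- tab[tab$cohort == 0 | tab$subject_id %in%
                utils::head(unique(tab$subject_id[tab$cohort == 1]), 4), ]
  w2 <- capture_warnings(birthweight_models(tiny, features = "volume_cm3"))
  expect_true(any(grepl("fewer than 10", w2)))
})

test_that("sensitivity covariates leave the pandemic effect stable", {
  tab <- small_cohort(seed = 47, n = 250)
  sens <- sensitivity_analysis(tab, features = c("volume_cm3",
                                                 "thickness_cm",
                                                 "elongation_cm"))
  expect_setequal(unique(sens$covariate),
                  c("fetal_sex", "maternal_weight_kg"))
  # the generator ties neither covariate to features or cohort: betas move
  # by less than an SE and conclusions are unchanged
  expect_true(all(abs(sens$beta - sens$beta_base) < sens$se))
  expect_false(any(sens$conclusion_changed))
  # collinear covariate surfaces as an error
  tab$clone <- tab$cohort
  expect_error(sensitivity_analysis(tab, features = "volume_cm3",
                                    extra_covariates = "clone"),
               "collinear|singular")
})

test_that("time-trend models recover injected pre-pandemic drift", {
  cfg <- synth_config(n_subjects = 350, pandemic_fraction = 0.4, seed = 48,
                      mediation_mode = "none",
                      time_drift = list(volume_cm3 = c(120, 0)))
  tab <- generate_cohort(cfg)
  tt <- time_trend(tab, features = "volume_cm3")
  pre <- tt$per_cohort[tt$per_cohort$cohort == 0, ]
  pand <- tt$per_cohort[tt$per_cohort$cohort == 1, ]
  expect_lt(abs(pre$beta - 120 / 365.25), 2 * pre$se)
  expect_gt(pre$beta / pre$se, 2)           # drift detected
  expect_lt(abs(pand$beta) / pand$se, 2.5)  # no drift in the pandemic era
  # a cohort without enough distinct dates is skipped
  one_day <- tab
  one_day$scan_date[one_day$cohort == 1] <- as.Date("2020-07-01")
  expect_warning(time_trend(one_day, features = "volume_cm3"),
                 "distinct dates")
})

test_that("spline time trend follows the sign of a step change at the knot", {
  for (f in c("volume_cm3", "elongation_cm")) {
    tab <- generate_cohort(synth_config(n_subjects = 400,
                                        pandemic_fraction = 0.5,
                                        seed = 49))
    tt <- time_trend(tab, features = f)
    expect_equal(sign(tt$spline$net_change[1]),
                 sign(unname(default_effect_table()[f])))
  }
})
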
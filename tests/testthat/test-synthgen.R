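test_that("config invariants are enforced", {
  expect_error(synth_config(pandemic_fraction = 1.2), "fractions")
  expect_error(synth_config(ga_range_weeks = c(6, 39)), "ga_range")
  expect_error(synth_config(voxel_spacing_mm = c(1, -1, 4)), "spacing")
  dp <- default_distress_params(); dp$sd[1] <- 0
  expect_error(synth_config(distress_params = dp), "sd")
  expect_error(generate_cohort(synth_config(n_subjects = 3,
                                            pandemic_fraction = 0.25)),
               ">= 2 subjects")
})

test_that("cohort generation is deterministic and respects the design", {
  cfg <- synth_config(n_subjects = 60, seed = 17)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1, t2)

  # no pandemic subjects when the fraction is zero
  t0 <- generate_cohort(synth_config(n_subjects = 30,
                                     pandemic_fraction = 0, seed = 2))
  expect_true(all(t0$cohort == 0))
  expect_true(all(t0$scan_date < as.Date("2020-03-11")))

  # two-scan subjects: shared id, strictly increasing GA, never mixing
  # cohorts, dates consistent with the cohort windows
  two <- t1[t1$subject_id %in% t1$subject_id[duplicated(t1$subject_id)], ]
  sp <- split(two, two$subject_id)
  expect_true(all(vapply(sp, function(s) diff(s$ga_at_mri_weeks) > 0,
                         logical(1))))
  expect_true(all(vapply(sp, function(s) length(unique(s$cohort)) == 1,
                         logical(1))))
  pand <- t1[t1$cohort == 1, ]
  expect_true(all(pand$scan_date > as.Date("2020-03-11")))
  expect_true(all(t1$scan_date[t1$cohort == 0] < as.Date("2020-03-01") +
                    2192))
  # scores within instrument ranges
  expect_equal(nrow(validate_scores(t1)$rejects), 0)
})

test_that("distress shift matches the configured cohort contrast", {
  tab <- generate_cohort(synth_config(n_subjects = 200,
                                      pandemic_fraction = 0.5, seed = 1))
  d <- mean(tab$pss[tab$cohort == 1]) - mean(tab$pss[tab$cohort == 0])
  expect_lt(abs(d - 3.23), 0.6)  # Monte-Carlo tolerance at n = 200
})

test_that("injected feature effects converge with sample size", {
  cfg <- synth_config(n_subjects = 1500, pandemic_fraction = 0.5, seed = 9)
  tab <- generate_cohort(cfg)
  for (f in c("volume_cm3", "thickness_cm")) {
    tgt <- default_effect_table()[f]
    # compare GA-adjusted cohort difference to the injected shift
    fit <- stats::lm(stats::reformulate(c("cohort", "ga_at_mri_weeks"),
                                        response = f), tab)
    expect_lt(abs(coef(fit)["cohort"] - tgt), 4 * summary(fit)$coef[2, 2])
  }
})

test_that("phantoms carry analytic ground truth and connected masks", {
  set.seed(3)
  ph <- placenta_phantom(c(50, 40, 20), spacing_mm = c(1, 1, 1),
                         bend_frac = 0)
  expect_equal(unname(ph$true_features["volume_cm3"]),
               4 / 3 * pi * 5 * 4 * 2, tolerance = 1e-9)
  expect_equal(unname(ph$true_features["thickness_cm"]), 4)
  expect_equal(unname(ph$true_features["elongation_cm"]), 10)
  # gamma = 0 and near-white noise: histogram is symmetric within error
  set.seed(4)
  ph0 <- placenta_phantom(c(16, 12, 8), corr_length_mm = 0, gamma = 0)
  v <- ph0$image$data[ph0$mask$data == 1]
  m2 <- mean((v - mean(v))^2)
  skew <- mean((v - mean(v))^3) / m2^1.5
  expect_lt(abs(skew), 0.15)
  # positive gamma skews right
  set.seed(4)
  phg <- placenta_phantom(c(16, 12, 8), corr_length_mm = 2, gamma = 1.2)
  vg <- phg$image$data[phg$mask$data == 1]
  sg <- mean((vg - mean(vg))^3) / mean((vg - mean(vg))^2)^1.5
  expect_gt(sg, 0.3)
  # masks: single 6-connected component, finite gray levels
  for (seed in 1:5) {
    set.seed(seed)
    p <- placenta_phantom(c(14, 10, 6), spacing_mm = c(1.64, 1.64, 4))
    lab <- placentex:::mask_components(p$mask$data)
    expect_equal(max(lab), 1)
    expect_true(all(is.finite(p$image$data)))
  }
})

test_that("phantom geometry responds to gestational age and cohort", {
  cfg <- synth_config(seed = 1, size_scale = 0.4,
                      voxel_spacing_mm = c(2, 2, 2))
  set.seed(10)
  ph_young <- generate_placenta_image(22, 0, cfg)
  set.seed(10)
  ph_old <- generate_placenta_image(37, 0, cfg)
  expect_gt(ph_old$true_features["volume_cm3"],
            ph_young$true_features["volume_cm3"])
  set.seed(10)
  ph_pand <- generate_placenta_image(30, 1, cfg)
  set.seed(10)
  ph_pre <- generate_placenta_image(30, 0, cfg)
  expect_equal(unname(ph_pand$true_features["volume_cm3"] -
                        ph_pre$true_features["volume_cm3"]),
               unname(default_effect_table()["volume_cm3"] * 0.4^3),
               tolerance = 0.02)
  expect_error(generate_placenta_image(10, 0, cfg), "outside")
})

test_that("measured volume ranks agree with ground truth across a batch", {
  cfg <- synth_config(seed = 6, size_scale = 0.35,
                      voxel_spacing_mm = c(2, 2, 2))
  set.seed(60)
  ga <- stats::runif(50, 18, 38)
  true_v <- meas_v <- numeric(50)
  for (i in 1:50) {
    ph <- generate_placenta_image(ga[i], i %% 2, cfg)
    true_v[i] <- ph$true_features["volume_cm3"]
    meas_v[i] <- mesh_volume(mask_to_mesh(ph$mask))
  }
  expect_gte(stats::cor(true_v, meas_v, method = "spearman"), 0.99)
})
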
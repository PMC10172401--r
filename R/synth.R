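#' Default cohort shifts for every placental feature
#'
#' The additive pandemic effect injected on each feature, in feature units.
#' Defaults are the distress-adjusted cohort contrasts reported for the
#' clinical cohort (e.g. +44.32 cm^3 volume, +0.38 cm thickness, -0.58 cm
#' elongation), so that the generator's ground truth reproduces the
#' published effect pattern.
#'
#' @return named numeric vector over [feature_names()].
#' @export
default_effect_table <- function() {
  c(volume_cm3 = 44.32, thickness_cm = 0.38, elongation_cm = -0.58,
    mean_gl = -0.80, variance_gl = -0.03, kurtosis_gl = 0.09,
    skewness_gl = 0.04,
    energy = -1.66e-3, entropy = 0.11, idm = -0.01, contrast = -3.69,
    cluster_shade = -350, cluster_prominence = -276e3,
    sre = 0.01, lre = -0.59, glnu = -26, rlnu = 3680,
    lglre = -1.26e-3, hglre = -495, srlgle = -0.96e-3, srhgle = -490,
    lrlgle = -0.02, lrhgle = -522)
}

# pre-pandemic feature level at the reference gestational age (29.4 w) and
# its reported adjusted-mean SE, used to set generator noise scales.
feature_baselines <- function() {
  data.frame(
    feature = feature_names(),
    base = c(599.1, 4.9, 17.8,
             4.72, 0.70, 0.14, 0.12,
             5.28e-3, 8.43, 0.31, 39.18, 5690, 1149e3,
             0.88, 4.36, 1727, 38590, 2.98e-3, 2079, 2.40e-3, 1942,
             0.04, 5176),
    se = c(43.3, 0.2, 0.6,
           0.57, 0.08, 0.03, 0.04,
           1.80e-3, 0.29, 0.03, 14.64, 3710, 497e3,
           0.02, 0.80, 310, 3260, 1.40e-3, 626, 1.06e-3, 605,
           0.04, 1038))
}

#' Default per-questionnaire distress parameters
#'
#' Pre-pandemic means are the published adjusted group means (SSAI 29.5,
#' STAI 31.0, PSS 10.9, EPDS 4.4); the pandemic mean is the pre-pandemic
#' mean plus the published cohort contrast (+1.15, +1.76, +3.23, +1.54),
#' which reproduces the printed pandemic means up to rounding. The SD
#' column reuses the printed pre-pandemic dispersion.
#'
#' @return data.frame: measure, mean_pre, mean_pandemic, sd.
#' @export
default_distress_params <- function() {
  data.frame(measure = c("ssai", "stai", "pss", "epds"),
             mean_pre = c(29.5, 31.0, 10.9, 4.4),
             mean_pandemic = c(29.5 + 1.15, 31.0 + 1.76, 10.9 + 3.23,
                               4.4 + 1.54),
             sd = c(2.3, 1.8, 1.3, 0.9))
}

#' Configuration of the synthetic cohort / image generator
#'
#' Defaults mirror the clinical study design: 228 subjects of whom 63
#' (27.6%) are pandemic-era, 56% scanned twice, gestational ages 17-39
#' weeks, 1.64 x 1.64 x 4 mm voxels.
#'
#' @param n_subjects number of subjects.
#' @param pandemic_fraction proportion of subjects in the pandemic cohort.
#' @param two_scan_fraction proportion of subjects scanned twice.
#' @param ga_range_weeks gestational-age range (min, max), inside (8, 42).
#' @param voxel_spacing_mm voxel spacing (dx, dy, dz) in mm.
#' @param gray_levels quantization levels used downstream.
#' @param effect_table named additive pandemic shift per feature (feature
#'   units); see [default_effect_table()]. Missing names mean no shift.
#' @param distress_params data.frame as [default_distress_params()].
#' @param texture_params list: `corr_length_mm` (Gaussian-field correlation
#'   length), `gamma` (monotone intensity-transform skew parameter; 0 keeps
#'   the field symmetric).
#' @param mediation_mode `"direct"` (features shift with cohort directly;
#'   distress also shifts), `"full"` (the entire feature shift is routed
#'   through the PSS score: pandemic -> distress -> feature, no direct
#'   path), or `"none"` (null generator: no feature shift, no distress
#'   shift).
#' @param time_drift named list feature -> c(pre, pandemic) linear drift in
#'   feature units per year of scan date (default: none).
#' @param size_scale global linear scale on phantom geometry (1 = clinical
#'   size; smaller values give small fast test images).
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the config.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 228L,
                         pandemic_fraction = 63 / 228,
                         two_scan_fraction = 128 / 228,
                         ga_range_weeks = c(17, 39),
                         voxel_spacing_mm = c(1.64, 1.64, 4),
                         gray_levels = 32L,
                         effect_table = default_effect_table(),
                         distress_params = default_distress_params(),
                         texture_params = list(corr_length_mm = 3,
                                               gamma = 0.5),
                         mediation_mode = c("direct", "full", "none"),
                         time_drift = list(),
                         size_scale = 1,
                         seed = 1L) {
  mediation_mode <- match.arg(mediation_mode)
  if (pandemic_fraction < 0 || pandemic_fraction > 1 ||
      two_scan_fraction < 0 || two_scan_fraction > 1)
    stop("synth_config: fractions must lie in [0, 1]")
  if (length(ga_range_weeks) != 2L || ga_range_weeks[1] <= 8 ||
      ga_range_weeks[2] >= 42 || diff(ga_range_weeks) <= 0)
    stop("synth_config: ga_range_weeks must be increasing inside (8, 42)")
  if (any(voxel_spacing_mm <= 0))
    stop("synth_config: voxel spacing must be strictly positive")
  if (any(distress_params$sd <= 0))
    stop("synth_config: distress sd must be > 0")
  if (size_scale <= 0) stop("synth_config: size_scale must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 pandemic_fraction = pandemic_fraction,
                 two_scan_fraction = two_scan_fraction,
                 ga_range_weeks = as.numeric(ga_range_weeks),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 gray_levels = as.integer(gray_levels),
                 effect_table = effect_table,
                 distress_params = distress_params,
                 texture_params = texture_params,
                 mediation_mode = mediation_mode,
                 time_drift = time_drift,
                 size_scale = size_scale,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# truncated-normal sampling by rejection; truncation slightly shrinks the
# realized group difference relative to the nominal means.
rtruncnorm_rej <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), if (length(mean) > 1) mean[bad] else
      mean, sd)
  }
  pmin(hi, pmax(lo, x))
}

ga_trend_slopes <- function() {
  bl <- feature_baselines()
  sl <- 0.1 * bl$se
  names(sl) <- bl$feature
  sl["volume_cm3"] <- 30; sl["thickness_cm"] <- 0.08
  sl["elongation_cm"] <- 0.3
  sl
}

recruitment_windows <- function() {
  list(pre = as.Date(c("2014-03-01", "2020-02-29")),
       pandemic = as.Date(c("2020-06-01", "2021-04-30")))
}

#' Generate a synthetic longitudinal cohort table
#'
#' One row per scan. Subjects are assigned to the pre-pandemic or pandemic
#' cohort (never mixing cohorts across their scans); two-scan subjects get
#' strictly increasing gestational ages with scan dates spaced accordingly
#' inside the cohort's recruitment window. Distress scores are drawn from
#' cohort-specific normals (subject random effect + scan noise) truncated
#' to each instrument's range. Feature columns carry the generator's ground
#' truth for all 23 features: a gestational-age trend plus subject and scan
#' noise, shifted by the pandemic effect (directly, or routed through the
#' PSS score in full-mediation mode). Birth weight is a linear function of
#' the subject-level latent volume and elongation with cohort-specific
#' slopes, plus gestational-age-at-birth effect and noise.
#'
#' @param config a `synth_config`.
#' @return data.frame with identifier/covariate/distress columns and the 23
#'   feature columns of [feature_names()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  n_pand <- round(config$pandemic_fraction * n)
  n_pre <- n - n_pand
  if ((n_pand < 2L && config$pandemic_fraction > 0) ||
      (n_pre < 2L && config$pandemic_fraction < 1))
    stop("generate_cohort: need >= 2 subjects per cohort for the models")
  cohort_subj <- c(rep(0L, n_pre), rep(1L, n_pand))
  two <- rep(FALSE, n)
  for (g in 0:1) {
    idx <- which(cohort_subj == g)
    if (length(idx))
      two[idx[seq_len(round(config$two_scan_fraction * length(idx)))]] <- TRUE
  }
  ga_lo <- config$ga_range_weeks[1]; ga_hi <- config$ga_range_weeks[2]
  ga1 <- ifelse(two, stats::runif(n, ga_lo, ga_hi - 6),
                stats::runif(n, ga_lo, ga_hi))
  gap <- stats::runif(n, 5, 12)
  ga2 <- pmin(ga_hi, ga1 + gap)

  win <- recruitment_windows()
  date1 <- as.Date(rep(NA, n))
  for (g in 0:1) {
    w <- if (g == 0) win$pre else win$pandemic
    idx <- which(cohort_subj == g)
    span <- as.numeric(w[2] - w[1])
    avail <- pmax(1, span - ifelse(two[idx], (ga2 - ga1)[idx] * 7, 0))
    date1[idx] <- w[1] + floor(stats::runif(length(idx)) * avail)
  }
  date2 <- date1 + round((ga2 - ga1) * 7)

  # subject covariates
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  mwt <- round(stats::rlnorm(n, log(73), 0.15), 1)
  parity <- stats::rbinom(n, 1L, 0.45)
  ga_birth <- rtruncnorm_rej(n, 39.6, 1.2, 31, 41.9)

  # distress: subject latent + per-scan noise, truncated to range
  dp <- config$distress_params
  ins <- distress_instruments()
  shift_distress <- config$mediation_mode != "none"
  subj_scores <- list()
  for (k in seq_len(nrow(dp))) {
    m <- dp$measure[k]
    mu <- ifelse(cohort_subj == 1L & shift_distress,
                 dp$mean_pandemic[k], dp$mean_pre[k])
    subj_scores[[m]] <- list(mu = mu,
                             b = stats::rnorm(n, 0, 0.8 * dp$sd[k]),
                             sd_scan = 0.6 * dp$sd[k])
  }

  # features: baseline + GA trend + subject/scan noise (+ effect)
  bl <- feature_baselines()
  slopes <- ga_trend_slopes()
  eff <- stats::setNames(numeric(nrow(bl)), bl$feature)
  if (config$mediation_mode != "none") {
    et <- config$effect_table
    eff[names(et)[names(et) %in% names(eff)]] <-
      et[names(et) %in% names(eff)]
  }
  sd_f <- stats::setNames(2 * bl$se, bl$feature)
  u_subj <- sapply(bl$feature, function(f) stats::rnorm(n, 0, 0.9 * sd_f[f]))

  # expand to scans
  sidx <- c(seq_len(n), which(two))
  tp <- c(rep(1L, n), rep(2L, sum(two)))
  o <- order(sidx, tp)
  sidx <- sidx[o]; tp <- tp[o]
  ns <- length(sidx)
  ga <- ifelse(tp == 1L, ga1[sidx], ga2[sidx])
  sdate <- as.Date(ifelse(tp == 1L, date1[sidx], date2[sidx]),
                   origin = "1970-01-01")
  cohort <- cohort_subj[sidx]

  tab <- data.frame(
    subject_id = sprintf("P%04d", sidx),
    scan_id = sprintf("P%04d_T%d", sidx, tp),
    timepoint = tp,
    scan_date = sdate,
    cohort = cohort,
    ga_at_mri_weeks = round(ga, 2),
    ga_at_birth_weeks = round(ga_birth[sidx], 2),
    fetal_sex = sex[sidx],
    maternal_weight_kg = mwt[sidx],
    parity = parity[sidx],
    stringsAsFactors = FALSE)

  for (k in seq_len(nrow(dp))) {
    m <- dp$measure[k]
    s <- subj_scores[[m]]
    raw <- s$mu[sidx] + s$b[sidx] + stats::rnorm(ns, 0, s$sd_scan)
    r <- ins[ins$instrument == m, ]
    tab[[m]] <- round(pmin(r$hi, pmax(r$lo, raw)))
  }

  # PSS routing for full mediation: feature shift proportional to the
  # subject's PSS elevation over the pre-pandemic mean
  pssk <- which(dp$measure == "pss")
  pss_gain <- (tab$pss - dp$mean_pre[pssk]) /
    (dp$mean_pandemic[pssk] - dp$mean_pre[pssk])

  drift_days <- numeric(ns)
  for (g in 0:1) {
    w <- if (g == 0) win$pre else win$pandemic
    i <- cohort == g
    drift_days[i] <- as.numeric(sdate[i] - w[1])
  }

  for (f in bl$feature) {
    base <- bl$base[bl$feature == f] + slopes[f] * (ga - 29.4)
    shift <- switch(config$mediation_mode,
                    direct = eff[f] * cohort,
                    full = eff[f] * pss_gain,
                    none = 0)
    dr <- config$time_drift[[f]]
    drift <- if (is.null(dr)) 0 else
      ifelse(cohort == 0L, dr[1], dr[2]) * drift_days / 365.25
    w_scan <- stats::rnorm(ns, 0, sqrt(1 - 0.81) * sd_f[f])
    tab[[f]] <- base + u_subj[sidx, f] + shift + drift + w_scan
  }

  # birth weight from the subject's last measured volume and elongation
  # (the near-term placenta predicts birth size), cohort-specific slopes
  # in g per cm^3 and g per mm
  s_vol <- c(0.73, 2.30); s_el <- c(4.19, 7.77)
  last_row <- vapply(seq_len(n), function(i) max(which(sidx == i)),
                     integer(1))
  bw_subj <- 3350 +
    s_vol[cohort_subj + 1L] * (tab$volume_cm3[last_row] - 599.1) +
    s_el[cohort_subj + 1L] * 10 * (tab$elongation_cm[last_row] - 17.8) +
    130 * (ga_birth - 39.6) + stats::rnorm(n, 0, 250)
  tab$birth_weight_g <- round(bw_subj[sidx])

  rownames(tab) <- NULL
  tab
}

# separable Gaussian smoothing of a 3-D array (sigma per axis, voxels)
smooth_gauss3d <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (is.na(s) || s < 0.05) next
    nk <- dim(a)[ax]
    d <- abs(outer(seq_len(nk), seq_len(nk), `-`))
    K <- exp(-0.5 * (d / s)^2)
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dm <- dim(ap)
    ap <- array(K %*% matrix(ap, nrow = dm[1]), dm)
    a <- aperm(ap, order(perm))
  }
  a
}

#' Deformed-ellipsoid placental phantom
#'
#' Builds a binary placenta-like mask — an ellipsoid with a gentle
#' volume-preserving bend along its major axis — and an interior texture
#' field: white Gaussian noise smoothed to correlation length
#' `corr_length_mm` and passed through the monotone transform
#' g(z) = (exp(gamma z) - 1) / gamma, which skews the histogram for
#' gamma != 0 while preserving ordering. Background voxels carry a dimmer
#' independent noise floor so whole-image statistics differ from the
#' masked region.
#'
#' @param semi_axes_mm ellipsoid semi-axes (a, b, c) in mm; c is the flat
#'   (thickness) axis.
#' @param spacing_mm voxel spacing in mm.
#' @param bend_frac bend amplitude as a fraction of the major semi-axis
#'   (default 0.1; 0 disables the bend).
#' @param corr_length_mm texture correlation length (0 = white noise).
#' @param gamma skew parameter of the intensity transform.
#' @param margin_vox background margin around the mask (voxels).
#' @return list: `image` (`volume_image`), `mask` (`seg_mask`),
#'   `true_features` (named 23-vector: analytic volume 4/3 pi abc, slab
#'   thickness 2c, centerline arc-length elongation; texture entries NA),
#'   `flat_axis` (index of the thickness axis).
#' @export
placenta_phantom <- function(semi_axes_mm, spacing_mm = c(1, 1, 1),
                             bend_frac = 0.1, corr_length_mm = 3,
                             gamma = 0.5, margin_vox = 2L) {
  a <- semi_axes_mm[1]; b <- semi_axes_mm[2]; cc <- semi_axes_mm[3]
  stopifnot(a > 0, b > 0, cc > 0, all(spacing_mm > 0))
  A <- bend_frac * a
  half <- c(a, b, cc + A)
  dims <- pmax(3L, as.integer(ceiling(2 * half / spacing_mm)) +
                 2L * as.integer(margin_vox) + 1L)
  ctr <- (dims + 1) / 2
  co <- arrayInd(seq_len(prod(dims)), dims)
  x <- (co[, 1] - ctr[1]) * spacing_mm[1]
  y <- (co[, 2] - ctr[2]) * spacing_mm[2]
  z <- (co[, 3] - ctr[3]) * spacing_mm[3]
  zoff <- if (A > 0) A * sin(pi * x / (2 * a)) else 0
  inside <- (x / a)^2 + (y / b)^2 + ((z - zoff) / cc)^2 <= 1
  m <- array(0L, dims)
  m[inside] <- 1L
  if (!sum(m)) m[ctr[1], ctr[2], ctr[3]] <- 1L

  field <- array(stats::rnorm(prod(dims)), dims)
  field <- smooth_gauss3d(field, corr_length_mm / spacing_mm)
  field <- (field - mean(field)) / stats::sd(field)
  g <- if (abs(gamma) > 1e-12) (exp(gamma * field) - 1) / gamma else field
  g <- (g - mean(g[inside])) / stats::sd(g[inside])
  img <- array(40 + 8 * stats::rnorm(prod(dims)), dims)
  img[inside] <- 100 + 20 * g[inside]

  arc <- if (A > 0) {
    f <- function(t) sqrt(1 + (A * pi / (2 * a) * cos(pi * t / (2 * a)))^2)
    stats::integrate(f, -a, a)$value
  } else 2 * a
  tf <- stats::setNames(rep(NA_real_, length(feature_names())),
                        feature_names())
  tf["volume_cm3"] <- 4 / 3 * pi * a * b * cc / 1000
  tf["thickness_cm"] <- 2 * cc / 10
  tf["elongation_cm"] <- arc / 10
  list(image = volume_image(img, spacing_mm),
       mask = seg_mask(m, spacing_mm),
       true_features = tf, flat_axis = 3L)
}

#' Generate one synthetic placental scan
#'
#' Converts gestational age and cohort into phantom geometry: target volume,
#' thickness and elongation follow the same growth curves and pandemic
#' shifts as [generate_cohort()], scaled by `config$size_scale`, and the
#' phantom semi-axes are solved from those targets (elongation = 2a,
#' thickness = 2c, volume = 4/3 pi abc).
#'
#' @param ga_weeks gestational age at the scan (inside the config range).
#' @param cohort 0 (pre-pandemic) or 1 (pandemic).
#' @param config a `synth_config`.
#' @return as [placenta_phantom()].
#' @export
generate_placenta_image <- function(ga_weeks, cohort, config) {
  stopifnot(inherits(config, "synth_config"))
  if (ga_weeks < config$ga_range_weeks[1] ||
      ga_weeks > config$ga_range_weeks[2])
    stop("generate_placenta_image: ga_weeks outside the configured range")
  eff <- config$effect_table
  e <- function(f) if (config$mediation_mode != "none" && f %in% names(eff))
    eff[[f]] else 0
  s <- config$size_scale
  vol <- max(40, 599.1 + 30 * (ga_weeks - 29.4) + e("volume_cm3") * cohort) *
    s^3
  thk <- max(1.2, 4.9 + 0.08 * (ga_weeks - 29.4) +
               e("thickness_cm") * cohort) * s
  elo <- max(4, 17.8 + 0.3 * (ga_weeks - 29.4) +
               e("elongation_cm") * cohort) * s
  a <- elo / 2 * 10
  cc <- thk / 2 * 10
  b <- 3 * (vol * 1000) / (4 * pi * a * cc)
  placenta_phantom(c(a, b, cc), config$voxel_spacing_mm,
                   bend_frac = 0.08,
                   corr_length_mm = config$texture_params$corr_length_mm,
                   gamma = config$texture_params$gamma)
}

#' Synthesize a full dataset on disk
#'
#' Generates the cohort table and one NIfTI image/mask pair per scan.
#'
#' @param config a `synth_config`.
#' @param out_dir output directory (created if needed).
#' @return list: `cohort` (data.frame; also written to cohort.csv),
#'   `manifest` (data.frame scan_id/image_path/mask_path, written to
#'   manifest.csv).
#' @export
synthesize_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  man <- data.frame(scan_id = cohort$scan_id,
                    image_path = file.path(img_dir,
                                           paste0(cohort$scan_id, ".nii.gz")),
                    mask_path = file.path(img_dir,
                                          paste0(cohort$scan_id,
                                                 "_mask.nii.gz")),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cohort))) {
    ph <- generate_placenta_image(cohort$ga_at_mri_weeks[i],
                                  cohort$cohort[i], config)
    write_nifti_volume(ph$image, man$image_path[i])
    write_nifti_volume(ph$mask, man$mask_path[i])
  }
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  list(cohort = cohort, manifest = man)
}
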
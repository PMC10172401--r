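#' Names of the 23 per-scan placental features
#'
#' Three shape features, four normalized histogram (first-set) features,
#' six co-occurrence (second-set) features and ten run-length (third-set)
#' features.
#'
#' @return character vector of length 23.
#' @export
feature_names <- function() {
  unlist(feature_sets(), use.names = FALSE)
}

#' Feature sets used for per-set FDR control
#'
#' @return named list of feature-name vectors: `shape` (3), `hist` (4),
#'   `glcm` (6), `rlm` (10).
#' @export
feature_sets <- function() {
  list(shape = c("volume_cm3", "thickness_cm", "elongation_cm"),
       hist = c("mean_gl", "variance_gl", "kurtosis_gl", "skewness_gl"),
       glcm = c("energy", "entropy", "idm", "contrast",
                "cluster_shade", "cluster_prominence"),
       rlm = c("sre", "lre", "glnu", "rlnu", "lglre", "hglre",
               "srlgle", "srhgle", "lrlgle", "lrhgle"))
}

#' Extract the full 23-feature vector from one scan
#'
#' Runs the shape pipeline (mesh volume, surface thickness, skeleton
#' elongation) on the mask and the texture pipeline (normalized histogram
#' statistics on raw intensities; co-occurrence and run-length features on
#' the mask-scoped quantized volume, averaged over lattice directions) on
#' the image.
#'
#' @param image a `volume_image`.
#' @param mask the paired `seg_mask`.
#' @param n_levels gray levels Ng for quantization (default 32).
#' @param direction_mode `"3d"` (13 lattice directions, default) or `"2d"`
#'   (4 in-plane directions per slice, for strongly anisotropic slices).
#' @param distance co-occurrence offset in voxels (default 1).
#' @param log_base entropy logarithm base (default 2).
#' @param quant_scope quantization scope, `"mask"` (default) or
#'   `"whole_image"`.
#' @param rim_fraction,resample_isotropic passed to the shape pipeline.
#' @return named numeric vector of the 23 features, with attribute
#'   `provenance` (list of the settings used).
#' @export
extract_features <- function(image, mask, n_levels = 32L,
                             direction_mode = c("3d", "2d"),
                             distance = 1L, log_base = 2,
                             quant_scope = c("mask", "whole_image"),
                             rim_fraction = 0.1,
                             resample_isotropic = FALSE) {
  direction_mode <- match.arg(direction_mode)
  quant_scope <- match.arg(quant_scope)
  if (isTRUE(attr(mask, "empty")))
    stop("extract_features: mask is empty")
  dirs <- if (direction_mode == "3d") lattice_directions_3d()
          else lattice_directions_2d()
  shp <- shape_features(mask, rim_fraction = rim_fraction,
                        resample_isotropic = resample_isotropic)
  hst <- histogram_features(image, mask)
  q <- quantize(image, mask, n_levels = n_levels, scope = quant_scope)
  glc <- glcm_features(glcm_accumulate(q, distance = distance,
                                       directions = dirs),
                       log_base = log_base)
  rlf <- rlm_features(rlm_accumulate_all(q, directions = dirs))
  out <- c(shp, hst, glc, rlf)[feature_names()]
  attr(out, "provenance") <- list(
    n_levels = as.integer(n_levels), direction_mode = direction_mode,
    distance = as.integer(distance), log_base = log_base,
    quant_scope = quant_scope, rim_fraction = rim_fraction,
    resample_isotropic = resample_isotropic,
    histogram_flags = attr(hst, "flags"))
  out
}

#' Extract features for a batch of scans listed in a manifest
#'
#' @param manifest data.frame with columns `scan_id`, `image_path`,
#'   `mask_path`.
#' @param out_csv optional path: write the tidy feature table (one row per
#'   scan, one column per feature) plus a JSON provenance sidecar
#'   (`<out_csv>.provenance.json`) recording Ng, direction mode, log base
#'   and quantization scope.
#' @param ... passed to [extract_features()].
#' @return data.frame: scan_id + 23 feature columns.
#' @export
extract_features_batch <- function(manifest, out_csv = NULL, ...) {
  need <- c("scan_id", "image_path", "mask_path")
  if (!all(need %in% names(manifest)))
    stop("extract_features_batch: manifest needs columns ",
         paste(need, collapse = ", "))
  rows <- vector("list", nrow(manifest))
  prov <- NULL
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$scan_id[i]
    if (!file.exists(manifest$mask_path[i]))
      stop("extract_features_batch: missing mask for scan ", sid, ": ",
           manifest$mask_path[i])
    if (!file.exists(manifest$image_path[i]))
      stop("extract_features_batch: missing image for scan ", sid, ": ",
           manifest$image_path[i])
    sc <- load_scan(manifest$image_path[i], manifest$mask_path[i])
    fv <- extract_features(sc$image, sc$mask, ...)
    prov <- attr(fv, "provenance")
    rows[[i]] <- data.frame(scan_id = sid, t(fv), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE)
    jsonlite::write_json(prov, paste0(out_csv, ".provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
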
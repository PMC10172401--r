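#' Construct a volume image
#'
#' A `volume_image` couples a 3-D scalar array with its physical voxel
#' spacing (mm) and an optional 4x4 voxel-to-world affine. Feature
#' computations run on the voxel lattice; the spacing only scales the
#' physical (shape) measurements, and the affine is carried as metadata.
#'
#' @param data 3-D numeric array of voxel intensities; must be finite.
#' @param spacing_mm numeric length-3, strictly positive voxel spacing in mm.
#' @param affine optional 4x4 voxel-to-world transform.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing_mm = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume_image: 'data' must be a 3-D array")
  if (!all(is.finite(data)))
    stop("volume_image: voxel data must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("volume_image: spacing must be 3 strictly positive values (mm)")
  if (!is.null(affine) && !identical(dim(affine), c(4L, 4L)))
    stop("volume_image: affine must be a 4x4 matrix")
  structure(list(data = data, spacing_mm = spacing_mm, affine = affine),
            class = "volume_image")
}

#' Construct a binary segmentation mask
#'
#' Any nonzero voxel is treated as foreground. An all-zero mask is legal at
#' construction (so files can be inspected) but is flagged `empty`; the
#' feature extractors refuse empty masks.
#'
#' @param data 3-D array; nonzero values mark the segmented region.
#' @param spacing_mm voxel spacing in mm, must match the paired image.
#' @return An object of class `seg_mask` with logical attribute `empty`.
#' @export
seg_mask <- function(data, spacing_mm = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("seg_mask: 'data' must be a 3-D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("seg_mask: spacing must be 3 strictly positive values (mm)")
  bin <- array(as.integer(data != 0), dim = dim(data))
  out <- structure(list(data = bin, spacing_mm = spacing_mm),
                   class = "seg_mask")
  attr(out, "empty") <- sum(bin) == 0L
  out
}

#' @export
print.volume_image <- function(x, ...) {
  cat("volume_image:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing_mm, 4), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat("seg_mask:", paste(dim(x$data), collapse = " x "),
      "voxels,", sum(x$data), "foreground, spacing",
      paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n")
  invisible(x)
}

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.numeric(pd[seq_len(3)])
}

#' Load an image/mask pair from NIfTI files
#'
#' Reads a gray-level volume and its placental segmentation, validates that
#' the two geometries agree (same array shape; spacings equal to within
#' 1e-3 mm), and binarizes the mask (any nonzero label becomes 1).
#'
#' @param image_path path to the anatomic volume (.nii or .nii.gz).
#' @param mask_path path to the segmentation (.nii or .nii.gz).
#' @return list with elements `image` (`volume_image`) and `mask`
#'   (`seg_mask`).
#' @export
load_scan <- function(image_path, mask_path) {
  if (!file.exists(image_path)) stop("load_scan: no such image: ", image_path)
  if (!file.exists(mask_path)) stop("load_scan: no such mask: ", mask_path)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img)[seq_len(3)]; dm <- dim(msk)[seq_len(3)]
  si <- nifti_spacing(img); sm <- nifti_spacing(msk)
  if (!identical(as.integer(di), as.integer(dm)))
    stop("load_scan: shape mismatch: image ",
         paste(di, collapse = "x"), " vs mask ", paste(dm, collapse = "x"))
  if (any(abs(si - sm) > 1e-3))
    stop("load_scan: spacing mismatch beyond 1e-3 mm: image (",
         paste(signif(si, 6), collapse = ", "), ") vs mask (",
         paste(signif(sm, 6), collapse = ", "), ")")
  image <- volume_image(array(as.numeric(img), dim = di), si,
                        affine = tryCatch(unclass(RNifti::xform(img)),
                                          error = function(e) NULL))
  mask <- seg_mask(array(as.numeric(msk), dim = dm), si)
  list(image = image, mask = mask)
}

#' Write an image or mask to a NIfTI file
#'
#' @param x a `volume_image` or `seg_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  stopifnot(inherits(x, "volume_image") || inherits(x, "seg_mask"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Quantize gray levels for co-occurrence / run-length analysis
#'
#' Equal-width binning between the minimum and maximum intensity of the
#' chosen scope. In-mask voxels receive integer levels 1..Ng; voxels outside
#' the mask are 0. The top bin edge is inclusive so the maximum maps to Ng.
#' A constant region cannot be split into bins: every in-mask voxel gets
#' level 1 and a warning is emitted.
#'
#' @param image a `volume_image`.
#' @param mask a `seg_mask` with matching geometry.
#' @param n_levels integer number of gray levels Ng (>= 2).
#' @param scope `"mask"` (default): bin edges span the masked intensities;
#'   `"whole_image"`: edges span all finite voxels of the image.
#' @return An object of class `quantized_volume`: list with `levels`
#'   (integer array, 0 outside mask), `n_levels`, `bin_edges`.
#' @export
quantize <- function(image, mask, n_levels = 32L,
                     scope = c("mask", "whole_image")) {
  scope <- match.arg(scope)
  stopifnot(inherits(image, "volume_image"), inherits(mask, "seg_mask"))
  if (!identical(dim(image$data), dim(mask$data)))
    stop("quantize: image and mask shapes differ")
  if (isTRUE(attr(mask, "empty")))
    stop("quantize: mask is empty")
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("quantize: n_levels must be >= 1")
  inmask <- mask$data != 0L
  ref <- if (scope == "mask") image$data[inmask] else image$data
  lo <- min(ref); hi <- max(ref)
  lev <- array(0L, dim = dim(image$data))
  if (hi - lo <= 0) {
    if (n_levels > 1L)
      warning("quantize: constant region; all voxels assigned level 1")
    lev[inmask] <- 1L
    edges <- c(lo, rep(hi, n_levels))
  } else {
    edges <- seq(lo, hi, length.out = n_levels + 1L)
    v <- image$data[inmask]
    k <- floor((v - lo) / (hi - lo) * n_levels) + 1L
    k[k > n_levels] <- n_levels   # top edge inclusive
    k[k < 1L] <- 1L               # out-of-scope values clamp into range
    lev[inmask] <- as.integer(k)
  }
  structure(list(levels = lev, n_levels = n_levels, bin_edges = edges,
                 scope = scope),
            class = "quantized_volume")
}
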
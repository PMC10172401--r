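#' The 13 unique 3-D lattice directions
#'
#' Offsets (dx, dy, dz) at Chebyshev distance 1, one representative per
#' antipodal pair (first nonzero component positive). Used for both
#' co-occurrence and run-length accumulation.
#'
#' @return integer matrix, 13 rows x 3 columns.
#' @export
lattice_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1L, function(d) d[which(d != 0)[1]] > 0)
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- apply(out, 1L, paste, collapse = ",")
  out
}

#' The 4 unique in-plane (per-slice) directions
#'
#' @return integer matrix, 4 rows x 3 columns, all with dz = 0.
#' @export
lattice_directions_2d <- function() {
  d <- lattice_directions_3d()
  d[d[, 3] == 0, , drop = FALSE]
}

# shifted copies of `a` such that pair (src, dst) sits at offset d;
# returns list(src=, dst=) of equal-length vectors (array values).
shift_pairs <- function(a, d) {
  dims <- dim(a)
  idx <- function(k) {
    lo <- max(1L, 1L - d[k]); hi <- min(dims[k], dims[k] - d[k])
    if (lo > hi) integer(0) else lo:hi
  }
  i1 <- idx(1); i2 <- idx(2); i3 <- idx(3)
  if (!length(i1) || !length(i2) || !length(i3))
    return(list(src = numeric(0), dst = numeric(0)))
  list(src = a[i1, i2, i3, drop = FALSE],
       dst = a[i1 + d[1], i2 + d[2], i3 + d[3], drop = FALSE])
}

#' Accumulate gray-level co-occurrence matrices
#'
#' Counts ordered pairs of in-mask voxels separated by `distance` voxels
#' along each direction. With `symmetric = TRUE` the transposed counts are
#' added, so each unordered pair contributes in both orders. Each
#' per-direction matrix is normalized to sum to 1; directions yielding no
#' valid pair are dropped with a warning. Per-direction matrices are kept
#' (not pooled) so features can be computed per direction and then averaged.
#'
#' @param q a `quantized_volume` (levels 0 outside the mask).
#' @param distance voxel offset magnitude along each direction (default 1).
#' @param directions integer matrix of direction rows; defaults to the 13
#'   unique 3-D lattice directions.
#' @param symmetric add transposed counts (default TRUE).
#' @return list of class `glcm_set`; each element has `P` (Ng x Ng,
#'   sums to 1), `counts`, `direction`, `distance`, `n_pairs`.
#' @export
glcm_accumulate <- function(q, distance = 1L,
                            directions = lattice_directions_3d(),
                            symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_volume"))
  ng <- q$n_levels
  lv <- q$levels
  out <- list()
  for (r in seq_len(nrow(directions))) {
    d <- as.integer(directions[r, ]) * as.integer(distance)
    sp <- shift_pairs(lv, d)
    ok <- sp$src > 0L & sp$dst > 0L
    src <- sp$src[ok]; dst <- sp$dst[ok]
    if (!length(src)) {
      warning("glcm_accumulate: no valid pairs along direction (",
              paste(directions[r, ], collapse = ","), "); excluded")
      next
    }
    cnt <- matrix(tabulate((dst - 1L) * ng + src, nbins = ng * ng),
                  nrow = ng, ncol = ng)
    if (symmetric) cnt <- cnt + t(cnt)
    out[[length(out) + 1L]] <- structure(
      list(P = cnt / sum(cnt), counts = cnt,
           direction = as.integer(directions[r, ]),
           distance = as.integer(distance), n_pairs = length(src)),
      class = "glcm")
  }
  if (!length(out)) stop("glcm_accumulate: no direction produced any pair")
  structure(out, class = "glcm_set")
}

glcm_features_one <- function(P, log_base = 2) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)        # row index
  j <- t(i)                               # column index
  nz <- P > 0
  energy <- sum(P^2)
  entropy <- -sum(P[nz] * log(P[nz], base = log_base))
  idm <- sum(P / (1 + (i - j)^2))
  contrast <- sum((i - j)^2 * P)
  mu_x <- sum(i * P); mu_y <- sum(j * P)
  dev <- i + j - mu_x - mu_y
  c(energy = energy, entropy = entropy, idm = idm, contrast = contrast,
    cluster_shade = sum(dev^3 * P), cluster_prominence = sum(dev^4 * P))
}

#' Co-occurrence features averaged over directions
#'
#' Per direction: energy = sum p^2; entropy = -sum p log p (0 log 0 := 0,
#' base 2 by default); inverse difference moment = sum p / (1 + (i-j)^2);
#' contrast = sum (i-j)^2 p; with mu_x = sum i p and mu_y = sum j p, cluster
#' shade and prominence are the 3rd and 4th moments of (i + j - mu_x - mu_y).
#' The reported value of each feature is the unweighted mean over the
#' retained directions (feature-then-average).
#'
#' @param glcms a `glcm_set` (or a single `glcm`).
#' @param log_base logarithm base for entropy (default 2, bits).
#' @return named numeric: energy, entropy, idm, contrast, cluster_shade,
#'   cluster_prominence.
#' @export
glcm_features <- function(glcms, log_base = 2) {
  if (inherits(glcms, "glcm")) glcms <- list(glcms)
  vals <- vapply(glcms, function(g) glcm_features_one(g$P, log_base),
                 numeric(6))
  rowMeans(vals)
}

# order all array voxels into maximal 1-D lines along direction d.
# Returns data.frame(line, t, level) sorted by (line, t); t consecutive
# within each line. Out-of-mask voxels carry level 0 and break runs.
line_decompose <- function(lv, d) {
  dims <- dim(lv)
  n <- prod(dims)
  co <- arrayInd(seq_len(n), dims)
  # steps backward until the line exits the array
  back <- rep(.Machine$integer.max, n)
  for (k in 1:3) {
    if (d[k] > 0L) back <- pmin(back, (co[, k] - 1L) %/% d[k])
    if (d[k] < 0L) back <- pmin(back, (dims[k] - co[, k]) %/% (-d[k]))
  }
  anchor <- co - back %o% as.integer(d)
  line <- (anchor[, 3] - 1L) * (dims[1] * dims[2]) +
    (anchor[, 2] - 1L) * dims[1] + anchor[, 1]
  ord <- order(line, back)
  list(line = line[ord], t = back[ord], level = as.integer(lv)[ord])
}

#' Accumulate a run-length matrix along one direction
#'
#' Decomposes the lattice into maximal 1-D lines along `direction`; a run is
#' a maximal streak of consecutive voxels on a line sharing the same gray
#' level and lying entirely inside the mask. Mask gaps terminate runs (no
#' bridging across non-placental voxels).
#'
#' @param q a `quantized_volume`.
#' @param direction integer length-3 lattice direction.
#' @return object of class `rlm`: `R` (Ng x Lmax run counts), `n_runs`,
#'   `n_voxels` (in-mask voxels counted; equals sum over R of j * R(i, j)),
#'   `direction`.
#' @export
rlm_accumulate <- function(q, direction) {
  stopifnot(inherits(q, "quantized_volume"))
  d <- as.integer(direction)
  if (length(d) != 3L || all(d == 0L))
    stop("rlm_accumulate: direction must be a nonzero length-3 offset")
  ng <- q$n_levels
  dec <- line_decompose(q$levels, d)
  # break runs on line change or level change (t is consecutive by design)
  m <- length(dec$level)
  if (m == 0L) stop("rlm_accumulate: empty volume")
  brk <- c(TRUE, dec$line[-1] != dec$line[-m] |
                 dec$level[-1] != dec$level[-m])
  grp <- cumsum(brk)
  run_len <- tabulate(grp)
  run_lev <- dec$level[brk]
  keep <- run_lev > 0L
  run_len <- run_len[keep]; run_lev <- run_lev[keep]
  lmax <- max(1L, if (length(run_len)) max(run_len) else 1L)
  R <- matrix(tabulate((run_len - 1L) * ng + run_lev, nbins = ng * lmax),
              nrow = ng, ncol = lmax)
  structure(list(R = R, n_runs = sum(R), n_voxels = sum(run_len),
                 direction = d),
            class = "rlm")
}

#' Run-length matrices along a set of directions
#'
#' @param q a `quantized_volume`.
#' @param directions integer matrix of direction rows (default: 13 unique
#'   3-D lattice directions).
#' @return list of class `rlm_set`.
#' @export
rlm_accumulate_all <- function(q, directions = lattice_directions_3d()) {
  out <- lapply(seq_len(nrow(directions)), function(r)
    rlm_accumulate(q, directions[r, ]))
  structure(out, class = "rlm_set")
}

rlm_features_one <- function(R) {
  nr <- sum(R)
  ng <- nrow(R); lm <- ncol(R)
  i <- matrix(seq_len(ng), ng, lm)   # gray level index
  j <- t(matrix(seq_len(lm), lm, ng))  # run length index
  gl_marg <- rowSums(R)   # sum over j
  rl_marg <- colSums(R)   # sum over i
  c(sre    = sum(R / j^2) / nr,
    lre    = sum(R * j^2) / nr,
    glnu   = sum(gl_marg^2) / nr,
    rlnu   = sum(rl_marg^2) / nr,
    lglre  = sum(R / i^2) / nr,
    hglre  = sum(R * i^2) / nr,
    srlgle = sum(R / (i^2 * j^2)) / nr,
    srhgle = sum(R * i^2 / j^2) / nr,
    lrlgle = sum(R * j^2 / i^2) / nr,
    lrhgle = sum(R * i^2 * j^2) / nr)
}

#' Run-length features averaged over directions
#'
#' The ten classical run-length statistics, computed per direction from the
#' run counts r(i, j) (level i, length j, Nr total runs) and averaged,
#' unweighted, over directions. Directions that produced no run are dropped
#' from the average.
#'
#' @param rlms an `rlm_set` (or single `rlm`).
#' @return named numeric: sre, lre, glnu, rlnu, lglre, hglre, srlgle,
#'   srhgle, lrlgle, lrhgle.
#' @export
rlm_features <- function(rlms) {
  if (inherits(rlms, "rlm")) rlms <- list(rlms)
  rlms <- Filter(function(r) r$n_runs >= 1, rlms)
  if (!length(rlms)) stop("rlm_features: no direction holds any run")
  vals <- vapply(rlms, function(r) rlm_features_one(r$R), numeric(10))
  rowMeans(vals)
}

moments4 <- function(v) {
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  c(mean = mu, variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_)
}

#' Normalized histogram features of the masked region
#'
#' First-set features: the mean, variance, skewness (standardized third
#' moment) and kurtosis (standardized fourth moment, not excess) of the raw
#' in-mask intensities, each divided by the same statistic computed over all
#' finite voxels of the whole image. Raw intensities are used (no
#' quantization) because the normalization is a ratio of intensity
#' statistics.
#'
#' Degenerate cases: a constant region has variance ratio 0 and undefined
#' skewness/kurtosis, reported as 0 and flagged; a whole-image denominator
#' within 1e-12 of 0 makes the ratio unstable, so the unnormalized region
#' statistic is returned and flagged.
#'
#' @param image a `volume_image`.
#' @param mask a `seg_mask` with at least 8 foreground voxels.
#' @return named numeric (mean_gl, variance_gl, kurtosis_gl, skewness_gl)
#'   with attribute `flags`: character vector naming any feature reported
#'   unnormalized or zeroed-degenerate.
#' @export
histogram_features <- function(image, mask) {
  stopifnot(inherits(image, "volume_image"), inherits(mask, "seg_mask"))
  inm <- mask$data != 0L
  if (sum(inm) < 8L)
    stop("histogram_features: need >= 8 masked voxels")
  whole <- image$data[is.finite(image$data)]
  if (length(unique(whole)) < 2L)
    stop("histogram_features: whole image is constant")
  reg <- moments4(image$data[inm])
  glob <- moments4(whole)
  flags <- character(0)
  ratio <- function(stat) {
    r <- reg[[stat]]; g <- glob[[stat]]
    if (is.na(r)) { flags <<- c(flags, paste0(stat, ":degenerate")); return(0) }
    if (is.na(g) || abs(g) < 1e-12) {
      flags <<- c(flags, paste0(stat, ":unnormalized")); return(r)
    }
    r / g
  }
  out <- c(mean_gl = ratio("mean"), variance_gl = ratio("variance"),
           kurtosis_gl = ratio("kurtosis"), skewness_gl = ratio("skewness"))
  attr(out, "flags") <- flags
  out
}
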
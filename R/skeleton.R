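# Nearest-neighbor resampling of a mask to isotropic spacing (the smallest
# of the three spacings). Strong slice anisotropy biases lattice thinning;
# this is the optional mitigation, off by default.
resample_mask_isotropic <- function(mask) {
  sp <- mask$spacing_mm
  iso <- min(sp)
  if (max(abs(sp - iso)) < 1e-9) return(mask)
  dims <- dim(mask$data)
  newdims <- pmax(1L, as.integer(round(dims * sp / iso)))
  src <- lapply(1:3, function(k)
    pmin(dims[k], pmax(1L, as.integer(ceiling((seq_len(newdims[k]) - 0.5) *
                                              iso / sp[k])))))
  seg_mask(mask$data[src[[1]], src[[2]], src[[3]], drop = FALSE],
           rep(iso, 3))
}

#' Curve skeleton of a binary mask
#'
#' Thinning-based 3-D skeletonization: border voxels are peeled in six
#' directional sub-iterations, deleting only topology-preserving (simple)
#' points and never curve endpoints, until a fixed point is reached.
#' Thinning runs on the voxel lattice; physical spacing enters only when
#' lengths are measured on the skeleton.
#'
#' @param mask a nonempty `seg_mask`.
#' @param resample_isotropic resample the mask to isotropic spacing before
#'   thinning (default FALSE: native-lattice processing).
#' @return a `seg_mask` holding the skeleton voxels.
#' @export
skeletonize <- function(mask, resample_isotropic = FALSE) {
  stopifnot(inherits(mask, "seg_mask"))
  if (isTRUE(attr(mask, "empty"))) stop("skeletonize: empty mask")
  if (resample_isotropic) mask <- resample_mask_isotropic(mask)
  sk <- .cpp_thin_skeleton(array(mask$data != 0L, dim(mask$data)),
                           dim(mask$data))
  seg_mask(array(as.integer(sk), dim(mask$data)), mask$spacing_mm)
}

#' Build the weighted graph of a voxel skeleton
#'
#' Nodes are skeleton voxel centers (physical mm coordinates); edges join
#' 26-adjacent skeleton voxels with weight equal to the physical distance
#' between their centers.
#'
#' @param skel a `seg_mask` holding skeleton voxels (see [skeletonize()]).
#' @return object of class `skeleton_graph`: `graph` (igraph, weighted),
#'   `coords_mm`, `endpoints` (node indices with degree <= 1), `junctions`
#'   (degree >= 3).
#' @export
skeleton_graph <- function(skel) {
  stopifnot(inherits(skel, "seg_mask"))
  dims <- dim(skel$data)
  fg <- which(skel$data != 0L)
  if (!length(fg)) stop("skeleton_graph: empty skeleton")
  pos <- arrayInd(fg, dims)
  lut <- integer(prod(dims))
  key <- (pos[, 3] - 1L) * (dims[1] * dims[2]) + (pos[, 2] - 1L) * dims[1] +
    pos[, 1]
  lut[key] <- seq_along(fg)
  dirs <- lattice_directions_3d()
  edges <- NULL; wts <- NULL
  sp <- skel$spacing_mm
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    nb <- sweep(pos, 2L, d, `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
      nb[, 2] >= 1L & nb[, 2] <= dims[2] &
      nb[, 3] >= 1L & nb[, 3] <= dims[3]
    nbkey <- (nb[ok, 3] - 1L) * (dims[1] * dims[2]) +
      (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    hit <- lut[nbkey] > 0L
    if (!any(hit)) next
    edges <- rbind(edges, cbind(which(ok)[hit], lut[nbkey[hit]]))
    wts <- c(wts, rep(sqrt(sum((d * sp)^2)), sum(hit)))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
    igraph::E(g)$weight <- wts
  }
  deg <- igraph::degree(g)
  structure(list(graph = g,
                 coords_mm = sweep(pos - 1, 2L, sp, `*`),
                 endpoints = which(deg <= 1L),
                 junctions = which(deg >= 3L)),
            class = "skeleton_graph")
}

branch_lengths <- function(sg) {
  g <- sg$graph
  deg <- igraph::degree(g)
  special <- which(deg != 2L)
  if (!length(special)) return(numeric(0))  # pure cycle
  visited_edge <- new.env()
  lens <- numeric(0)
  for (s in special) {
    for (nb in as.integer(igraph::neighbors(g, s))) {
      ekey <- paste(min(s, nb), max(s, nb))
      if (!is.null(visited_edge[[ekey]])) next
      len <- 0; prev <- s; cur <- nb
      visited_edge[[ekey]] <- TRUE
      len <- len + igraph::E(g, P = c(prev, cur))$weight
      while (deg[cur] == 2L) {
        nxt <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (!length(nxt)) break
        nxt <- nxt[1]
        visited_edge[[paste(min(cur, nxt), max(cur, nxt))]] <- TRUE
        len <- len + igraph::E(g, P = c(cur, nxt))$weight
        prev <- cur; cur <- nxt
      }
      lens <- c(lens, len)
    }
  }
  lens
}

#' Placental elongation: longest branch of the medial-axis skeleton
#'
#' The mask is thinned to a curve skeleton, the skeleton is turned into a
#' weighted voxel graph, and the elongation is the physical length of its
#' longest branch. Two notions of "branch" are offered: the default
#' `"geodesic"` takes the longest shortest path between any two skeleton
#' endpoints; `"branch"` takes the longest simple segment between
#' endpoint/junction nodes after junction decomposition.
#'
#' @param mask a nonempty `seg_mask`.
#' @param method `"geodesic"` (default) or `"branch"`.
#' @param resample_isotropic see [skeletonize()].
#' @return elongation in cm; 0 (with a warning) when the skeleton collapses
#'   to a single voxel or has no endpoint pair.
#' @export
elongation <- function(mask, method = c("geodesic", "branch"),
                       resample_isotropic = FALSE) {
  method <- match.arg(method)
  sk <- skeletonize(mask, resample_isotropic = resample_isotropic)
  nvox <- sum(sk$data)
  if (nvox <= 1L) {
    warning("elongation: skeleton reduced to a single voxel")
    return(0)
  }
  sg <- skeleton_graph(sk)
  if (method == "branch") {
    lens <- branch_lengths(sg)
    if (!length(lens)) {
      warning("elongation: skeleton has no branch decomposition (cycle)")
      return(0)
    }
    return(max(lens) / 10)
  }
  ep <- sg$endpoints
  if (length(ep) < 2L) {
    warning("elongation: fewer than two skeleton endpoints")
    return(0)
  }
  dm <- igraph::distances(sg$graph, v = ep, to = ep)
  dm[!is.finite(dm)] <- 0
  max(dm) / 10  # mm -> cm
}

#' All three shape features of a segmented placenta
#'
#' @param mask a nonempty `seg_mask`.
#' @param rim_fraction rim band for surface labeling (see
#'   [label_surfaces()]).
#' @param resample_isotropic see [skeletonize()].
#' @return named numeric: volume_cm3, thickness_cm, elongation_cm.
#' @export
shape_features <- function(mask, rim_fraction = 0.1,
                           resample_isotropic = FALSE) {
  mesh <- mask_to_mesh(mask)
  mesh <- label_surfaces(mesh, rim_fraction = rim_fraction)
  c(volume_cm3 = mesh_volume(mesh),
    thickness_cm = thickness(mesh),
    elongation_cm = elongation(mask,
                               resample_isotropic = resample_isotropic))
}
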
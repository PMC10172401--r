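#' @useDynLib placentex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 6-connected components of a binary array, via igraph on the foreground
# voxel adjacency. Returns integer array of component labels (0 background).
mask_components <- function(m) {
  dims <- dim(m)
  fg <- which(m != 0L)
  lab <- array(0L, dims)
  if (!length(fg)) return(lab)
  pos <- arrayInd(fg, dims)
  key <- (pos[, 3] - 1L) * (dims[1] * dims[2]) + (pos[, 2] - 1L) * dims[1] +
    pos[, 1]
  lut <- integer(prod(dims)); lut[key] <- seq_along(fg)
  edges <- NULL
  for (ax in 1:3) {
    ok <- pos[, ax] < dims[ax]
    nb <- pos[ok, , drop = FALSE]; nb[, ax] <- nb[, ax] + 1L
    nbkey <- (nb[, 3] - 1L) * (dims[1] * dims[2]) + (nb[, 2] - 1L) * dims[1] +
      nb[, 1]
    hit <- lut[nbkey] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], lut[nbkey[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

keep_largest_component <- function(m, warn = TRUE) {
  lab <- mask_components(m)
  k <- max(lab)
  if (k <= 1L) return(m)
  if (warn)
    warning("mask has ", k, " connected components; keeping the largest")
  best <- which.max(tabulate(lab[lab > 0L], nbins = k))
  array(as.integer(lab == best), dim(m))
}

# The 6 Kuhn simplices of the unit cube (vertex offsets, one tet per row
# permutation path from (0,0,0) to (1,1,1)). Translation-invariant and
# face-to-face across neighboring cells, so the extracted surface closes.
kuhn_tets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(seq_len(nrow(perms)), function(r) {
    e <- diag(3)
    v <- matrix(0, 4, 3)
    v[2, ] <- e[perms[r, 1], ]
    v[3, ] <- v[2, ] + e[perms[r, 2], ]
    v[4, ] <- c(1, 1, 1)
    v
  })
}

#' Extract a closed triangular surface mesh from a segmentation mask
#'
#' Iso-surface of the binary mask at level 0.5 on the physically scaled
#' lattice, extracted by marching tetrahedra over the Kuhn (six-simplex)
#' decomposition of each voxel cell; surface vertices sit at lattice edge
#' midpoints. The mask is zero-padded first so the surface always closes.
#' If the mask has several 6-connected components, the largest is kept with
#' a warning. Triangles are wound so that their normals point outward, so
#' the signed divergence-theorem volume is positive.
#'
#' @param mask a nonempty `seg_mask`.
#' @return object of class `placenta_mesh`: `vertices` (n x 3, mm),
#'   `triangles` (m x 3 vertex indices), `labels` (NULL until
#'   [label_surfaces()]), `spacing_mm`.
#' @export
mask_to_mesh <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  if (isTRUE(attr(mask, "empty"))) stop("mask_to_mesh: empty mask")
  m <- keep_largest_component(mask$data)
  dims <- dim(m)
  B <- array(0L, dims + 2L)
  B[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- m
  nd <- dim(B)
  Bv <- as.integer(B)
  lin <- function(ijk) (ijk[, 3] - 1L) * (nd[1] * nd[2]) +
    (ijk[, 2] - 1L) * nd[1] + ijk[, 1]

  # active cells: 2x2x2 corner blocks with mixed occupancy
  cd <- nd - 1L
  S <- array(0L, cd)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1)
    S <- S + B[(1:cd[1]) + ox, (1:cd[2]) + oy, (1:cd[3]) + oz]
  act <- which(S > 0L & S < 8L)
  if (!length(act)) stop("mask_to_mesh: no surface cells found")
  base <- arrayInd(act, cd)

  tets <- kuhn_tets()
  triA <- triB <- NULL  # edge endpoint corner ids per triangle vertex
  refs <- NULL          # an inside corner id per triangle (orientation ref)
  for (tet in tets) {
    gid <- sapply(1:4, function(v)
      lin(sweep(base, 2L, as.integer(tet[v, ]), `+`)))
    if (is.null(dim(gid))) gid <- matrix(gid, nrow = 1L)
    vals <- matrix(Bv[gid], nrow = nrow(gid))
    mcount <- rowSums(vals)
    emit <- function(rows, vcorn, ocorn) {
      # single separated corner vcorn vs three corners ocorn (3 columns)
      if (!length(rows)) return(NULL)
      v <- gid[rows, , drop = FALSE][cbind(seq_along(rows), vcorn)]
      o <- sapply(1:3, function(k)
        gid[rows, , drop = FALSE][cbind(seq_along(rows), ocorn[, k])])
      if (is.null(dim(o))) o <- matrix(o, nrow = 1L)
      list(A = cbind(v, v, v), B = o)
    }
    # one inside corner
    r1 <- which(mcount == 1L)
    if (length(r1)) {
      ins <- as.integer(vals[r1, , drop = FALSE] %*% (1:4))
      outs <- t(apply(cbind(ins), 1L, function(i) setdiff(1:4, i)))
      e <- emit(r1, ins, outs)
      triA <- rbind(triA, e$A); triB <- rbind(triB, e$B)
      refs <- c(refs, gid[r1, , drop = FALSE][cbind(seq_along(r1), ins)])
    }
    # one outside corner
    r3 <- which(mcount == 3L)
    if (length(r3)) {
      out1 <- as.integer((1L - vals[r3, , drop = FALSE]) %*% (1:4))
      ins3 <- t(apply(cbind(out1), 1L, function(i) setdiff(1:4, i)))
      e <- emit(r3, out1, ins3)
      triA <- rbind(triA, e$A); triB <- rbind(triB, e$B)
      refs <- c(refs, gid[r3, , drop = FALSE][cbind(seq_along(r3), ins3[, 1])])
    }
    # two-two split: quad across the four cut edges, two triangles
    r2 <- which(mcount == 2L)
    if (length(r2)) {
      pat <- as.integer(vals[r2, , drop = FALSE] %*% c(1L, 2L, 4L, 8L))
      pairs <- list(`3` = c(1, 2, 3, 4), `5` = c(1, 3, 2, 4),
                    `9` = c(1, 4, 2, 3), `6` = c(2, 3, 1, 4),
                    `10` = c(2, 4, 1, 3), `12` = c(3, 4, 1, 2))
      for (pt in names(pairs)) {
        rr <- r2[pat == as.integer(pt)]
        if (!length(rr)) next
        pp <- pairs[[pt]]  # inside v,w; outside a,b
        g <- gid[rr, , drop = FALSE]
        v <- g[, pp[1]]; w <- g[, pp[2]]; a <- g[, pp[3]]; b <- g[, pp[4]]
        # quad m(v,a) - m(v,b) - m(w,b) - m(w,a)
        triA <- rbind(triA, cbind(v, v, w), cbind(v, w, w))
        triB <- rbind(triB, cbind(a, b, b), cbind(a, b, a))
        refs <- c(refs, v, v)
      }
    }
  }

  nc1 <- prod(nd) + 1
  key <- pmin(triA, triB) * nc1 + pmax(triA, triB)
  ukey <- sort(unique(as.numeric(key)))
  vid <- matrix(match(as.numeric(key), ukey), nrow = nrow(key))
  corner_xyz <- function(id) {
    id0 <- id - 1
    cbind(id0 %% nd[1] + 1, (id0 %/% nd[1]) %% nd[2] + 1,
          id0 %/% (nd[1] * nd[2]) + 1)
  }
  ca <- corner_xyz(ukey %/% nc1)
  cb <- corner_xyz(ukey %% nc1)
  # padded lattice index -> physical mm: voxel centers at (i - 1) * spacing
  sp <- mask$spacing_mm
  verts <- sweep((ca + cb) / 2 - 2, 2L, sp, `*`)
  refxyz <- sweep(corner_xyz(refs) - 2, 2L, sp, `*`)

  # orient each triangle so its normal points away from the inside corner
  p1 <- verts[vid[, 1], , drop = FALSE]
  p2 <- verts[vid[, 2], , drop = FALSE]
  p3 <- verts[vid[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cent <- (p1 + p2 + p3) / 3
  flip <- rowSums(nrm * (cent - refxyz)) < 0
  tmp <- vid[flip, 2]; vid[flip, 2] <- vid[flip, 3]; vid[flip, 3] <- tmp

  structure(list(vertices = verts, triangles = vid, labels = NULL,
                 spacing_mm = sp),
            class = "placenta_mesh")
}

#' @export
print.placenta_mesh <- function(x, ...) {
  cat("placenta_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles",
      if (!is.null(x$labels)) "(surfaces labeled)" else "", "\n")
  invisible(x)
}

mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  n1 <- nrow(mesh$vertices) + 1
  ed <- rbind(cbind(tr[, 1], tr[, 2]), cbind(tr[, 2], tr[, 3]),
              cbind(tr[, 3], tr[, 1]))
  key <- pmin(ed[, 1], ed[, 2]) * n1 + pmax(ed[, 1], ed[, 2])
  all(table(key) == 2L)
}

#' Divergence-theorem volume of a closed mesh
#'
#' V = (1/6) |sum over triangles of det(v1, v2, v3)|. The mesh must be
#' closed (every edge shared by exactly two triangles); the absolute value
#' makes the result orientation-proof for consistently wound meshes.
#'
#' @param mesh a `placenta_mesh` (vertices in mm).
#' @return volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "placenta_mesh"))
  if (!mesh_is_closed(mesh)) stop("mesh_volume: mesh is not closed")
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(det6)) / 6 / 1000  # mm^3 -> cm^3
}

#' Label maternal and fetal surfaces of a placental mesh
#'
#' Default heuristic: project vertices (relative to their centroid) onto the
#' smallest principal axis of the vertex cloud — for a disc-like placenta
#' this is the flat axis — and split by sign. Vertices within a band of the
#' splitting plane are labeled `rim`. The side assignment is geometric, not
#' anatomical; `flip` swaps the two caps, and an explicit `labels` vector
#' always overrides the heuristic.
#'
#' @param mesh a `placenta_mesh`.
#' @param rim_fraction half-width of the rim band as a fraction of the
#'   maximal absolute projection (default 0.1).
#' @param flip swap maternal and fetal caps.
#' @param labels optional character vector (length = number of vertices)
#'   with values in maternal/fetal/rim; returned unchanged.
#' @return the mesh with `labels` set.
#' @export
label_surfaces <- function(mesh, rim_fraction = 0.1, flip = FALSE,
                           labels = NULL) {
  stopifnot(inherits(mesh, "placenta_mesh"))
  if (!is.null(labels)) {
    if (length(labels) != nrow(mesh$vertices))
      stop("label_surfaces: labels length must match vertex count")
    if (!all(labels %in% c("maternal", "fetal", "rim")))
      stop("label_surfaces: labels must be maternal/fetal/rim")
    mesh$labels <- labels
    return(mesh)
  }
  pc <- stats::prcomp(mesh$vertices, center = TRUE, scale. = FALSE)
  sdv <- pc$sdev
  if (sdv[3] <= 0 || sdv[2] / max(sdv[3], 1e-12) < 1.05)
    warning("label_surfaces: near-degenerate principal axes; ",
            "split may be arbitrary")
  s <- pc$x[, 3]
  band <- rim_fraction * max(abs(s))
  lab <- ifelse(s > band, "fetal", ifelse(s < -band, "maternal", "rim"))
  if (flip) {
    swap <- c(maternal = "fetal", fetal = "maternal", rim = "rim")
    lab <- unname(swap[lab])
  }
  mesh$labels <- lab
  mesh
}

#' Maximal maternal-to-fetal surface distance (placental thickness)
#'
#' For every vertex of the maternal surface the projection onto the fetal
#' surface is its closest point on the fetal sub-mesh (exact point-to-
#' triangle distance); the thickness is the maximum of these distances.
#' Reduces to the plate separation for parallel slabs.
#'
#' @param mesh a labeled `placenta_mesh` (see [label_surfaces()]).
#' @return thickness in cm.
#' @export
thickness <- function(mesh) {
  stopifnot(inherits(mesh, "placenta_mesh"))
  if (is.null(mesh$labels)) stop("thickness: mesh has no surface labels")
  mat <- mesh$labels == "maternal"
  fet <- mesh$labels == "fetal"
  if (!any(mat) || !any(fet))
    stop("thickness: maternal or fetal surface is empty")
  tr <- mesh$triangles
  allfet <- fet[tr[, 1]] & fet[tr[, 2]] & fet[tr[, 3]]
  if (!any(allfet)) allfet <- fet[tr[, 1]] | fet[tr[, 2]] | fet[tr[, 3]]
  if (!any(allfet)) stop("thickness: no fetal triangles")
  ft <- tr[allfet, , drop = FALSE]
  v <- mesh$vertices
  d <- .cpp_min_point_tri_dist(v[mat, , drop = FALSE],
                               v[ft[, 1], , drop = FALSE],
                               v[ft[, 2], , drop = FALSE],
                               v[ft[, 3], , drop = FALSE])
  max(d) / 10  # mm -> cm
}
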
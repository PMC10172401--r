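test_that("mesh extraction closes and recovers the volume of simple solids", {
  cube <- box_mask(c(10, 10, 10))
  mesh <- mask_to_mesh(cube)
  expect_true(placentex:::mesh_is_closed(mesh))
  v <- mesh_volume(mesh) * 1000  # mm^3
  expect_lt(abs(v - 1000) / 1000, 0.05)

  # single-voxel mask: a valid tiny closed mesh
  one <- make_mask(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3))
  m1 <- mask_to_mesh(one)
  expect_true(placentex:::mesh_is_closed(m1))
  expect_gt(mesh_volume(m1), 0)

  # rotating the lattice must not change the volume
  rot <- seg_mask(aperm(cube$data, c(2, 1, 3))[, dim(cube$data)[1]:1, ],
                  cube$spacing_mm)
  expect_equal(mesh_volume(mask_to_mesh(rot)), mesh_volume(mesh))

  # multiple components: largest kept, with a warning
  two <- cube$data
  two[1, 1, 1] <- 1L
  expect_warning(m2 <- mask_to_mesh(seg_mask(two, c(1, 1, 1))),
                 "components")
  expect_equal(mesh_volume(m2), mesh_volume(mesh))

  expect_error(mask_to_mesh(make_mask(rep(0, 27), c(3, 3, 3))), "empty")
})

test_that("divergence-theorem volume is exact on a hand-built tetrahedron", {
  mesh <- structure(list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    triangles = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
    labels = NULL, spacing_mm = c(1, 1, 1)), class = "placenta_mesh")
  expect_equal(mesh_volume(mesh), 1 / 6 / 1000, tolerance = 1e-12)
  # mirror image: same volume after orientation fix
  mir <- mesh
  mir$vertices[, 1] <- -mir$vertices[, 1]
  expect_equal(mesh_volume(mir), 1 / 6 / 1000, tolerance = 1e-12)
  # open mesh is rejected
  open_mesh <- mesh
  open_mesh$triangles <- mesh$triangles[1:3, ]
  expect_error(mesh_volume(open_mesh), "not closed")
})

test_that("mesh volume tracks voxel volume and scales with spacing cubed", {
  for (ax in list(c(9, 7, 5), c(15, 6, 4))) {
    m <- ellipsoid_mask(ax)
    vox <- sum(m$data) / 1000
    expect_lt(abs(mesh_volume(mask_to_mesh(m)) - vox) / vox, 0.05)
  }
  m1 <- ellipsoid_mask(c(9, 7, 5))
  m2 <- seg_mask(m1$data, c(2, 2, 2))
  expect_equal(mesh_volume(mask_to_mesh(m2)),
               8 * mesh_volume(mask_to_mesh(m1)), tolerance = 1e-9)
})

test_that("surface labeling splits caps along the flat axis", {
  slab <- box_mask(c(40, 30, 10), spacing = c(2, 2, 2))
  mesh <- label_surfaces(mask_to_mesh(slab))
  z <- mesh$vertices[, 3]
  lo <- mesh$labels[z == min(z)]
  hi <- mesh$labels[z == max(z)]
  expect_true(all(lo == lo[1]) && all(hi == hi[1]) && lo[1] != hi[1])
  expect_setequal(c(lo[1], hi[1]), c("maternal", "fetal"))

  # generator phantoms are flat along z: caps must split along z too
  set.seed(8)
  ph <- placenta_phantom(c(20, 15, 6), bend_frac = 0)
  pm <- label_surfaces(mask_to_mesh(ph$mask))
  zc <- pm$vertices[, 3]
  expect_true(mean(pm$labels[zc > stats::median(zc)] == "fetal") > 0.8 ||
              mean(pm$labels[zc > stats::median(zc)] == "maternal") > 0.8)

  # an explicit labeling always wins
  lab <- rep("rim", nrow(mesh$vertices))
  lab[1:10] <- "maternal"; lab[11:20] <- "fetal"
  expect_identical(label_surfaces(mesh, labels = lab)$labels, lab)
  # near-spherical clouds warn
  ball <- ellipsoid_mask(c(8, 8, 8))
  expect_warning(label_surfaces(mask_to_mesh(ball)), "degenerate")
})

test_that("thickness equals plate separation and is swap-symmetric", {
  slab <- box_mask(c(40, 30, 10), spacing = c(2, 2, 2))
  mesh <- label_surfaces(mask_to_mesh(slab))
  expect_equal(thickness(mesh), 2)
  expect_equal(thickness(label_surfaces(mesh, flip = TRUE)), 2)
  # empty cap errors
  bad <- mesh; bad$labels[bad$labels == "fetal"] <- "rim"
  expect_error(thickness(bad), "empty")
})

test_that("disc-to-dome thickness matches the analytic maximum", {
  # hemispherical dome of radius 30 mm (fetal) over its base disc
  # (maternal): the farthest disc point is the center, at distance r
  r <- 30
  th <- seq(0, pi / 2, length.out = 60)
  phi <- seq(0, 2 * pi, length.out = 120)
  dome <- cbind(as.vector(r * outer(sin(th), cos(phi))),
                as.vector(r * outer(sin(th), sin(phi))),
                as.vector(r * outer(cos(th), rep(1, length(phi)))))
  # fetal surface as a triangle fan over the dome point cloud is overkill;
  # point-triangle distance needs triangles, so triangulate the lat-long grid
  nth <- length(th); nph <- length(phi)
  idx <- function(i, j) (j - 1) * nth + i  # column-major grid flattening
  tris <- NULL
  for (i in 1:(nth - 1)) for (j in 1:(nph - 1))
    tris <- rbind(tris, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                  c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  disc_r <- as.vector(outer(seq(0, r, length.out = 12), rep(1, 24)))
  disc_a <- as.vector(outer(rep(1, 12), seq(0, 2 * pi, length.out = 24)))
  disc <- cbind(disc_r * cos(disc_a), disc_r * sin(disc_a), 0)
  verts <- rbind(dome, disc)
  labels <- c(rep("fetal", nrow(dome)), rep("maternal", nrow(disc)))
  mesh <- structure(list(vertices = verts, triangles = tris,
                         labels = labels, spacing_mm = c(1, 1, 1)),
                    class = "placenta_mesh")
  got <- thickness(mesh)
  # brute-force oracle: min distance from each disc point to a fine dome
  # sampling, then the maximum
  fine_th <- seq(0, pi / 2, length.out = 200)
  fine_ph <- seq(0, 2 * pi, length.out = 400)
  fp <- cbind(as.vector(r * outer(sin(fine_th), cos(fine_ph))),
              as.vector(r * outer(sin(fine_th), sin(fine_ph))),
              as.vector(r * outer(cos(fine_th), rep(1, length(fine_ph)))))
  dmin <- apply(disc, 1, function(p)
    sqrt(min(colSums((t(fp) - p)^2))))
  expect_equal(got, max(dmin) / 10, tolerance = 0.02)
  expect_equal(got, 3, tolerance = 0.02)
})

test_that("shape features are invariant to axis permutation and scale", {
  m <- ellipsoid_mask(c(12, 8, 5))
  f1 <- suppressWarnings(shape_features(m))
  mp <- seg_mask(aperm(m$data, c(3, 1, 2)), c(1, 1, 1))
  f2 <- suppressWarnings(shape_features(mp))
  expect_equal(unname(f1["volume_cm3"]), unname(f2["volume_cm3"]),
               tolerance = 1e-9)
  expect_equal(unname(f1["elongation_cm"]), unname(f2["elongation_cm"]),
               tolerance = 1e-9)
  expect_equal(unname(f1["thickness_cm"]), unname(f2["thickness_cm"]),
               tolerance = 1e-6)
  # doubling the spacing doubles lengths and scales volume by 8
  ms <- seg_mask(m$data, c(2, 2, 2))
  f3 <- suppressWarnings(shape_features(ms))
  expect_equal(unname(f3["volume_cm3"]), 8 * unname(f1["volume_cm3"]),
               tolerance = 1e-9)
  expect_equal(unname(f3["thickness_cm"]), 2 * unname(f1["thickness_cm"]),
               tolerance = 1e-9)
  expect_equal(unname(f3["elongation_cm"]), 2 * unname(f1["elongation_cm"]),
               tolerance = 1e-9)
})
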
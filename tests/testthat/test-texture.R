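qv <- function(levels, dims = NULL, ng = max(levels)) {
  if (is.null(dims)) dims <- dim(levels)
  structure(list(levels = array(as.integer(levels), dims),
                 n_levels = as.integer(ng),
                 bin_edges = seq(0, 1, length.out = ng + 1), scope = "mask"),
            class = "quantized_volume")
}

test_that("co-occurrence accumulation counts the expected pairs", {
  # constant 2x2x2 block: every pair is (1,1)
  q <- qv(rep(1L, 8), c(2, 2, 2))
  g <- glcm_accumulate(q, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(g[[1]]$P[1, 1], 1)
  # row 1,2,1,2 along y: three ordered pairs, symmetric -> p(1,2)=p(2,1)=0.5
  q2 <- qv(c(1L, 2L, 1L, 2L), c(1, 4, 1), ng = 2)
  g2 <- glcm_accumulate(q2, directions = matrix(c(0L, 1L, 0L), 1))
  expect_equal(g2[[1]]$P, matrix(c(0, 0.5, 0.5, 0), 2))
  # a mask gap splits the row: only within-mask pairs are counted
  q3 <- qv(c(1L, 2L, 0L, 1L, 2L), c(1, 5, 1), ng = 2)
  g3 <- glcm_accumulate(q3, directions = matrix(c(0L, 1L, 0L), 1))
  expect_equal(g3[[1]]$counts[1, 2] + g3[[1]]$counts[2, 1], 4)
  expect_equal(sum(g3[[1]]$counts), 4)
})

test_that("co-occurrence features match hand values and degenerate cases", {
  # all mass on one diagonal cell
  g1 <- structure(list(P = matrix(c(1, 0, 0, 0), 2), direction = c(1, 0, 0),
                       distance = 1, n_pairs = 1), class = "glcm")
  f1 <- glcm_features(g1)
  expect_equal(unname(f1[c("energy", "entropy", "idm", "contrast",
                           "cluster_shade", "cluster_prominence")]),
               c(1, 0, 1, 0, 0, 0))
  # uniform 4x4: energy 1/16, entropy 4 bits
  g2 <- structure(list(P = matrix(1 / 16, 4, 4)), class = "glcm")
  f2 <- glcm_features(g2)
  expect_equal(unname(f2["energy"]), 0.0625)
  expect_equal(unname(f2["entropy"]), 4)
  # p = [[.5,.25],[.25,0]]: hand expansion
  P <- matrix(c(0.5, 0.25, 0.25, 0), 2)
  f3 <- glcm_features(structure(list(P = P), class = "glcm"))
  expect_equal(unname(f3["contrast"]), 0.5)
  expect_equal(unname(f3["energy"]), 0.375)
  expect_equal(unname(f3["idm"]), 0.75)
  expect_equal(f3[names(oracle_glcm_features(P))],
               oracle_glcm_features(P), tolerance = 1e-12)
})

test_that("run decomposition counts maximal in-mask streaks", {
  # line 1,1,2,2,2 -> R(1,2)=1, R(2,3)=1
  r <- rlm_accumulate(qv(c(1L, 1L, 2L, 2L, 2L), c(1, 5, 1)), c(0, 1, 0))
  expect_equal(r$n_runs, 2)
  expect_equal(r$n_voxels, 5)
  expect_equal(r$R[1, 2], 1)
  expect_equal(r$R[2, 3], 1)
  # alternating levels: four runs of length one
  r2 <- rlm_accumulate(qv(c(1L, 2L, 1L, 2L), c(1, 4, 1)), c(0, 1, 0))
  expect_equal(r2$n_runs, 4)
  expect_equal(ncol(r2$R), 1)
  # constant line: one run of full length
  r3 <- rlm_accumulate(qv(rep(2L, 7), c(1, 7, 1)), c(0, 1, 0))
  expect_equal(r3$n_runs, 1)
  expect_equal(r3$R[2, 7], 1)
  # mask gaps break runs
  r4 <- rlm_accumulate(qv(c(2L, 2L, 0L, 2L), c(1, 4, 1)), c(0, 1, 0))
  expect_equal(r4$n_runs, 2)
  expect_equal(r4$n_voxels, 3)
})

test_that("run-length features match single-run and two-run hand values", {
  single <- structure(list(R = {
    R <- matrix(0, 3, 4); R[2, 4] <- 1; R
  }, n_runs = 1, n_voxels = 4, direction = c(1, 0, 0)), class = "rlm")
  f <- rlm_features(single)
  expect_equal(unname(f[c("sre", "lre", "hglre", "srhgle")]),
               c(1 / 16, 16, 4, 0.25))
  two <- rlm_accumulate(qv(c(1L, 1L, 2L, 2L, 2L), c(1, 5, 1)), c(0, 1, 0))
  f2 <- rlm_features(two)
  expect_equal(unname(f2["sre"]), (1 / 4 + 1 / 9) / 2)
  expect_equal(unname(f2["glnu"]), 1)
  expect_equal(unname(f2["rlnu"]), 1)
  # all runs length 1
  f3 <- rlm_features(rlm_accumulate(qv(c(1L, 2L, 1L, 2L), c(1, 4, 1)),
                                    c(0, 1, 0)))
  expect_equal(unname(f3["sre"]), 1)
  expect_equal(unname(f3["lre"]), 1)
})

test_that("implementation agrees with brute-force oracles on random arrays", {
  dirs <- lattice_directions_3d()
  for (seed in 1:30) {
    sc <- random_masked_scan(seed)
    q <- quantize(sc$image, sc$mask, 4)
    oc <- oracle_texture_features(q, dirs)
    gl <- glcm_features(glcm_accumulate(q, directions = dirs))
    rl <- rlm_features(rlm_accumulate_all(q, directions = dirs))
    expect_equal(gl[names(oc$glcm)], oc$glcm, tolerance = 1e-12)
    expect_equal(rl[names(oc$rlm)], oc$rlm, tolerance = 1e-12)
  }
})

test_that("GLCM and RLM structural invariants hold on random inputs", {
  dirs <- lattice_directions_3d()
  for (seed in 31:45) {
    sc <- random_masked_scan(seed)
    q <- quantize(sc$image, sc$mask, 5)
    np <- sum(q$levels > 0)
    for (g in glcm_accumulate(q, directions = dirs)) {
      expect_equal(sum(g$P), 1, tolerance = 1e-9)
      expect_equal(rowSums(g$P), colSums(g$P), tolerance = 1e-12)
    }
    for (r in rlm_accumulate_all(q, directions = dirs)) {
      expect_equal(sum(sweep(r$R, 2, seq_len(ncol(r$R)), `*`)), np)
      expect_equal(sum(r$R), r$n_runs)
    }
  }
})

test_that("texture features ignore intensity offsets after quantization", {
  sc <- random_masked_scan(99)
  q1 <- quantize(sc$image, sc$mask, 6)
  img2 <- sc$image; img2$data <- img2$data + 17.3
  q2 <- quantize(img2, sc$mask, 6)
  expect_identical(q1$levels, q2$levels)
  expect_equal(glcm_features(glcm_accumulate(q1)),
               glcm_features(glcm_accumulate(q2)))
})

test_that("histogram features are ratios to whole-image statistics", {
  # mask = whole image -> all ratios are exactly 1
  set.seed(4)
  img <- make_image(stats::rnorm(120, 10, 3)^2, c(5, 6, 4))
  h <- histogram_features(img, make_mask(rep(1, 120), c(5, 6, 4)))
  expect_equal(as.numeric(h), rep(1, 4))
  # a listed-value region inside a known whole image: verify the four
  # ratios against direct moment formulas
  reg_vals <- c(1, 2, 3, 4, 5, 6, 2, 5)
  vals <- c(reg_vals, rep(0.5, 112))
  img2 <- make_image(vals, c(5, 6, 4))
  msk2 <- make_mask(c(rep(1, 8), rep(0, 112)), c(5, 6, 4))
  h2 <- histogram_features(img2, msk2)
  mom <- function(v) {
    m <- mean(v); s <- mean((v - m)^2)
    c(m, s, mean((v - m)^4) / s^2, mean((v - m)^3) / s^1.5)
  }
  reg <- mom(reg_vals); who <- mom(vals)
  expect_equal(as.numeric(h2), reg / who, tolerance = 1e-12)
  # constant region in a varying image: variance ratio 0, flags set
  img3 <- make_image(c(rep(2, 8), stats::rnorm(112)), c(5, 6, 4))
  msk3 <- make_mask(c(rep(1, 8), rep(0, 112)), c(5, 6, 4))
  h3 <- histogram_features(img3, msk3)
  expect_equal(unname(h3["variance_gl"]), 0)
  expect_equal(unname(h3[c("kurtosis_gl", "skewness_gl")]), c(0, 0))
  expect_true(length(attr(h3, "flags")) >= 2)
})

test_that("longer texture correlation lengths raise long-run emphasis", {
  lre_at <- function(ell) {
    vals <- numeric(20)
    for (s in 1:20) {
      set.seed(1000 + s)
      ph <- placenta_phantom(c(16, 12, 8), spacing_mm = c(1, 1, 1),
                             corr_length_mm = ell, gamma = 0)
      q <- quantize(ph$image, ph$mask, 8)
      vals[s] <- rlm_features(rlm_accumulate_all(q))["lre"]
    }
    mean(vals)
  }
  v <- c(lre_at(0.8), lre_at(2), lre_at(4))
  expect_true(all(diff(v) > 0))
})
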
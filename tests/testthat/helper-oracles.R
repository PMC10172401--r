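# independent brute-force oracles; deliberately naive (explicit loops and
# scalar accumulation), sharing no code with the implementation

oracle_glcm <- function(levels, d, symmetric = TRUE) {
  dims <- dim(levels)
  ng <- max(levels)
  cnt <- matrix(0, ng, ng)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (levels[i, j, k] == 0) next
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > dims[1] || jj > dims[2] ||
          kk > dims[3]) next
      if (levels[ii, jj, kk] == 0) next
      cnt[levels[i, j, k], levels[ii, jj, kk]] <-
        cnt[levels[i, j, k], levels[ii, jj, kk]] + 1
    }
  if (symmetric) cnt <- cnt + t(cnt)
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

oracle_glcm_features <- function(P, log_base = 2) {
  ng <- nrow(P)
  energy <- entropy <- idm <- contrast <- 0
  mux <- muy <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    energy <- energy + p * p
    if (p > 0) entropy <- entropy - p * log(p, base = log_base)
    idm <- idm + p / (1 + (i - j)^2)
    contrast <- contrast + (i - j)^2 * p
    mux <- mux + i * p
    muy <- muy + j * p
  }
  shade <- prom <- 0
  for (i in 1:ng) for (j in 1:ng) {
    dev <- i + j - mux - muy
    shade <- shade + dev^3 * P[i, j]
    prom <- prom + dev^4 * P[i, j]
  }
  c(energy = energy, entropy = entropy, idm = idm, contrast = contrast,
    cluster_shade = shade, cluster_prominence = prom)
}

# run-length matrix by explicit line walking
oracle_rlm <- function(levels, d) {
  dims <- dim(levels)
  ng <- max(levels)
  runs <- list()
  visited <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      # start of a line: the previous voxel along d is out of bounds
      pi <- i - d[1]; pj <- j - d[2]; pk <- k - d[3]
      if (pi >= 1 && pj >= 1 && pk >= 1 && pi <= dims[1] &&
          pj <= dims[2] && pk <= dims[3]) next
      # walk the line
      ci <- i; cj <- j; ck <- k
      cur_lev <- 0; cur_len <- 0
      while (ci >= 1 && cj >= 1 && ck >= 1 && ci <= dims[1] &&
             cj <= dims[2] && ck <= dims[3]) {
        lv <- levels[ci, cj, ck]
        if (lv == cur_lev && lv != 0) {
          cur_len <- cur_len + 1
        } else {
          if (cur_lev != 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
          cur_lev <- lv; cur_len <- if (lv != 0) 1 else 0
        }
        ci <- ci + d[1]; cj <- cj + d[2]; ck <- ck + d[3]
      }
      if (cur_lev != 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
    }
  if (!length(runs)) return(NULL)
  lmax <- max(vapply(runs, `[`, 0, 2))
  R <- matrix(0, ng, lmax)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_rlm_features <- function(R) {
  nr <- sum(R)
  vals <- c(sre = 0, lre = 0, glnu = 0, rlnu = 0, lglre = 0, hglre = 0,
            srlgle = 0, srhgle = 0, lrlgle = 0, lrhgle = 0)
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    r <- R[i, j]
    if (r == 0) next
    vals["sre"] <- vals["sre"] + r / j^2
    vals["lre"] <- vals["lre"] + r * j^2
    vals["lglre"] <- vals["lglre"] + r / i^2
    vals["hglre"] <- vals["hglre"] + r * i^2
    vals["srlgle"] <- vals["srlgle"] + r / (i^2 * j^2)
    vals["srhgle"] <- vals["srhgle"] + r * i^2 / j^2
    vals["lrlgle"] <- vals["lrlgle"] + r * j^2 / i^2
    vals["lrhgle"] <- vals["lrhgle"] + r * i^2 * j^2
  }
  for (i in seq_len(nrow(R))) vals["glnu"] <- vals["glnu"] + sum(R[i, ])^2
  for (j in seq_len(ncol(R))) vals["rlnu"] <- vals["rlnu"] + sum(R[, j])^2
  vals / nr
}

# min-over-suffix BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (j in k:m) best <- min(best, p[o[j]] * m / j)
    q[o[k]] <- min(1, best)
  }
  q
}

# texture features via the oracles, matching the implementation's
# feature-then-average convention
oracle_texture_features <- function(q, dirs = lattice_directions_3d()) {
  gl <- list(); rl <- list()
  for (r in seq_len(nrow(dirs))) {
    P <- oracle_glcm(q$levels, dirs[r, ])
    if (!is.null(P)) gl[[length(gl) + 1]] <- oracle_glcm_features(P)
    R <- oracle_rlm(q$levels, dirs[r, ])
    if (!is.null(R)) rl[[length(rl) + 1]] <- oracle_rlm_features(R)
  }
  list(glcm = rowMeans(do.call(cbind, gl)),
       rlm = rowMeans(do.call(cbind, rl)))
}
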
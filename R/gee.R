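#' Generalized estimating equations for Gaussian outcomes
#'
#' Marginal linear regression for clustered (longitudinal) data, solved by
#' iterated generalized least squares with a working correlation estimated
#' from Pearson residuals, and the robust (sandwich) covariance for
#' inference. Designed for cohorts in which each subject contributes one or
#' two scans, but handles general cluster sizes.
#'
#' Working correlation structures: `"unstructured"` (one parameter per
#' within-cluster position pair, positions taken in row order),
#' `"exchangeable"` (single common correlation), `"independence"`.
#' If the unstructured estimate is not a valid correlation matrix (or no
#' cluster carries a position pair) the fit falls back to exchangeable with
#' a logged warning. With all clusters of size 1 every structure reduces to
#' ordinary least squares.
#'
#' @param formula model formula (Gaussian outcome, identity link).
#' @param data data.frame holding outcome, predictors and the cluster id.
#' @param id name of the cluster (subject) id column.
#' @param corstr working correlation structure.
#' @param tol convergence tolerance on the coefficient change.
#' @param maxit maximum number of IGLS iterations.
#' @return object of class `gee_fit` with elements `coefficients`,
#'   `robust_se`, `vcov` (sandwich), `p_value`, `ci_lower`/`ci_upper`
#'   (normal 95%), `phi`, `alpha` (estimated correlation parameter(s)),
#'   `corstr`, `corstr_used`, `n_obs`, `n_clusters`, `n_dropped`,
#'   `xbar` (design column means, used for LS means), `converged`.
#' @export
gee_fit <- function(formula, data, id,
                    corstr = c("unstructured", "exchangeable",
                               "independence"),
                    tol = 1e-8, maxit = 50L) {
  corstr <- match.arg(corstr)
  if (!is.character(id) || length(id) != 1L || !id %in% names(data))
    stop("gee_fit: 'id' must name a column of 'data'")
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf) & !is.na(data[[id]])
  n_dropped <- sum(!keep)
  mf <- mf[keep, , drop = FALSE]
  if (!nrow(mf)) stop("gee_fit: no complete cases")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("gee_fit: singular design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cl <- as.character(data[[id]][keep])
  ucl <- unique(cl)
  cid <- match(cl, ucl)
  ord <- order(cid)            # cluster-contiguous, original order within
  X <- X[ord, , drop = FALSE]; y <- y[ord]; cid <- cid[ord]
  pos <- stats::ave(seq_along(cid), cid, FUN = seq_along)
  ni <- tabulate(cid)
  N <- length(y); K <- length(ucl); Tmax <- max(ni)

  beta <- qr.solve(X, y)
  corstr_used <- corstr
  fallback_warned <- FALSE
  alpha <- NULL; Rhat <- diag(1)
  converged <- FALSE

  estimate_R <- function(e, use) {
    # returns list(R = Tmax x Tmax working correlation) for corstr `use`
    if (use == "independence" || Tmax == 1L)
      return(diag(Tmax))
    if (use == "exchangeable") {
      s <- rowsum(e, cid); s2 <- rowsum(e^2, cid)
      num <- sum((s^2 - s2) / 2)
      den <- sum(ni * (ni - 1) / 2) - p
      if (den <= 0) den <- max(1, sum(ni * (ni - 1) / 2))
      a <- max(-0.95, min(0.95, num / den))
      R <- matrix(a, Tmax, Tmax); diag(R) <- 1
      return(R)
    }
    # unstructured
    R <- diag(Tmax)
    ok <- TRUE
    for (j in 1:(Tmax - 1)) for (k in (j + 1):Tmax) {
      hasj <- cid[pos == j]; ej <- e[pos == j]
      hask <- cid[pos == k]; ek <- e[pos == k]
      common <- intersect(hasj, hask)
      if (length(common) < 2L) { ok <- FALSE; next }
      num <- sum(ej[match(common, hasj)] * ek[match(common, hask)])
      den <- length(common) - p
      if (den <= 0) den <- length(common)
      R[j, k] <- R[k, j] <- num / den
    }
    if (!ok || any(abs(R[upper.tri(R)]) >= 1) ||
        min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-6)
      return(NULL)
    R
  }

  for (it in seq_len(maxit)) {
    r <- as.numeric(y - X %*% beta)
    phi <- sum(r^2) / (N - p)
    e <- r / sqrt(phi)
    use <- corstr_used
    Rhat <- estimate_R(e, use)
    if (is.null(Rhat)) {
      if (!fallback_warned) {
        warning("gee_fit: unstructured working correlation estimate ",
                "invalid; falling back to exchangeable")
        fallback_warned <- TRUE
      }
      corstr_used <- "exchangeable"
      Rhat <- estimate_R(e, "exchangeable")
    }
    Xt <- X / phi                       # V^{-1} X rows, start from size-1 form
    yt <- y / phi
    if (Tmax >= 2L) {
      # closed-form inverse for size-2 clusters (the typical case)
      two <- which(ni == 2L)
      if (length(two)) {
        i1 <- which(cid %in% two & pos == 1L)
        i2 <- which(cid %in% two & pos == 2L)
        a <- Rhat[1, 2]
        den <- phi * (1 - a^2)
        Xt[i1, ] <- (X[i1, , drop = FALSE] - a * X[i2, , drop = FALSE]) / den
        Xt[i2, ] <- (X[i2, , drop = FALSE] - a * X[i1, , drop = FALSE]) / den
        yt[i1] <- (y[i1] - a * y[i2]) / den
        yt[i2] <- (y[i2] - a * y[i1]) / den
      }
      big <- which(ni >= 3L)
      for (b in big) {
        rows <- which(cid == b)
        Vi <- phi * Rhat[pos[rows], pos[rows]]
        Vinv <- solve(Vi)
        Xt[rows, ] <- Vinv %*% X[rows, , drop = FALSE]
        yt[rows] <- Vinv %*% y[rows]
      }
    }
    A <- crossprod(X, Xt)
    bvec <- crossprod(Xt, y)
    beta_new <- solve(A, bvec)
    delta <- max(abs(beta_new - beta))
    beta <- as.numeric(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }

  # sandwich covariance: B^{-1} M B^{-1} with M from per-cluster scores
  r <- as.numeric(y - X %*% beta)
  u <- r / phi
  if (Tmax >= 2L) {
    two <- which(ni == 2L)
    if (length(two)) {
      i1 <- which(cid %in% two & pos == 1L)
      i2 <- which(cid %in% two & pos == 2L)
      a <- Rhat[1, 2]; den <- phi * (1 - a^2)
      u[i1] <- (r[i1] - a * r[i2]) / den
      u[i2] <- (r[i2] - a * r[i1]) / den
    }
    for (b in which(ni >= 3L)) {
      rows <- which(cid == b)
      Vinv <- solve(phi * Rhat[pos[rows], pos[rows]])
      u[rows] <- Vinv %*% r[rows]
    }
  }
  S <- rowsum(X * u, cid)               # per-cluster score contributions
  # bread of the sandwich, at the final beta/alpha
  Xt <- X / phi
  if (Tmax >= 2L) {
    two <- which(ni == 2L)
    if (length(two)) {
      i1 <- which(cid %in% two & pos == 1L)
      i2 <- which(cid %in% two & pos == 2L)
      a <- Rhat[1, 2]; den <- phi * (1 - a^2)
      Xt[i1, ] <- (X[i1, , drop = FALSE] - a * X[i2, , drop = FALSE]) / den
      Xt[i2, ] <- (X[i2, , drop = FALSE] - a * X[i1, , drop = FALSE]) / den
    }
    for (b in which(ni >= 3L)) {
      rows <- which(cid == b)
      Vinv <- solve(phi * Rhat[pos[rows], pos[rows]])
      Xt[rows, ] <- Vinv %*% X[rows, , drop = FALSE]
    }
  }
  A <- crossprod(X, Xt)
  Ainv <- solve(A)
  M <- crossprod(S)
  V <- Ainv %*% M %*% Ainv
  V <- (V + t(V)) / 2
  se <- sqrt(diag(V))
  names(beta) <- colnames(X)
  z <- beta / se
  zc <- stats::qnorm(0.975)
  structure(list(coefficients = beta, robust_se = stats::setNames(se, names(beta)),
                 vcov = V,
                 p_value = stats::setNames(2 * stats::pnorm(-abs(z)), names(beta)),
                 ci_lower = stats::setNames(beta - zc * se, names(beta)),
                 ci_upper = stats::setNames(beta + zc * se, names(beta)),
                 phi = phi,
                 alpha = if (Tmax >= 2L) Rhat[1, 2] else NA_real_,
                 working_R = Rhat,
                 corstr = corstr, corstr_used = corstr_used,
                 n_obs = N, n_clusters = K, n_dropped = n_dropped,
                 xbar = colMeans(X), converged = converged,
                 formula = formula, call = match.call()),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE (gaussian identity), working correlation:", x$corstr_used,
      "\nclusters:", x$n_clusters, " observations:", x$n_obs,
      if (x$n_dropped) paste0(" (", x$n_dropped, " rows dropped)"), "\n")
  tab <- data.frame(beta = x$coefficients, robust_se = x$robust_se,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                    p = x$p_value)
  print(signif(tab, 4))
  invisible(x)
}

#' @rdname gee_fit
#' @param object a `gee_fit`.
#' @param ... unused.
#' @export
summary.gee_fit <- function(object, ...) {
  object
}

#' Least-squares (model-adjusted) group means
#'
#' Predicted outcome for each level of a binary group indicator with every
#' other design column held at its grand mean over the rows used in the
#' fit; standard errors by the delta method on the robust covariance. The
#' difference of the two LS means equals the group coefficient.
#'
#' @param fit a `gee_fit`.
#' @param group name of the 0/1 group column in the design.
#' @return data.frame with columns `group`, `ls_mean`, `se`.
#' @export
ls_means <- function(fit, group) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!group %in% names(fit$coefficients))
    stop("ls_means: '", group, "' is not a design column")
  out <- lapply(c(0, 1), function(g) {
    cv <- fit$xbar
    cv[group] <- g
    est <- sum(cv * fit$coefficients)
    se <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
    data.frame(group = g, ls_mean = est, se = se)
  })
  do.call(rbind, out)
}
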
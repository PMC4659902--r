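# Oblique gradient-projection rotation with the quartimin criterion
# (oblimin with gamma = 0), after Jennrich's GPA scheme. A is the
# unrotated loading matrix; returns the rotated pattern, the factor
# correlation matrix Phi, and the rotation matrix T such that
# pattern = A %*% t(solve(T)).
rotate_oblimin <- function(A, eps = 1e-6, maxit = 1000) {
  k <- ncol(A)
  if (k < 2) return(list(loadings = A, Phi = diag(k), Tmat = diag(k)))
  N <- matrix(1, k, k) - diag(k)
  vgq <- function(L) {
    L2 <- L^2
    X <- L2 %*% N
    list(f = sum(L2 * X) / 4, Gq = L * X)
  }
  Tmat <- diag(k)
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  v <- vgq(L)
  f <- v$f
  G <- -t(t(L) %*% v$Gq %*% Ti)
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (half in 1:25) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vt <- vgq(L)
      if (vt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vt$f
    G <- -t(t(L) %*% vt$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat)
}

#' Rotated principal component analysis of environmental variables
#'
#' Standardizes every variable to zero mean and unit variance, extracts
#' the first two components from the correlation matrix, and (by default)
#' applies an oblimin (quartimin) rotation so that correlated axes — e.g.,
#' a seasonal and a spatial gradient — can each be read off one component.
#' Component signs are fixed so that each component's largest-|loading|
#' variable loads positively; sample scores use the regression method on
#' the standardized variables.
#'
#' @param env Numeric matrix, samples (named rows) by variables; every
#'   variable must have positive variance.
#' @param n_components Number of components (only 2 supported).
#' @param rotation `"oblimin"` (default) or `"none"`.
#' @return Object of class `env_pca`: list with `loadings` (pattern,
#'   variables x 2), `structure`, `phi` (inter-component correlation),
#'   `scores` (samples x 2), `var_explained` (per component, unrotated),
#'   `var_explained_rotated` (per component contribution after rotation),
#'   `total_var_explained` (total communality of the 2-component
#'   solution / number of variables), `rotation`.
#' @export
env_pca <- function(env, n_components = 2, rotation = c("oblimin", "none")) {
  rotation <- match.arg(rotation)
  env <- as.matrix(env)
  if (nrow(env) < 3) stop("need at least 3 samples", call. = FALSE)
  if (ncol(env) < 2) stop("need at least 2 variables", call. = FALSE)
  if (n_components != 2)
    stop("only the 2-component solution is supported", call. = FALSE)
  if (n_components > ncol(env))
    stop("more components than variables", call. = FALSE)
  vars <- apply(env, 2, stats::var)
  if (any(vars == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(env)[vars == 0], collapse = ", "), call. = FALSE)
  Z <- scale(env)
  R <- stats::cor(env)
  e <- eigen(R, symmetric = TRUE)
  A <- e$vectors[, 1:2, drop = FALSE] %*% diag(sqrt(e$values[1:2]), 2)
  rownames(A) <- colnames(env)
  if (rotation == "oblimin") {
    rot <- rotate_oblimin(A)
    L <- rot$loadings
    Phi <- rot$Phi
  } else {
    L <- A
    Phi <- diag(2)
  }
  # sign convention: the largest-|loading| variable of each component
  # loads positively
  for (j in 1:2) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) {
      L[, j] <- -L[, j]
      Phi[j, -j] <- -Phi[j, -j]
      Phi[-j, j] <- -Phi[-j, j]
    }
  }
  dimnames(L) <- list(colnames(env), c("PC1", "PC2"))
  S <- L %*% Phi                      # structure = pattern %*% Phi
  # regression-method score weights; pseudo-inverse covers the singular
  # correlation matrices that arise from collinear variables
  W <- tryCatch(solve(R, S), error = function(e) MASS::ginv(R) %*% S)
  scores <- Z %*% W
  dimnames(scores) <- list(rownames(env), c("PC1", "PC2"))
  p <- ncol(env)
  communality <- rowSums((L %*% Phi) * L)
  structure(list(
    loadings = L, structure = S, phi = Phi, scores = scores,
    var_explained = e$values[1:2] / p,
    var_explained_rotated = colSums(L * S) / p,
    total_var_explained = sum(communality) / p,
    rotation = rotation),
    class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("Environmental PCA (", x$rotation, " rotation): ",
      round(100 * x$total_var_explained, 1),
      "% of variance in 2 components; inter-component r = ",
      round(x$phi[1, 2], 3), "\n", sep = "")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Correlate OTU or class abundances with environmental axes
#'
#' Pearson correlation of each entity's per-sample abundance against each
#' component's sample scores, with optional Bonferroni adjustment over the
#' testable entities per axis. Constant entities are untestable and get NA
#' statistics.
#'
#' @param abundances An [otu_table] or a numeric matrix with entities as
#'   named rows and samples as named columns (e.g., class abundance
#'   vectors stacked with `rbind`).
#' @param scores Sample-score matrix from [env_pca] (or the `env_pca`
#'   object itself).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Data frame with columns `entity`, `n`, `r_pc1`, `r_pc2`,
#'   `p_pc1`, `p_pc2`, `sig_pc1`, `sig_pc2`.
#' @export
correlate_with_axes <- function(abundances, scores, alpha = 0.05,
                                adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (inherits(scores, "env_pca")) scores <- scores$scores
  m <- unclass(abundances)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("abundances must carry entity row names and sample column names",
         call. = FALSE)
  shared <- intersect(colnames(m), rownames(scores))
  if (length(shared) < 4)
    stop("fewer than 4 samples shared between abundances and scores",
         call. = FALSE)
  m <- m[, shared, drop = FALSE]
  sc <- scores[shared, , drop = FALSE]
  n <- length(shared)
  one_axis <- function(axis) {
    t(apply(m, 1, function(x) {
      if (stats::var(x) == 0) return(c(NA_real_, NA_real_))
      r <- stats::cor(x, sc[, axis])
      p <- if (abs(r) >= 1) 0 else
        2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2)
      c(r, p)
    }))
  }
  a1 <- one_axis(1); a2 <- one_axis(2)
  p1 <- a1[, 2]; p2 <- a2[, 2]
  if (adjust == "bonferroni") {
    fam <- sum(!is.na(p1))
    p1 <- pmin(1, p1 * fam)
    p2 <- pmin(1, p2 * fam)
  }
  out <- data.frame(entity = rownames(m), n = n,
                    r_pc1 = a1[, 1], r_pc2 = a2[, 1],
                    p_pc1 = p1, p_pc2 = p2,
                    sig_pc1 = !is.na(p1) & p1 < alpha,
                    sig_pc2 = !is.na(p2) & p2 < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "adjust") <- adjust
  out
}
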
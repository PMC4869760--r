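## gsmodel: RR-BLUP and G-BLUP with a single random kernel.
## REML is computed exactly on the spectral decomposition of the kernel
## restricted to the orthogonal complement of the fixed-effect space
## (profiled likelihood in the variance ratio), so fits are deterministic and
## fast at population sizes typical of a breeding program (N in the
## hundreds).

## Profiled REML for y = Xb + h + e, h ~ N(0, H * s2_k), e ~ N(0, I * s2_e).
## Returns the kernel-scale variance s2_k, s2_e and lambda = s2_e / s2_k.
reml_kernel <- function(y, X, H, lambda = NULL,
                        log_bounds = c(-12, 12)) {
  n <- length(y); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop("fixed-effect design is rank deficient")
  Q2 <- qr.Q(qx, complete = TRUE)[, -(seq_len(p)), drop = FALSE]
  A <- crossprod(Q2, H %*% Q2)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  eta <- drop(crossprod(eg$vectors, crossprod(Q2, y)))
  m <- n - p
  negll <- function(loglam) {
    lam <- exp(loglam)
    s2 <- sum(eta^2 / (xi + lam)) / m
    0.5 * (m * log(s2) + sum(log(xi + lam)))
  }
  boundary <- FALSE
  if (is.null(lambda)) {
    ## coarse grid then local refinement: the profile can be multimodal-flat
    grid <- seq(log_bounds[1], log_bounds[2], length.out = 49)
    v <- vapply(grid, negll, 0)
    i <- which.min(v)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimise(negll, c(lo, hi), tol = 1e-10)
    loglam <- opt$minimum
    boundary <- loglam > log_bounds[2] - 0.3 || loglam < log_bounds[1] + 0.3
    lambda <- exp(loglam)
  }
  s2_k <- sum(eta^2 / (xi + lambda)) / m
  list(lambda = lambda, s2_k = s2_k, s2_e = lambda * s2_k,
       boundary = boundary)
}

## solve the mixed model given variance components; returns fixed effects,
## the kernel BLUP (genetic values) and the projection matrix pieces
mm_solve <- function(y, X, H, s2_k, s2_e) {
  n <- length(y)
  V <- s2_k * H + diag(s2_e, n)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  Cb <- solve(XtVi %*% X)
  b <- drop(Cb %*% (XtVi %*% y))
  P <- Vi - t(XtVi) %*% Cb %*% XtVi
  alpha <- drop(P %*% y)            # = Vi (y - X bhat)
  list(b = b, alpha = alpha, P = P, Vi = Vi, Cb = Cb)
}

#' Fit a ridge-regression BLUP (RR-BLUP) model
#'
#' `y = X b + Z u + e` with marker effects `u ~ N(0, I s2_u)` and residuals
#' `e ~ N(0, I s2_e)`; all marker effects are shrunken equally with ridge
#' penalty `lambda2 = s2_e / s2_u`. Variance components are REML estimates
#' from the spectral decomposition of the `Z Z'` kernel; effects come from
#' the mixed-model equations at those estimates.
#'
#' @param y Named (or `Z`-aligned) numeric vector of line phenotypes (BLUEs).
#' @param Z [marker_matrix()] (or matrix) of codes, rows aligned with `y`.
#' @param X Fixed-effect design matrix (default: intercept only). Must have
#'   full column rank.
#' @param lambda2 If supplied, the ridge parameter is fixed and only the
#'   scale variance is profiled (used for closed-form checks).
#' @return A list of class `gs_fit` with `b`, `u` (marker effects), `gebv`
#'   (fitted genetic values `Z u`), `sigma2_u`, `sigma2_e`, `lambda2`,
#'   `marker_ids`, `line_ids`.
#' @export
fit_rrblup <- function(y, Z, X = NULL, lambda2 = NULL) {
  Z <- unclass(Z)
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  if (nrow(Z) != length(y)) stop("rows of Z must align with y")
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  H <- tcrossprod(Z)
  vc <- reml_kernel(y, X, H, lambda = lambda2)
  if (vc$boundary && vc$lambda > 1)
    warning("marker variance estimated near zero: no genetic signal")
  sol <- mm_solve(y, X, H, vc$s2_k, vc$s2_e)
  u <- vc$s2_k * drop(crossprod(Z, sol$alpha))
  gebv <- drop(Z %*% u)
  names(gebv) <- rownames(Z) %||% names(y)
  structure(list(method = "rrblup", b = sol$b, u = setNames(u, colnames(Z)),
                 gebv = gebv, sigma2_u = vc$s2_k, sigma2_e = vc$s2_e,
                 lambda2 = vc$lambda,
                 marker_ids = colnames(Z), line_ids = names(gebv),
                 X = X),
            class = "gs_fit")
}

#' Fit a genomic BLUP (G-BLUP) model
#'
#' `y = X b + g + e` with genotypic effects `g ~ N(0, K s2_G)`. The kinship
#' matrix is stabilised by a ridge `K + eps I` before solving. Per-line
#' prediction error variances (PEV) and the reliability-type accuracy
#' `r_PEV = sqrt(1 - PEV / (G_ii s2_G))` are returned.
#'
#' @param y Phenotype vector aligned with `K`.
#' @param K A `kinship_matrix` from [compute_kinship()].
#' @param X Fixed-effect design (default intercept).
#' @param lambda2 Optional fixed variance ratio `s2_e / s2_G`.
#' @param ridge Stabilisation constant added to the diagonal of `K`.
#' @return A `gs_fit` with `g` (BLUPs), `gebv` (= `g`), `sigma2_G`,
#'   `sigma2_e`, `lambda2`, `pev`, `r_pev`, `G_ii`.
#' @export
fit_gblup <- function(y, K, X = NULL, lambda2 = NULL, ridge = 1e-8) {
  K <- unclass(K)
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  if (nrow(K) != length(y)) stop("K must align with y")
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  H <- K + diag(ridge, nrow(K))
  vc <- reml_kernel(y, X, H, lambda = lambda2)
  if (vc$boundary && vc$lambda > 1)
    warning("genetic variance estimated near zero: no genetic signal")
  sol <- mm_solve(y, X, H, vc$s2_k, vc$s2_e)
  g <- vc$s2_k * drop(H %*% sol$alpha)
  ## PEV = Var(g - ghat) = s2G K - s2G K P K s2G  (P accounts for bhat)
  KP <- H %*% sol$P
  pev <- vc$s2_k * diag(H) - vc$s2_k^2 * rowSums(KP * t(H))
  pev <- pmax(pev, 0)
  ids <- rownames(K) %||% names(y)
  names(g) <- ids; names(pev) <- ids
  G_ii <- setNames(diag(K), ids)
  r_pev <- line_accuracy_rpev(pev, G_ii, vc$s2_k)
  structure(list(method = "gblup", b = sol$b, g = g, gebv = g,
                 sigma2_G = vc$s2_k, sigma2_e = vc$s2_e, lambda2 = vc$lambda,
                 pev = pev, r_pev = r_pev, G_ii = G_ii,
                 line_ids = ids, X = X),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  v_g <- x$sigma2_u %||% x$sigma2_G
  cat(sprintf("%s fit: %d lines; s2_g = %.4g, s2_e = %.4g, lambda2 = %.4g\n",
              toupper(x$method), length(x$gebv), v_g, x$sigma2_e, x$lambda2))
  invisible(x)
}

#' Predict GEBVs for new lines from estimated marker effects
#'
#' `GEBV = Z_new u` (+ an optional fixed offset). Marker sets are aligned by
#' id; a non-trivial intersection is used with a warning when they differ.
#'
#' @param fit A `gs_fit` from [fit_rrblup()].
#' @param newlines [marker_matrix()] of candidate lines.
#' @param offset Fixed-effect offset added to every prediction (default 0;
#'   predictions are genetic deviations).
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, newlines, offset = 0) {
  if (is.null(fit$u)) stop("marker effects absent: fit with fit_rrblup()")
  Z <- unclass(newlines)
  common <- intersect(colnames(Z), names(fit$u))
  if (!length(common)) stop("empty marker intersection between fit and new lines")
  if (length(common) < length(fit$u) || length(common) < ncol(Z))
    warning("marker sets differ; using ", length(common), " common markers")
  drop(Z[, common, drop = FALSE] %*% fit$u[common]) + offset
}

#' Individual-line accuracy from prediction error variance
#'
#' `r_PEV = sqrt(1 - PEV / (G_ii * sigma2_G))`; values with `PEV` exceeding
#' `G_ii * sigma2_G` are clamped to 0 with a warning.
#'
#' @param pev Per-line prediction error variance(s), >= 0.
#' @param G_ii Kinship diagonal element(s).
#' @param sigma2_G Genetic variance (> 0).
#' @return Accuracy value(s) in `[0, 1]`.
#' @export
line_accuracy_rpev <- function(pev, G_ii, sigma2_G) {
  if (length(sigma2_G) != 1 || sigma2_G <= 0) stop("sigma2_G must be > 0")
  if (any(pev < 0)) stop("pev must be >= 0")
  denom <- G_ii * sigma2_G
  if (any(denom <= 0)) stop("G_ii * sigma2_G must be > 0")
  ratio <- pev / denom
  if (any(ratio > 1 + 1e-8))
    warning("PEV exceeds G_ii * sigma2_G for some lines; accuracy clamped to 0")
  sqrt(pmax(0, 1 - pmin(ratio, 1)))
}

#' G-BLUP prediction (with PEV) for unphenotyped lines
#'
#' Given a `gs_fit` from [fit_gblup()] on the training lines and a kinship
#' matrix covering training and new lines, returns the conditional-mean GEBVs
#' and prediction error variances of the new lines.
#'
#' @param fit A G-BLUP `gs_fit`.
#' @param K Kinship over a superset of training and new lines.
#' @param new_ids Line ids to predict.
#' @param ridge Diagonal stabilisation, as in [fit_gblup()].
#' @return A list with `gebv`, `pev` and `r_pev` (named by `new_ids`).
#' @export
predict_gblup <- function(fit, K, new_ids, ridge = 1e-8) {
  stopifnot(identical(fit$method, "gblup"))
  K <- unclass(K)
  tr <- fit$line_ids
  if (!all(tr %in% rownames(K)) || !all(new_ids %in% rownames(K)))
    stop("K must cover training and new lines")
  if (length(intersect(tr, new_ids)))
    stop("new lines overlap the training set")
  Ktt <- K[tr, tr, drop = FALSE] + diag(ridge, length(tr))
  Kvt <- K[new_ids, tr, drop = FALSE]
  s2 <- fit$sigma2_G
  y <- NULL # alpha from the stored fit
  ## recompute P-projected residual pieces from the training fit
  ## (gebv = s2 * Ktt %*% alpha  =>  alpha = s2^-1 Ktt^-1 gebv)
  alpha <- solve(Ktt, fit$g) / s2
  gebv <- s2 * drop(Kvt %*% alpha)
  ## conditional PEV given training phenotypes (fixed effects at their BLUE)
  V <- s2 * Ktt + diag(fit$sigma2_e, length(tr))
  Vi <- solve(V)
  pev <- s2 * diag(K)[new_ids] - s2^2 * rowSums((Kvt %*% Vi) * Kvt)
  pev <- pmax(pev, 0)
  r_pev <- line_accuracy_rpev(pev, diag(K)[new_ids], s2)
  list(gebv = setNames(gebv, new_ids), pev = setNames(pev, new_ids),
       r_pev = setNames(r_pev, new_ids))
}
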
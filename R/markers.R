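## markers: quality control, missing-genotype imputation and the genomic
## relationship matrix for near-inbred line populations genotyped with
## biallelic markers coded -1 (homozygote), 0 (heterozygote), +1 (homozygote).

#' Construct a marker matrix
#'
#' A lines x markers numeric matrix of genotype codes in \{-1, 0, +1\} with
#' `NA` for missing calls. Row and column names (line and marker ids) are
#' required and line ids must be unique. Imputed matrices may carry
#' continuous dosage-like codes in `[-1, 1]`.
#'
#' @param x A numeric matrix with dimnames.
#' @return The matrix with class `marker_matrix`.
#' @export
marker_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("marker matrix needs line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(x))) stop("duplicated line ids")
  rng <- range(x, na.rm = TRUE)
  if (rng[1] < -1 || rng[2] > 1)
    stop("genotype codes must lie in [-1, 1] (expected -1/0/+1)")
  structure(x, class = c("marker_matrix", class(matrix())))
}

#' @export
`[.marker_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("marker_matrix", class(matrix()))
  out
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x), "lines x", ncol(x), "markers;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x))))
  invisible(x)
}

#' Allele frequencies of the +1-coded allele
#'
#' Computed per marker on non-missing calls only, on the dosage scale
#' `(code + 1)/2`, so heterozygotes contribute half to each allele count.
#'
#' @param m A [marker_matrix()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_freq <- function(m) {
  colMeans((unclass(m) + 1) / 2, na.rm = TRUE)
}

#' Marker quality control
#'
#' Removes markers with a call rate below `min_call_rate`, a minor allele
#' frequency below `min_maf`, or more than `max_missing` missing data. A
#' marker failing several rules is counted once per rule but removed once;
#' per-rule counts are attached as attribute `qc_counts`.
#'
#' @param m A [marker_matrix()].
#' @param min_call_rate Minimum fraction of non-missing calls.
#' @param min_maf Minimum minor allele frequency (computed on non-missing
#'   calls).
#' @param max_missing Maximum fraction of missing calls.
#' @return The filtered [marker_matrix()].
#' @export
filter_markers <- function(m, min_call_rate = 0.90, min_maf = 0.05,
                           max_missing = 0.10) {
  stopifnot(inherits(m, "marker_matrix"))
  for (th in c(min_call_rate, min_maf, max_missing))
    if (!is.numeric(th) || th <= 0 || th >= 1)
      stop("QC thresholds must lie in (0, 1)")
  miss <- colMeans(is.na(unclass(m)))
  p <- allele_freq(m)
  maf <- pmin(p, 1 - p)
  fail_call <- (1 - miss) < min_call_rate
  fail_maf <- maf < min_maf
  fail_miss <- miss > max_missing
  keep <- !(fail_call | fail_maf | fail_miss)
  if (!any(keep))
    stop("empty marker set: all markers removed by QC")
  out <- m[, keep, drop = FALSE]
  attr(out, "qc_counts") <- c(call_rate = sum(fail_call), maf = sum(fail_maf),
                              missing = sum(fail_miss),
                              removed = sum(!keep), retained = sum(keep))
  out
}

#' Impute missing genotypes by a multivariate-normal EM algorithm
#'
#' Marker columns (centred by their observed mean) are modelled as draws from
#' a multivariate normal over lines with a line-by-line covariance matrix.
#' The E-step replaces each column's missing entries by their conditional
#' expectation given the observed entries and the current covariance (adding
#' the conditional covariance in the sufficient statistics); the M-step
#' re-estimates the covariance, shrunk towards its diagonal for stability
#' when lines outnumber informative markers locally. Iteration stops when the
#' relative change of the covariance falls below `tol`. Observed entries are
#' never altered; imputed values are clamped to `[-1, 1]`.
#'
#' @param m A [marker_matrix()] (QC already applied; every marker needs at
#'   least 2 non-missing calls).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative-change convergence tolerance.
#' @param shrink Shrinkage weight towards the diagonal of the covariance;
#'   the default `NULL` uses `max(0.02, N/(N+M))`, growing with the
#'   lines-to-markers ratio for stability while keeping strong line-line
#'   correlations intact when markers are plentiful.
#' @return A complete [marker_matrix()]; attribute `em_converged` reports
#'   convergence (a warning is raised otherwise) and `em_iter` the number of
#'   iterations used.
#' @export
impute_missing <- function(m, max_iter = 100, tol = 2e-4, shrink = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  X <- unclass(m)
  if (!anyNA(X)) {
    attr(m, "em_converged") <- TRUE
    attr(m, "em_iter") <- 0L
    return(m)
  }
  n_obs <- colSums(!is.na(X))
  if (any(n_obs < 2))
    stop("every marker needs >= 2 non-missing calls (run filter_markers first)")
  N <- nrow(X); M <- ncol(X)
  ## adaptive intensity: more lines per marker column -> noisier covariance
  ## -> stronger shrinkage; the floor keeps near-duplicate profiles intact
  if (is.null(shrink)) shrink <- max(0.02, N / (N + M))
  miss <- is.na(X)
  miss_cols <- which(colSums(miss) > 0)
  ## start from column-mean imputation; the marker means are re-estimated
  ## every iteration from the completed matrix (centring on observed-only
  ## means would conflict with the line-sum-zero degeneracy of the
  ## column-centred covariance and bias the conditional means)
  Xf <- X
  mu0 <- colMeans(X, na.rm = TRUE)
  for (k in miss_cols) Xf[miss[, k], k] <- mu0[k]
  converged <- FALSE; it <- 0L
  Cond <- matrix(0, N, N)
  Sigma_old <- NULL
  for (it in seq_len(max_iter)) {
    ## M-step: means and covariance from the completed data plus the
    ## accumulated conditional covariance of the imputed entries
    mu_col <- colMeans(Xf)
    Xc <- sweep(Xf, 2, mu_col)
    Sigma <- (tcrossprod(Xc) + Cond) / M
    Sigma <- (1 - shrink) * Sigma + shrink * diag(diag(Sigma) + 1e-8, N)
    if (!is.null(Sigma_old)) {
      delta <- norm(Sigma - Sigma_old, "F") / max(norm(Sigma_old, "F"), 1e-12)
      if (delta < tol) { converged <- TRUE; break }
    }
    Sigma_old <- Sigma
    ## E-step: conditional expectations from the precision matrix
    A <- solve(Sigma)
    Cond <- matrix(0, N, N)
    for (k in miss_cols) {
      mi <- which(miss[, k]); oi <- which(!miss[, k])
      Amm_inv <- solve(A[mi, mi, drop = FALSE])
      Xf[mi, k] <- mu_col[k] -
        drop(Amm_inv %*% (A[mi, oi, drop = FALSE] %*% Xc[oi, k]))
      Cond[mi, mi] <- Cond[mi, mi] + Amm_inv
    }
  }
  if (!converged)
    warning("MVN-EM imputation did not converge in ", max_iter, " iterations")
  out <- Xf
  out[!miss] <- X[!miss]
  out <- pmin(pmax(out, -1), 1)
  dimnames(out) <- dimnames(X)
  out <- marker_matrix(out)
  attr(out, "em_converged") <- converged
  attr(out, "em_iter") <- it
  out
}

#' Genomic relationship (kinship) matrix
#'
#' Computes `K = W W' / (2 * sum_k p_k (1 - p_k))` where `W` is the marker
#' matrix with each column centred to mean zero (equivalent to subtracting
#' `2 p_k - 1` from the \{-1,0,1\} codes) and `p_k` is the frequency of the
#' +1-coded allele. Rows of `K` sum to zero by construction of the centring.
#'
#' @param m A complete [marker_matrix()] (impute first).
#' @return A symmetric N x N matrix of class `kinship_matrix` with line ids
#'   as dimnames; attribute `denom` holds the normalisation constant.
#' @export
compute_kinship <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  X <- unclass(m)
  if (anyNA(X)) stop("missing genotypes present: run impute_missing first")
  p <- allele_freq(m)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic markers present: run filter_markers first")
  W <- sweep(X, 2, colMeans(X))
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  structure(K, class = c("kinship_matrix", class(matrix())), denom = denom)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix:", nrow(x), "lines; mean diagonal",
      sprintf("%.3f\n", mean(diag(x))))
  invisible(x)
}

#' @export
`[.kinship_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("kinship_matrix", class(matrix()))
  out
}
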